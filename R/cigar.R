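# CIGAR arithmetic used throughout: parsing, consumed lengths, reference span.
# Ops: M/=/X consume query+reference, I/S query only, D/N reference only,
# H/P neither. "=" and "X" are accepted on input and normalized to M for
# storage (adjacent runs merged), since the modcigar carries the mismatch
# information.

cigar_ops <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || cigar == "") {
    return(list(len = integer(0), op = character(0)))
  }
  lens <- regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]]
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops) ||
      nchar(cigar) != sum(nchar(lens)) + length(ops)) {
    stop("malformed CIGAR: ", cigar, call. = FALSE)
  }
  list(len = as.integer(lens), op = ops)
}

cigar_query_length <- function(cigar) {
  co <- cigar_ops(cigar)
  sum(co$len[co$op %in% c("M", "I", "S", "=", "X")])
}

#' Reference span of a CIGAR
#'
#' Number of reference bases consumed by an alignment (ops M, D, N, `=`, X),
#' so that a read starting at `pos` ends at `pos + reference_span(cigar) - 1`.
#'
#' @param cigar CIGAR string.
#' @return Integer span in bp (0 for `"*"`).
#' @export
reference_span <- function(cigar) {
  co <- cigar_ops(cigar)
  sum(co$len[co$op %in% c("M", "D", "N", "=", "X")])
}

# "="/"X" -> M with adjacent-run merging; canonical stored form
normalize_cigar <- function(cigar) {
  co <- cigar_ops(cigar)
  if (length(co$op) == 0L) return(cigar)
  op <- ifelse(co$op %in% c("=", "X"), "M", co$op)
  keep_len <- integer(0); keep_op <- character(0)
  for (i in seq_along(op)) {
    n <- length(keep_op)
    if (n > 0L && keep_op[[n]] == op[[i]]) {
      keep_len[[n]] <- keep_len[[n]] + co$len[[i]]
    } else {
      keep_len <- c(keep_len, co$len[[i]])
      keep_op <- c(keep_op, op[[i]])
    }
  }
  paste0(keep_len, keep_op, collapse = "")
}
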