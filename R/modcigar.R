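#' @title Reference-based read compression: the modcigar
#'
#' @description
#' Instead of storing a read's sequence (and quality string), only the bases
#' that differ from the reference are kept, in a compact auxiliary field
#' called the *modcigar* — the same idea CRAM uses for reference-based
#' compression, but rendered in plain text. Together with the reference
#' genome and the read's CIGAR, the modcigar reconstructs the original
#' sequence exactly. Quality strings are discarded irrecoverably; decoding
#' emits the SAM missing-quality sentinel `*`.
#'
#' A modcigar is an ordered list of tokens `(query_offset, op, bases)` with
#' 0-based query offsets, ops `X` (mismatch run), `I` (insertion) and `S`
#' (soft-clip), serialized as `"<offset><op><bases>"` joined by `";"`, e.g.
#' `"12XA;45IACG"`. The empty string means the read equals the reference over
#' its whole alignment. One token covers one contiguous run of differing
#' bases; offsets are strictly increasing.
#'
#' @name modcigar
NULL

new_modcigar <- function(offset = integer(0), op = character(0),
                         bases = character(0)) {
  structure(
    data.frame(offset = as.integer(offset), op = op, bases = bases,
               stringsAsFactors = FALSE),
    class = c("modcigar", "data.frame")
  )
}

#' @export
print.modcigar <- function(x, ...) {
  cat(sprintf("<modcigar> \"%s\"\n", modcigar_serialize(x)))
  invisible(x)
}

#' Serialize a modcigar to its canonical wire form
#'
#' @param m A `modcigar` object.
#' @return A string, `""` for the empty modcigar; the rendering is canonical —
#'   one rendering per value, so `modcigar_parse()` is an exact inverse.
#' @export
modcigar_serialize <- function(m) {
  if (nrow(m) == 0L) return("")
  paste0(m$offset, m$op, m$bases, collapse = ";")
}

#' Parse a serialized modcigar
#'
#' @param s Serialized modcigar string (see [modcigar]).
#' @return A `modcigar` object.
#' @export
modcigar_parse <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s)) {
    stop("modcigar must be a character scalar", call. = FALSE)
  }
  if (s == "") return(new_modcigar())
  toks <- strsplit(s, ";", fixed = TRUE)[[1]]
  mm <- regmatches(toks, regexec("^([0-9]+)([XIS])([ACGTN]+)$", toks))
  bad <- vapply(mm, length, 0L) != 4L
  if (any(bad)) stop("malformed modcigar token: '", toks[bad][[1]], "'",
                     call. = FALSE)
  off <- as.integer(vapply(mm, `[[`, "", 2L))
  if (any(diff(off) <= 0L) && length(off) > 1L) {
    stop("modcigar offsets must be strictly increasing", call. = FALSE)
  }
  new_modcigar(off, vapply(mm, `[[`, "", 3L), vapply(mm, `[[`, "", 4L))
}

#' Encode a read against the reference
#'
#' Walks the CIGAR over the read and the reference window and records every
#' difference: a token per contiguous mismatch run inside M/`=`/X segments,
#' one `I` token per insertion segment, one `S` token per soft-clip segment
#' (soft-clipped bases are absent from the reference so they are always
#' carried). The encoding is minimal — a read identical to the reference over
#' all aligned segments, with no insertions or soft clips, encodes to the
#' empty modcigar. Sequences are uppercased before comparison; `N` vs a
#' non-`N` base counts as a mismatch.
#'
#' @param seq Read sequence (its length must equal the CIGAR's
#'   query-consuming length).
#' @param cigar CIGAR string; `=`/`X` accepted and treated as M.
#' @param ref_window Reference bases starting at the read's mapped position;
#'   must cover the CIGAR's full reference span.
#' @return A `modcigar` object; `decode_sequence(ref_window, cigar, result)`
#'   reproduces `seq` exactly.
#' @export
encode_modcigar <- function(seq, cigar, ref_window) {
  seq <- toupper(seq); ref_window <- toupper(ref_window)
  co <- cigar_ops(cigar)
  qlen <- sum(co$len[co$op %in% c("M", "I", "S", "=", "X")])
  rlen <- sum(co$len[co$op %in% c("M", "D", "N", "=", "X")])
  if (nchar(seq) != qlen) {
    stop(sprintf("sequence length %d does not match CIGAR query length %d",
                 nchar(seq), qlen), call. = FALSE)
  }
  if (nchar(ref_window) < rlen) {
    stop(sprintf("reference window (%d bp) shorter than CIGAR span (%d bp)",
                 nchar(ref_window), rlen), call. = FALSE)
  }
  sq <- strsplit(seq, "", fixed = TRUE)[[1]]
  rf <- strsplit(ref_window, "", fixed = TRUE)[[1]]
  off <- integer(0); op <- character(0); bases <- character(0)
  q <- 0L; r <- 0L   # consumed so far
  for (i in seq_along(co$op)) {
    L <- co$len[[i]]
    o <- co$op[[i]]
    if (o %in% c("M", "=", "X")) {
      diffv <- sq[(q + 1L):(q + L)] != rf[(r + 1L):(r + L)]
      if (any(diffv)) {
        runs <- rle(diffv)
        at <- cumsum(c(0L, runs$lengths[-length(runs$lengths)]))
        for (j in which(runs$values)) {
          s0 <- at[[j]]; n <- runs$lengths[[j]]
          off <- c(off, q + s0)
          op <- c(op, "X")
          bases <- c(bases, paste(sq[(q + s0 + 1L):(q + s0 + n)],
                                  collapse = ""))
        }
      }
      q <- q + L; r <- r + L
    } else if (o %in% c("I", "S")) {
      off <- c(off, q)
      op <- c(op, if (o == "I") "I" else "S")
      bases <- c(bases, paste(sq[(q + 1L):(q + L)], collapse = ""))
      q <- q + L
    } else if (o %in% c("D", "N")) {
      r <- r + L
    }
    # H and P consume nothing and carry nothing
  }
  new_modcigar(off, op, bases)
}

#' Reconstruct a read sequence from reference, CIGAR and modcigar
#'
#' The inverse of [encode_modcigar()]: reference bases are copied for aligned
#' positions not covered by a mismatch token; `X` tokens overwrite aligned
#' positions; every insertion and soft-clip segment takes its bases from its
#' (mandatory) `I`/`S` token. Deleted/skipped reference bases (D/N) are
#' skipped.
#'
#' @param ref_window Reference bases starting at the read's mapped position.
#' @param cigar CIGAR string.
#' @param modcigar A `modcigar` object or its serialized string form.
#' @return The reconstructed read sequence; its length equals the CIGAR's
#'   query-consuming length.
#' @export
decode_sequence <- function(ref_window, cigar, modcigar) {
  if (is.character(modcigar)) modcigar <- modcigar_parse(modcigar)
  ref_window <- toupper(ref_window)
  co <- cigar_ops(cigar)
  qlen <- sum(co$len[co$op %in% c("M", "I", "S", "=", "X")])
  rlen <- sum(co$len[co$op %in% c("M", "D", "N", "=", "X")])
  if (nchar(ref_window) < rlen) {
    stop(sprintf("reference window (%d bp) shorter than CIGAR span (%d bp)",
                 nchar(ref_window), rlen), call. = FALSE)
  }
  rf <- strsplit(ref_window, "", fixed = TRUE)[[1]]
  out <- character(qlen)
  # segment bookkeeping for validation: which query interval belongs to which op
  seg_op <- character(0); seg_start <- integer(0); seg_len <- integer(0)
  q <- 0L; r <- 0L
  for (i in seq_along(co$op)) {
    L <- co$len[[i]]; o <- co$op[[i]]
    if (o %in% c("M", "=", "X")) {
      out[(q + 1L):(q + L)] <- rf[(r + 1L):(r + L)]
      seg_op <- c(seg_op, "M"); seg_start <- c(seg_start, q)
      seg_len <- c(seg_len, L)
      q <- q + L; r <- r + L
    } else if (o %in% c("I", "S")) {
      seg_op <- c(seg_op, if (o == "I") "I" else "S")
      seg_start <- c(seg_start, q); seg_len <- c(seg_len, L)
      q <- q + L
    } else if (o %in% c("D", "N")) {
      r <- r + L
    }
  }
  filled <- logical(length(seg_op))   # I/S segments that received their token
  if (nrow(modcigar) > 0L) {
    for (t in seq_len(nrow(modcigar))) {
      toff <- modcigar$offset[[t]]; top <- modcigar$op[[t]]
      tb <- modcigar$bases[[t]]; tn <- nchar(tb)
      if (top == "X") {
        seg <- which(seg_op == "M" & seg_start <= toff &
                       toff + tn <= seg_start + seg_len)
        if (length(seg) != 1L) {
          stop(sprintf("modcigar X token at offset %d falls outside aligned segments",
                       toff), call. = FALSE)
        }
      } else {
        want <- if (top == "I") "I" else "S"
        seg <- which(seg_op == want & seg_start == toff & seg_len == tn)
        if (length(seg) != 1L || filled[[seg]]) {
          stop(sprintf("modcigar %s token at offset %d does not match a CIGAR %s segment of length %d",
                       top, toff, want, tn), call. = FALSE)
        }
        filled[[seg]] <- TRUE
      }
      out[(toff + 1L):(toff + tn)] <- strsplit(tb, "", fixed = TRUE)[[1]]
    }
  }
  missing <- which(seg_op %in% c("I", "S") & !filled)
  if (length(missing)) {
    stop(sprintf("modcigar is missing bases for the CIGAR %s segment at query offset %d",
                 seg_op[[missing[[1]]]], seg_start[[missing[[1]]]]),
         call. = FALSE)
  }
  paste(out, collapse = "")
}
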