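# internal helpers shared across modules

hex_encode <- function(x) {
  if (is.character(x)) x <- charToRaw(x)
  paste(as.character(x), collapse = "")
}

# returns raw; NULL when the hex text is malformed (odd length / non-hex digit)
hex_decode <- function(h) {
  if (nchar(h) == 0L) return(raw(0))
  if (nchar(h) %% 2L != 0L) return(NULL)
  pairs <- substring(h, seq(1L, nchar(h), 2L), seq(2L, nchar(h), 2L))
  v <- suppressWarnings(strtoi(pairs, 16L))
  if (anyNA(v)) return(NULL)
  as.raw(v)
}

sha256_hex <- function(x) {
  if (is.character(x)) x <- charToRaw(x)
  digest::digest(x, algo = "sha256", serialize = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical JSON used for on-chain settings payloads: sorted names, no rounding
canonical_json <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
}
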