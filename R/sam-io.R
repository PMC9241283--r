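# SAM/BAM and reference FASTA I/O.
#
# Records are kept close to the wire: the 11 mandatory fields plus the
# optional tags as one verbatim tab-joined string, and the header as verbatim
# lines — the chain stores headers byte-for-byte and tags untouched, which a
# decomposed parse would not round-trip. BAM input/output is delegated to
# Rsamtools (asSam / asBam).

FLAG_UNMAPPED <- 4L

#' Read an alignment file into a record table
#'
#' Accepts SAM text or BAM (auto-detected by extension; BAM is converted via
#' `Rsamtools::asSam`).
#'
#' @param path SAM or BAM file.
#' @return A list with `header` (character vector of verbatim `@` lines) and
#'   `records`, a data.frame with the 11 mandatory SAM columns (`qname`,
#'   `flag`, `rname`, `pos`, `mapq`, `cigar`, `rnext`, `pnext`, `tlen`, `seq`,
#'   `qual`) plus `tags` (verbatim optional fields, tab-joined, `""` if none).
#' @export
read_sam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    tmp <- tempfile(fileext = ".sam")
    on.exit(unlink(tmp), add = TRUE)
    Rsamtools::asSam(path, sub("\\.sam$", "", tmp), overwrite = TRUE)
    path <- tmp
  }
  lines <- readLines(path, warn = FALSE)
  is_hdr <- startsWith(lines, "@")
  body <- lines[!is_hdr & nzchar(lines)]
  list(header = lines[is_hdr], records = parse_sam_lines(body))
}

parse_sam_lines <- function(lines) {
  if (length(lines) == 0L) {
    return(data.frame(qname = character(0), flag = integer(0),
                      rname = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0),
                      rnext = character(0), pnext = integer(0),
                      tlen = integer(0), seq = character(0),
                      qual = character(0), tags = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L)) {
    stop("malformed SAM record (fewer than 11 fields) at line ",
         which(nf < 11L)[[1]], call. = FALSE)
  }
  field <- function(i) vapply(parts, `[[`, "", i)
  data.frame(
    qname = field(1), flag = as.integer(field(2)), rname = field(3),
    pos = as.integer(field(4)), mapq = as.integer(field(5)),
    cigar = field(6), rnext = field(7), pnext = as.integer(field(8)),
    tlen = as.integer(field(9)), seq = field(10), qual = field(11),
    tags = vapply(parts, function(f) {
      if (length(f) > 11L) paste(f[-(1:11)], collapse = "\t") else ""
    }, ""),
    stringsAsFactors = FALSE
  )
}

sam_record_lines <- function(records) {
  base <- paste(records$qname, records$flag, records$rname, records$pos,
                records$mapq, records$cigar, records$rnext, records$pnext,
                records$tlen, records$seq, records$qual, sep = "\t")
  ifelse(nzchar(records$tags), paste(base, records$tags, sep = "\t"), base)
}

#' Write an alignment file
#'
#' Writes SAM text; with a `.bam` output path the SAM is converted with
#' `Rsamtools::asBam` (the index is not built).
#'
#' @param header Character vector of verbatim header lines.
#' @param records Record data.frame as produced by [read_sam()].
#' @param path Output `.sam` or `.bam` path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(header, records, path) {
  to_bam <- grepl("\\.bam$", path, ignore.case = TRUE)
  sam_path <- if (to_bam) tempfile(fileext = ".sam") else path
  writeLines(c(header, sam_record_lines(records)), sam_path)
  if (to_bam) {
    on.exit(unlink(sam_path), add = TRUE)
    Rsamtools::asBam(sam_path, sub("\\.bam$", "", path), overwrite = TRUE,
                     indexDestination = FALSE)
  }
  invisible(path)
}

#' Load a reference genome
#'
#' @param fasta Path to a (multi-record) FASTA file, or an already-loaded
#'   `DNAStringSet`.
#' @return A `DNAStringSet` named by the first whitespace-delimited token of
#'   each record header.
#' @export
read_reference <- function(fasta) {
  if (inherits(fasta, "DNAStringSet")) return(fasta)
  ref <- Biostrings::readDNAStringSet(fasta)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

# stable identifier of a reference: digest over names, lengths and sequence
# content, so a different genome with the same layout still mismatches
reference_id <- function(ref) {
  ref <- read_reference(ref)
  sha256_hex(paste(names(ref), Biostrings::width(ref), as.character(ref),
                   sep = ":", collapse = ";"))
}

# plain-string view of a reference for fast repeated window extraction
# (S4 subsetting per read is far too slow on large fixtures)
ref_cache <- function(ref) {
  ref <- read_reference(ref)
  list(seq = as.character(ref), len = Biostrings::width(ref),
       names = names(ref))
}

ref_window <- function(cache, chrom, start, len) {
  i <- match(chrom, cache$names)
  if (is.na(i)) stop("chromosome not in reference: ", chrom, call. = FALSE)
  substr(cache$seq[[i]], start, min(start + len - 1L, cache$len[[i]]))
}
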