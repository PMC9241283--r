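#' @title Variant chains
#'
#' @description
#' Stores a single-sample VCF on-chain in exactly two streams: `metaData`
#' (the verbatim header, line by line) and `allVariantData` (one item per
#' data line, payload verbatim). Unlike read chains there is no positional
#' binning — a variant is a point position, so the per-key index alone gives
#' efficient retrieval. Each item carries three retrieval keys:
#' `POS:<chrom>:<pos>`, `GT:<genotype>` and `ID:<rsid>` (the ID key is
#' omitted when the rsID is `.`). Conjunctive queries fetch by position and
#' filter by genotype and/or rsID.
#'
#' Positions are allowed to repeat (real VCFs do); all matches are returned.
#' Genotype keys are verbatim, so `0/1` and `0|1` are distinct (phasing
#' preserved); `query_variants(..., normalize_phase = TRUE)` folds them.
#'
#' @name varchain
NULL

VARIANT_STREAM <- "allVariantData"

#' Build a variant chain
#'
#' @param dir Directory for the new chain.
#' @param name Chain name.
#' @param owner Owner identity.
#' @param block_size Transactions per automatically sealed block.
#' @return A `genochain_varchain` handle.
#' @export
build_variant_chain <- function(dir, name = "varchain", owner = "owner",
                                block_size = 1000L) {
  store <- chain_create(dir, name = name, owner = owner,
                        block_size = block_size)
  create_stream(store, META_STREAM, owner)
  create_stream(store, VARIANT_STREAM, owner)
  mine_pending(store)
  structure(list(store = store), class = "genochain_varchain")
}

#' Open an existing variant chain
#' @param dir Chain directory created by [build_variant_chain()].
#' @return A `genochain_varchain` handle.
#' @export
open_variant_chain <- function(dir) {
  store <- chain_open(dir)
  if (!(VARIANT_STREAM %in% chain_streams(store))) {
    stop("no ", VARIANT_STREAM, " stream; not a variant chain", call. = FALSE)
  }
  structure(list(store = store), class = "genochain_varchain")
}

#' @export
print.genochain_varchain <- function(x, ...) {
  cat(sprintf("<variant chain '%s'> %d variants stored\n", x$store$name,
              length(x$store$streams[[VARIANT_STREAM]])))
  invisible(x)
}

# minimal field extraction for keys; the stored payload stays verbatim
parse_vcf_line <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 8L) return(NULL)
  if (length(f) > 10L) {
    stop("multi-sample VCF detected (", length(f) - 9L,
         " sample columns); variant chains hold a single personal genome",
         call. = FALSE)
  }
  pos <- suppressWarnings(as.integer(f[[2]]))
  if (is.na(pos) || pos < 1L || !nzchar(f[[4]])) return(NULL)
  gt <- NA_character_
  if (length(f) == 10L) {
    fmt <- strsplit(f[[9]], ":", fixed = TRUE)[[1]]
    gi <- match("GT", fmt)
    if (!is.na(gi)) {
      sv <- strsplit(f[[10]], ":", fixed = TRUE)[[1]]
      if (gi <= length(sv)) gt <- sv[[gi]]
    }
  }
  list(chrom = f[[1]], pos = pos, rsid = f[[3]], ref = f[[4]], alt = f[[5]],
       qual = f[[6]], filter = f[[7]], info = f[[8]], genotype = gt)
}

#' Insert a VCF into a variant chain
#'
#' Header lines go to `metaData` in order; each data line becomes one
#' `allVariantData` item whose payload is the original line verbatim, keyed
#' by position, genotype and (when present) rsID. A malformed data line is
#' reported with its line number and skipped; insertion continues.
#'
#' @param vc Variant-chain handle.
#' @param vcf Path to a single-sample VCF (4.x text).
#' @param publisher Publishing identity.
#' @return A report (class `genochain_vcf_report`): header line count,
#'   variants stored, and the line numbers of skipped malformed lines.
#' @export
insert_vcf <- function(vc, vcf, publisher = vc$store$owner) {
  stopifnot(inherits(vc, "genochain_varchain"))
  lines <- readLines(vcf, warn = FALSE)
  is_hdr <- startsWith(lines, "#")
  n_var <- 0L
  bad_lines <- integer(0)
  begin_batch(vc$store)
  on.exit(end_batch(vc$store), add = TRUE)
  for (ln in which(is_hdr)) {
    publish(vc$store, META_STREAM, publisher, keys = "header",
            data = lines[[ln]])
  }
  for (ln in which(!is_hdr & nzchar(lines))) {
    v <- parse_vcf_line(lines[[ln]])
    if (is.null(v)) {
      warning("skipping malformed VCF line ", ln, call. = FALSE)
      bad_lines <- c(bad_lines, ln)
      next
    }
    keys <- paste0("POS:", v$chrom, ":", v$pos)
    if (!is.na(v$genotype)) keys <- c(keys, paste0("GT:", v$genotype))
    if (v$rsid != ".") keys <- c(keys, paste0("ID:", v$rsid))
    publish(vc$store, VARIANT_STREAM, publisher, keys = keys,
            data = lines[[ln]])
    n_var <- n_var + 1L
  }
  mine_pending(vc$store)
  structure(list(header_lines = sum(is_hdr), variants = n_var,
                 malformed_lines = bad_lines),
            class = "genochain_vcf_report")
}

#' @export
print.genochain_vcf_report <- function(x, ...) {
  cat(sprintf("inserted %d variants + %d header lines%s\n", x$variants,
              x$header_lines,
              if (length(x$malformed_lines))
                sprintf(" (skipped %d malformed lines)",
                        length(x$malformed_lines)) else ""))
  invisible(x)
}

#' Conjunctive variant query
#'
#' Retrieves the variants at a genomic position via the `POS` key, then
#' filters by genotype and/or rsID when given (AND semantics). No match is an
#' empty result, not an error.
#'
#' @param vc Variant-chain handle.
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @param genotype Optional GT filter (e.g. `"0/1"`, `"0|1"`).
#' @param rsid Optional rsID filter (e.g. `"rs123"`).
#' @param normalize_phase Treat `|` and `/` genotype separators as equal.
#' @return A data.frame with the parsed fields (`chrom`, `pos`, `rsid`,
#'   `ref`, `alt`, `qual`, `filter`, `info`, `genotype`) plus `line`, the
#'   verbatim VCF data line, in publication order.
#' @export
query_variants <- function(vc, chrom, pos, genotype = NULL, rsid = NULL,
                           normalize_phase = FALSE) {
  items <- list_stream_key_items(vc$store, VARIANT_STREAM,
                                 paste0("POS:", chrom, ":", pos))
  fold <- function(g) if (normalize_phase) gsub("|", "/", g, fixed = TRUE)
                      else g
  rows <- list()
  for (d in items$data) {
    v <- parse_vcf_line(d)
    if (!is.null(genotype) &&
        (is.na(v$genotype) || fold(v$genotype) != fold(genotype))) next
    if (!is.null(rsid) && v$rsid != rsid) next
    rows[[length(rows) + 1L]] <-
      data.frame(chrom = v$chrom, pos = v$pos, rsid = v$rsid, ref = v$ref,
                 alt = v$alt, qual = v$qual, filter = v$filter,
                 info = v$info, genotype = v$genotype, line = d,
                 stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      rsid = character(0), ref = character(0),
                      alt = character(0), qual = character(0),
                      filter = character(0), info = character(0),
                      genotype = character(0), line = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Rebuild a VCF from a variant chain
#'
#' Concatenates the verbatim header lines from `metaData` and every stored
#' data line (publication order) — the input file up to data-line order.
#'
#' @param vc Variant-chain handle.
#' @param out Output path.
#' @return `out`, invisibly.
#' @export
build_vcf_file <- function(vc, out) {
  header <- list_stream_key_items(vc$store, META_STREAM, "header")$data
  body <- list_stream_items(vc$store, VARIANT_STREAM)$data
  writeLines(c(header, body), out)
  invisible(out)
}
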