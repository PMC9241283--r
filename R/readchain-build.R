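#' @title Binned read chains
#'
#' @description
#' A read chain stores a whole alignment file on a chain as three kinds of
#' streams: `metaData` (chain settings and the verbatim SAM header),
#' `unmappedANDcontigs` (unmapped reads and reads on non-configured
#' contigs, sequence kept verbatim for future realignment), and one binned
#' stream per fixed-length genomic interval, named `<chrom>stream<j>`. A read
#' is filed in the bin containing its start coordinate; a `FLANK=1` key marks
#' reads whose alignment spills into the next bin, so a region query knows to
#' also look one bin upstream. Binning is what makes region queries touch
#' only a handful of streams instead of scanning one giant stream.
#'
#' @name readchain
NULL

#' Chain configuration for a read chain
#'
#' @param chromosomes Chromosome lengths in bp: a named integer vector or a
#'   data.frame with columns `name` and `length`. Order is kept and defines
#'   the coordinate sort order.
#' @param bin_length Genomic interval length per binned stream, in bp. Must be
#'   at least `read_length`, so no read can span more than two bins (the FLANK
#'   key is binary).
#' @param read_length Declared maximum read length in bp.
#' @param reference_id Identifier of the reference genome the chain is tied
#'   to; pass a FASTA path / `DNAStringSet` to derive it, or `NULL` to skip
#'   reference checking.
#' @return A `genochain_config` object.
#' @export
chain_config <- function(chromosomes, bin_length, read_length,
                         reference_id = NULL) {
  if (!is.data.frame(chromosomes)) {
    chromosomes <- data.frame(name = names(chromosomes),
                              length = as.integer(chromosomes),
                              stringsAsFactors = FALSE)
  }
  chromosomes$length <- as.integer(chromosomes$length)
  if (nrow(chromosomes) == 0L || anyNA(chromosomes$length) ||
      any(chromosomes$length < 1L)) {
    stop("chromosome lengths must be positive integers", call. = FALSE)
  }
  if (anyDuplicated(chromosomes$name)) {
    stop("duplicate chromosome names", call. = FALSE)
  }
  bin_length <- as.integer(bin_length)
  read_length <- as.integer(read_length)
  if (is.na(bin_length) || bin_length < 1L ||
      is.na(read_length) || read_length < 1L) {
    stop("bin_length and read_length must be >= 1", call. = FALSE)
  }
  if (bin_length < read_length) {
    stop("bin_length must be >= read_length, otherwise a read could span ",
         "more than two bins", call. = FALSE)
  }
  if (!is.null(reference_id) &&
      (inherits(reference_id, "DNAStringSet") ||
       (is.character(reference_id) && file.exists(reference_id)))) {
    reference_id <- reference_id(read_reference(reference_id))
  }
  structure(
    list(chromosomes = chromosomes, bin_length = bin_length,
         read_length = read_length, reference_id = reference_id),
    class = "genochain_config"
  )
}

#' @export
print.genochain_config <- function(x, ...) {
  cat(sprintf(
    "<genochain config> %d chromosome(s), bin %s bp, read length %d bp\n",
    nrow(x$chromosomes), format(x$bin_length, big.mark = ","), x$read_length))
  invisible(x)
}

config_to_json <- function(config) {
  canonical_json(list(
    chromosomes = lapply(seq_len(nrow(config$chromosomes)), function(i) {
      list(name = config$chromosomes$name[[i]],
           length = config$chromosomes$length[[i]])
    }),
    bin_length = config$bin_length,
    read_length = config$read_length,
    reference_id = config$reference_id
  ))
}

config_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  chain_config(
    chromosomes = data.frame(
      name = vapply(x$chromosomes, `[[`, "", "name"),
      length = vapply(x$chromosomes, function(c) as.integer(c$length), 0L),
      stringsAsFactors = FALSE
    ),
    bin_length = x$bin_length, read_length = x$read_length,
    reference_id = if (is.character(x$reference_id)) x$reference_id else NULL
  )
}

#' Number of bins covering a chromosome
#'
#' Ceiling division: the smallest `k` with `k * bin_length >= chrom_length`.
#' For the 248,956,422 bp of human chromosome 1 at 1 Mbp bins this is 249.
#'
#' @param chrom_length Chromosome length in bp.
#' @param bin_length Bin length in bp.
#' @return Integer bin count.
#' @export
n_bins <- function(chrom_length, bin_length) {
  if (any(chrom_length < 1L) || any(bin_length < 1L)) {
    stop("lengths must be >= 1", call. = FALSE)
  }
  as.integer(ceiling(chrom_length / bin_length))
}

#' Bin index of a genomic position
#'
#' Bin `j` covers the closed interval
#' `[(j-1) * bin_length + 1, j * bin_length]` (1-based, both ends inclusive).
#'
#' @param pos 1-based reference position(s).
#' @param bin_length Bin length in bp.
#' @return 1-based bin index (vectorized over `pos`).
#' @export
bin_index <- function(pos, bin_length) {
  if (any(pos < 1L)) stop("positions are 1-based (pos >= 1)", call. = FALSE)
  as.integer((pos - 1) %/% bin_length + 1)
}

bin_stream_name <- function(chrom, j) paste0(chrom, "stream", j)

#' FLANK value of a mapped read
#'
#' `0` when the read's whole reference span lies in the bin of its start
#' position, `1` when it reaches into the next consecutive bin. A span
#' touching three or more bins is unrepresentable (FLANK is binary) and is an
#' error — ruled out up front by the `bin_length >= read_length` config
#' invariant.
#'
#' @param pos 1-based mapped start position.
#' @param cigar CIGAR string (reference span must be >= 1).
#' @param bin_length Bin length in bp.
#' @return `0L` or `1L`.
#' @export
flank_of <- function(pos, cigar, bin_length) {
  span <- reference_span(cigar)
  if (span < 1L) stop("reference span must be >= 1", call. = FALSE)
  b1 <- bin_index(pos, bin_length)
  b2 <- bin_index(pos + span - 1L, bin_length)
  if (b2 > b1 + 1L) {
    stop(sprintf("read at pos %d spans %d bins; only two consecutive bins are supported",
                 pos, b2 - b1 + 1L), call. = FALSE)
  }
  if (b2 == b1) 0L else 1L
}

META_STREAM <- "metaData"
UNMAPPED_STREAM <- "unmappedANDcontigs"
PAYLOAD_FORMAT <- "genochain-read-payload-v1"

#' Build a read chain
#'
#' Creates a fresh chain with the full stream layout: `metaData`,
#' `unmappedANDcontigs`, and one binned stream per `bin_length` interval of
#' every configured chromosome. The configuration is serialized canonically
#' and published to `metaData` under the key `settings`, along with the
#' payload grammar version under `format`; the stream-creation transactions
#' are sealed into a first block.
#'
#' @param dir Directory for the new chain.
#' @param config A [chain_config()].
#' @param name Chain name.
#' @param owner Owner identity.
#' @param block_size Transactions per automatically sealed block.
#' @return A read-chain handle of class `genochain_readchain`.
#' @export
build_read_chain <- function(dir, config, name = "readchain",
                             owner = "owner", block_size = 1000L) {
  stopifnot(inherits(config, "genochain_config"))
  store <- chain_create(dir, name = name, owner = owner,
                        block_size = block_size)
  begin_batch(store)
  on.exit(end_batch(store), add = TRUE)
  create_stream(store, META_STREAM, owner)
  create_stream(store, UNMAPPED_STREAM, owner)
  for (i in seq_len(nrow(config$chromosomes))) {
    chrom <- config$chromosomes$name[[i]]
    for (j in seq_len(n_bins(config$chromosomes$length[[i]],
                             config$bin_length))) {
      create_stream(store, bin_stream_name(chrom, j), owner)
    }
  }
  publish(store, META_STREAM, owner, keys = "settings",
          data = config_to_json(config))
  publish(store, META_STREAM, owner, keys = "format", data = PAYLOAD_FORMAT)
  mine_pending(store)
  new_readchain(store, config)
}

new_readchain <- function(store, config) {
  structure(list(store = store, config = config),
            class = "genochain_readchain")
}

#' Open an existing read chain
#'
#' @param dir Chain directory created by [build_read_chain()].
#' @return A `genochain_readchain` handle, with the configuration read back
#'   from the on-chain `settings` item.
#' @export
open_read_chain <- function(dir) {
  store <- chain_open(dir)
  it <- list_stream_key_items(store, META_STREAM, "settings")
  if (nrow(it) == 0L) stop("no settings found in metaData; not a read chain")
  new_readchain(store, config_from_json(it$data[[1]]))
}

#' @export
print.genochain_readchain <- function(x, ...) {
  nb <- sum(n_bins(x$config$chromosomes$length, x$config$bin_length))
  cat(sprintf(
    "<read chain '%s'> %d chromosome(s), %d binned streams (bin %s bp)\n",
    x$store$name, nrow(x$config$chromosomes), nb,
    format(x$config$bin_length, big.mark = ",")))
  invisible(x)
}

chrom_length <- function(config, chrom) {
  i <- match(chrom, config$chromosomes$name)
  if (is.na(i)) stop("chromosome not configured: ", chrom, call. = FALSE)
  config$chromosomes$length[[i]]
}

check_reference <- function(rc, ref) {
  if (!is.null(rc$config$reference_id) &&
      !identical(reference_id(ref), rc$config$reference_id)) {
    stop("reference mismatch: this chain was built against a different ",
         "reference genome", call. = FALSE)
  }
  invisible(TRUE)
}
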