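#' @title On-chain read analytics
#'
#' @description
#' Region queries over a read chain: retrieving reads (with their sequences
#' regenerated from reference + CIGAR + modcigar), CIGAR-aware per-position
#' depth, pileup columns, and reconstruction of a full alignment file.
#' Every query first maps the region to the bins that can hold overlapping
#' reads — the intersecting bins plus one bin upstream for `FLANK=1` reads —
#' and touches only those streams.
#'
#' Overlap is closed-interval on reference coordinates (a read whose end
#' equals the query start overlaps). The optional MAPQ filter is inclusive
#' (`mapq >= min_mapq` retained).
#'
#' @name readqueries
NULL

#' Bins a region query must visit
#'
#' The bins whose intervals intersect `[start, end]`, preceded by the single
#' bin immediately upstream of the first (when one exists): a read starting
#' in that bin can reach into the first intersecting bin, and such reads are
#' marked `FLANK=1` there.
#'
#' @param config A [chain_config()].
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive region bounds.
#' @return A data.frame with columns `chrom`, `j` (bin index), `stream`
#'   (stream name) and `upstream` (`TRUE` for the prepended upstream bin).
#' @export
streams_for <- function(config, chrom, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  clen <- chrom_length(config, chrom)
  if (start < 1L || end < start || end > clen) {
    stop(sprintf("invalid region %s:%d-%d (chromosome length %d)",
                 chrom, start, end, clen), call. = FALSE)
  }
  j1 <- bin_index(start, config$bin_length)
  j2 <- min(bin_index(end, config$bin_length),
            n_bins(clen, config$bin_length))
  j <- j1:j2
  upstream <- logical(length(j))
  if (j1 > 1L) {
    j <- c(j1 - 1L, j)
    upstream <- c(TRUE, upstream)
  }
  data.frame(chrom = chrom, j = j, stream = bin_stream_name(chrom, j),
             upstream = upstream, stringsAsFactors = FALSE)
}

# candidate records overlapping [start, end]: parsed payloads from the bins
# streams_for() dictates, truly-overlap filtered, MAPQ filtered, in
# (bin, publication) order. The upstream bin is read through its FLANK=1 key
# only — by construction no FLANK=0 read there can reach the region.
region_candidates <- function(rc, chrom, start, end, min_mapq = NULL) {
  sf <- streams_for(rc$config, chrom, start, end)
  out <- list()
  for (i in seq_len(nrow(sf))) {
    items <- if (sf$upstream[[i]]) {
      list_stream_key_items(rc$store, sf$stream[[i]], "FLANK=1")
    } else {
      list_stream_items(rc$store, sf$stream[[i]])
    }
    for (d in items$data) {
      rec <- parse_payload(d)
      if (!is.null(min_mapq) && rec$mapq < min_mapq) next
      rec$end <- rec$pos + reference_span(rec$cigar) - 1L
      if (rec$pos <= end && rec$end >= start) out[[length(out) + 1L]] <- rec
    }
  }
  out
}

#' Query reads overlapping a region
#'
#' Returns exactly the stored mapped records whose reference interval
#' intersects `[start, end]`, with sequences regenerated from the reference
#' and the on-chain modcigar. QUAL is the missing-quality sentinel `*`
#' (quality strings are not stored).
#'
#' @param rc Read-chain handle.
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive region bounds.
#' @param reference Reference FASTA path or `DNAStringSet`.
#' @param min_mapq Optional inclusive MAPQ filter.
#' @return A data.frame of SAM records (mandatory columns + `tags`), in
#'   (bin, publication) order.
#' @export
query_reads <- function(rc, chrom, start, end, reference, min_mapq = NULL) {
  ref <- read_reference(reference)
  check_reference(rc, ref)
  ref <- ref_cache(ref)
  cand <- region_candidates(rc, chrom, start, end, min_mapq)
  rows <- lapply(cand, function(rec) {
    win <- ref_window(ref, rec$rname, rec$pos, reference_span(rec$cigar))
    data.frame(
      qname = rec$qname, flag = rec$flag, rname = rec$rname, pos = rec$pos,
      mapq = rec$mapq, cigar = rec$cigar, rnext = rec$rnext,
      pnext = rec$pnext, tlen = rec$tlen,
      seq = decode_sequence(win, rec$cigar, rec$field10), qual = "*",
      tags = rec$tags, stringsAsFactors = FALSE
    )
  })
  if (length(rows) == 0L) {
    return(parse_sam_lines(character(0)))
  }
  do.call(rbind, rows)
}

# per-read walk shared by depth and pileup: for each reference position of
# the query covered by an M run, call on_base(offset, qpos); for each
# deleted/skipped position, call on_del(offset). Offsets are 1-based into
# [start, end].
walk_coverage <- function(rec, start, end, on_base, on_del) {
  co <- cigar_ops(rec$cigar)
  rpos <- rec$pos; qpos <- 1L
  for (k in seq_along(co$op)) {
    L <- co$len[[k]]; o <- co$op[[k]]
    if (o %in% c("M", "=", "X")) {
      lo <- max(rpos, start); hi <- min(rpos + L - 1L, end)
      if (lo <= hi) {
        for (p in lo:hi) on_base(p - start + 1L, qpos + (p - rpos))
      }
      rpos <- rpos + L; qpos <- qpos + L
    } else if (o %in% c("D", "N")) {
      if (o == "D") {
        lo <- max(rpos, start); hi <- min(rpos + L - 1L, end)
        if (lo <= hi) for (p in lo:hi) on_del(p - start + 1L)
      }
      rpos <- rpos + L
    } else if (o %in% c("I", "S")) {
      qpos <- qpos + L
    }
  }
}

#' Per-position sequencing depth over a region
#'
#' Depth at position `p` counts the retained reads with a query base aligned
#' to `p` — CIGAR ops that consume both query and reference (M/`=`/X). A
#' deletion or skip (D/N) in a read contributes 0 at the deleted positions;
#' insertions, clips and padding never cover a reference position. No
#' reference is needed: depth is computed from positions and CIGARs alone.
#'
#' @inheritParams query_reads
#' @return A named integer vector, one entry per position `start:end`.
#' @export
query_depth <- function(rc, chrom, start, end, min_mapq = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  depth <- integer(end - start + 1L)
  for (rec in region_candidates(rc, chrom, start, end, min_mapq)) {
    walk_coverage(rec, start, end,
                  on_base = function(off, qpos) {
                    depth[off] <<- depth[off] + 1L
                  },
                  on_del = function(off) NULL)
  }
  names(depth) <- as.character(start:end)
  depth
}

#' Pileup over a region
#'
#' One column per position covered by at least one aligned or deleted read:
#' the reference base, the depth (aligned bases only, consistent with
#' [query_depth()]), and the per-read observed bases in stream publication
#' order, with `*` marking reads deleted at that position (excluded from
#' depth).
#'
#' @inheritParams query_reads
#' @return A data.frame with columns `chrom`, `pos`, `ref_base`, `depth`,
#'   `bases`.
#' @export
pileup <- function(rc, chrom, start, end, reference, min_mapq = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  ref <- read_reference(reference)
  check_reference(rc, ref)
  ref <- ref_cache(ref)
  n <- end - start + 1L
  cols <- vector("list", n)   # per-position character vectors, read order
  for (rec in region_candidates(rc, chrom, start, end, min_mapq)) {
    win <- ref_window(ref, rec$rname, rec$pos, reference_span(rec$cigar))
    sq <- strsplit(decode_sequence(win, rec$cigar, rec$field10), "",
                   fixed = TRUE)[[1]]
    walk_coverage(rec, start, end,
                  on_base = function(off, qpos) {
                    cols[[off]] <<- c(cols[[off]], sq[[qpos]])
                  },
                  on_del = function(off) {
                    cols[[off]] <<- c(cols[[off]], "*")
                  })
  }
  keep <- which(lengths(cols) > 0L)
  if (length(keep) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref_base = character(0), depth = integer(0),
                      bases = character(0), stringsAsFactors = FALSE))
  }
  refseq <- strsplit(ref_window(ref, chrom, start, n), "", fixed = TRUE)[[1]]
  data.frame(
    chrom = chrom, pos = start + keep - 1L, ref_base = refseq[keep],
    depth = vapply(cols[keep], function(b) sum(b != "*"), 0L),
    bases = vapply(cols[keep], paste, "", collapse = ""),
    stringsAsFactors = FALSE
  )
}

#' Rebuild an alignment file from a read chain
#'
#' Retrieves the verbatim header from `metaData`, every stored record from
#' the binned streams (sequences regenerated against the reference) and from
#' `unmappedANDcontigs` (sequences verbatim), and writes a coordinate-sorted
#' SAM or BAM file with unmapped records last. QUAL is `*` throughout:
#' quality strings are discarded at insertion and cannot be recovered.
#'
#' @param rc Read-chain handle.
#' @param reference Reference FASTA path or `DNAStringSet`.
#' @param out Output `.sam` or `.bam` path.
#' @return `out`, invisibly.
#' @export
build_alignment_file <- function(rc, reference, out) {
  ref <- read_reference(reference)
  check_reference(rc, ref)
  ref <- ref_cache(ref)
  config <- rc$config
  header <- list_stream_key_items(rc$store, META_STREAM, "header")$data

  payloads <- character(0)
  rank <- integer(0)
  for (i in seq_len(nrow(config$chromosomes))) {
    chrom <- config$chromosomes$name[[i]]
    for (j in seq_len(n_bins(config$chromosomes$length[[i]],
                             config$bin_length))) {
      d <- list_stream_items(rc$store, bin_stream_name(chrom, j))$data
      payloads <- c(payloads, d)
      rank <- c(rank, rep(i, length(d)))
    }
  }
  mapped <- parse_payload_frame(payloads)
  mapped$seq <- vapply(seq_len(nrow(mapped)), function(k) {
    win <- ref_window(ref, mapped$rname[[k]], mapped$pos[[k]],
                      reference_span(mapped$cigar[[k]]))
    decode_sequence(win, mapped$cigar[[k]], mapped$field10[[k]])
  }, "")
  ord <- order(rank, mapped$pos)
  mapped <- mapped[ord, , drop = FALSE]

  unmapped <- parse_payload_frame(
    list_stream_items(rc$store, UNMAPPED_STREAM)$data)
  unmapped$seq <- unmapped$field10   # stored verbatim

  records <- rbind(mapped, unmapped)
  records$qual <- rep("*", nrow(records))
  records$field10 <- NULL
  records <- records[, c("qname", "flag", "rname", "pos", "mapq", "cigar",
                         "rnext", "pnext", "tlen", "seq", "qual", "tags"),
                     drop = FALSE]
  write_sam(header, records, out)
}
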