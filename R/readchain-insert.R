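# Insertion of SAM data into a read chain, with storage-limit checking and
# resumable checkpoints.
#
# On-chain payload grammar (version genochain-read-payload-v1), tab-separated:
#   binned streams:      qname flag rname pos mapq cigar rnext pnext tlen
#                        modcigar [tags...]
#   unmappedANDcontigs:  qname flag rname pos mapq cigar rnext pnext tlen
#                        seq [tags...]
# Quality strings are discarded irrecoverably at encode time; reconstruction
# emits "*". Optional SAM tags are stored verbatim as the tab-joined tail.

mapped_payload <- function(rec, modcigar_str) {
  base <- paste(rec$qname, rec$flag, rec$rname, rec$pos, rec$mapq,
                normalize_cigar(rec$cigar), rec$rnext, rec$pnext, rec$tlen,
                modcigar_str, sep = "\t")
  if (nzchar(rec$tags)) paste(base, rec$tags, sep = "\t") else base
}

unmapped_payload <- function(rec) {
  base <- paste(rec$qname, rec$flag, rec$rname, rec$pos, rec$mapq,
                rec$cigar, rec$rnext, rec$pnext, rec$tlen, rec$seq,
                sep = "\t")
  if (nzchar(rec$tags)) paste(base, rec$tags, sep = "\t") else base
}

# shared by query/rebuild paths; field 10 is the modcigar (binned streams)
# or the verbatim sequence (unmappedANDcontigs)
parse_payload <- function(data) {
  f <- strsplit(data, "\t", fixed = TRUE)[[1]]
  if (length(f) == 9L) f <- c(f, "")   # strsplit drops a trailing empty field
  list(qname = f[[1]], flag = as.integer(f[[2]]), rname = f[[3]],
       pos = as.integer(f[[4]]), mapq = as.integer(f[[5]]), cigar = f[[6]],
       rnext = f[[7]], pnext = as.integer(f[[8]]), tlen = as.integer(f[[9]]),
       field10 = f[[10]],
       tags = if (length(f) > 10L) paste(f[-(1:10)], collapse = "\t") else "")
}

# vectorized payload parse -> data.frame (field10 as its own column)
parse_payload_frame <- function(datas) {
  if (length(datas) == 0L) {
    return(data.frame(qname = character(0), flag = integer(0),
                      rname = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0),
                      rnext = character(0), pnext = integer(0),
                      tlen = integer(0), field10 = character(0),
                      tags = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(datas, "\t", fixed = TRUE)
  fld <- function(i, pad = FALSE) {
    vapply(parts, function(f) {
      if (pad && length(f) < i) "" else f[[i]]
    }, "")
  }
  data.frame(
    qname = fld(1), flag = as.integer(fld(2)), rname = fld(3),
    pos = as.integer(fld(4)), mapq = as.integer(fld(5)), cigar = fld(6),
    rnext = fld(7), pnext = as.integer(fld(8)), tlen = as.integer(fld(9)),
    field10 = fld(10, pad = TRUE),
    tags = vapply(parts, function(f) {
      if (length(f) > 10L) paste(f[-(1:10)], collapse = "\t") else ""
    }, ""),
    stringsAsFactors = FALSE
  )
}

is_unmapped_record <- function(rec, config) {
  bitwAnd(rec$flag, FLAG_UNMAPPED) != 0L || rec$rname == "*" ||
    !(rec$rname %in% config$chromosomes$name)
}

checkpoint_path <- function(rc) file.path(rc$store$dir, "insert.checkpoint")

write_checkpoint <- function(rc, done, total) {
  writeLines(canonical_json(list(done = done, total = total)),
             checkpoint_path(rc))
}

#' Default free-storage probe
#'
#' Queries the filesystem holding the chain directory (via `df -kP`) for the
#' available byte count. Returns `Inf` when the probe is unavailable, so
#' insertion is never blocked by a missing `df`.
#'
#' @param rc Read-chain handle.
#' @return Free bytes (numeric scalar).
#' @export
default_storage_check <- function(rc) {
  out <- tryCatch(
    suppressWarnings(system2("df", c("-kP", shQuote(rc$store$dir)),
                             stdout = TRUE, stderr = FALSE)),
    error = function(e) NULL
  )
  if (is.null(out) || length(out) < 2L) return(Inf)
  f <- strsplit(trimws(out[[2]]), "\\s+")[[1]]
  avail <- suppressWarnings(as.numeric(f[[4]]))
  if (is.na(avail)) Inf else avail * 1024
}

storage_error <- function(rc, done, total, free_bytes) {
  structure(
    class = c("genochain_storage_error", "error", "condition"),
    list(
      message = sprintf(
        paste0("storage limit reached after %d of %d units (%.0f bytes free);",
               " chain sealed at %s; rerun insert_alignments(..., resume = TRUE)",
               " after freeing space"),
        done, total, free_bytes, rc$store$dir),
      call = NULL, done = done, total = total
    )
  )
}

#' Insert SAM data into a read chain
#'
#' Publishes the header line-by-line (in order) to `metaData`, then every
#' record: reads flagged unmapped, with `rname` `*`, or on a non-configured
#' contig go to `unmappedANDcontigs` with their sequence verbatim (they may
#' be realigned later); every other record is encoded against the reference
#' ([encode_modcigar()]), its SEQ and QUAL dropped, and published to the
#' binned stream of its start position under the key `FLANK=0` or `FLANK=1`.
#' Secondary/supplementary alignments are stored like primary ones; duplicate
#' reads are not collapsed.
#'
#' Free storage is probed every `check_every` records; when it falls below
#' `min_free_bytes` the pending block is sealed, a checkpoint (the ordinal of
#' the last fully inserted unit) is persisted, and a classed
#' `genochain_storage_error` is raised carrying the resume point. Re-running
#' with `resume = TRUE` skips already-inserted units, yielding a chain
#' identical to an uninterrupted insertion.
#'
#' @param rc Read-chain handle.
#' @param sam SAM/BAM path, or a `list(header, records)` as from [read_sam()].
#' @param reference Reference FASTA path or `DNAStringSet` (needed to compute
#'   modcigars); must match the chain's `reference_id` when one is set.
#' @param publisher Publishing identity (needs write permission).
#' @param resume Continue an interrupted insertion from its checkpoint.
#' @param check_every Probe storage every this many records.
#' @param min_free_bytes Seal and raise when free storage drops below this.
#' @param storage_check Probe function `function(rc) -> free bytes`; the
#'   default inspects the filesystem. Tests substitute a simulated probe.
#' @return An insertion report (class `genochain_insert_report`): counts of
#'   header lines, mapped, unmapped and FLANK=1 reads, and the resume offset.
#' @export
insert_alignments <- function(rc, sam, reference, publisher = rc$store$owner,
                              resume = FALSE, check_every = 1000L,
                              min_free_bytes = 50e6,
                              storage_check = default_storage_check) {
  stopifnot(inherits(rc, "genochain_readchain"))
  if (is.character(sam)) sam <- read_sam(sam)
  ref <- read_reference(reference)
  check_reference(rc, ref)
  ref <- ref_cache(ref)
  config <- rc$config
  store <- rc$store

  cp <- checkpoint_path(rc)
  done0 <- 0L
  if (resume) {
    if (!file.exists(cp)) stop("no checkpoint to resume from", call. = FALSE)
    done0 <- as.integer(jsonlite::fromJSON(readLines(cp, warn = FALSE))$done)
  } else if (file.exists(cp)) {
    stop("an interrupted insertion exists for this chain; rerun with ",
         "resume = TRUE (or build a fresh chain)", call. = FALSE)
  }

  # one unit = one header line or one record, in file order
  n_hdr <- length(sam$header)
  n_rec <- nrow(sam$records)
  total <- n_hdr + n_rec
  mapped <- 0L; unmapped <- 0L; flank1 <- 0L
  done <- done0

  begin_batch(store)
  on.exit(end_batch(store), add = TRUE)

  check_storage <- function() {
    free <- storage_check(rc)
    if (free < min_free_bytes) {
      mine_pending(store)
      write_checkpoint(rc, done, total)
      stop(storage_error(rc, done, total, free))
    }
  }

  for (u in seq_len(total)) {
    if (u <= done0) next
    if (u <= n_hdr) {
      publish(store, META_STREAM, publisher, keys = "header",
              data = sam$header[[u]])
    } else {
      i <- u - n_hdr
      if ((i %% check_every) == 1L || check_every == 1L) check_storage()
      rec <- lapply(sam$records, `[[`, i)
      if (is_unmapped_record(rec, config)) {
        publish(store, UNMAPPED_STREAM, publisher,
                keys = "UNMAPPED", data = unmapped_payload(rec))
        unmapped <- unmapped + 1L
      } else {
        span <- reference_span(rec$cigar)
        win <- ref_window(ref, rec$rname, rec$pos, span)
        mc <- encode_modcigar(rec$seq, rec$cigar, win)
        j <- bin_index(rec$pos, config$bin_length)
        jmax <- n_bins(chrom_length(config, rec$rname), config$bin_length)
        flank <- flank_of(rec$pos, rec$cigar, config$bin_length)
        if (j + flank > jmax) {
          stop(sprintf("read '%s' extends beyond the end of %s", rec$qname,
                       rec$rname), call. = FALSE)
        }
        publish(store, bin_stream_name(rec$rname, j), publisher,
                keys = paste0("FLANK=", flank),
                data = mapped_payload(rec, modcigar_serialize(mc)))
        mapped <- mapped + 1L
        if (flank == 1L) flank1 <- flank1 + 1L
      }
    }
    done <- u
  }
  mine_pending(store)
  if (file.exists(cp)) unlink(cp)
  structure(
    list(header_lines = n_hdr, records = n_rec, mapped = mapped,
         unmapped = unmapped, flank1 = flank1, resumed_from = done0),
    class = "genochain_insert_report"
  )
}

#' @export
print.genochain_insert_report <- function(x, ...) {
  cat(sprintf(
    "inserted %d records (%d mapped, %d unmapped/contig, %d FLANK=1) + %d header lines%s\n",
    x$records, x$mapped, x$unmapped, x$flank1, x$header_lines,
    if (x$resumed_from > 0L) sprintf(" [resumed from unit %d]", x$resumed_from)
    else ""))
  invisible(x)
}
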