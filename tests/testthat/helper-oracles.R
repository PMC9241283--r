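# Brute-force reference implementations used as oracles. They operate on the
# original SAM/VCF records (never on chain state) and use their own
# character-by-character CIGAR walker, independent of the package's parsing
# and query code paths.

oracle_cigar_ops <- function(cigar) {
  ops <- list()
  num <- ""
  for (ch in strsplit(cigar, "", fixed = TRUE)[[1]]) {
    if (ch >= "0" && ch <= "9") {
      num <- paste0(num, ch)
    } else {
      ops[[length(ops) + 1L]] <- list(len = as.integer(num), op = ch)
      num <- ""
    }
  }
  ops
}

oracle_ref_span <- function(cigar) {
  s <- 0L
  for (o in oracle_cigar_ops(cigar)) {
    if (o$op %in% c("M", "D", "N", "=", "X")) s <- s + o$len
  }
  s
}

# per-read coverage map: aligned reference positions (and the query index
# observing each), plus deleted reference positions
oracle_covered <- function(pos, cigar) {
  cover <- integer(0); qidx <- integer(0); del <- integer(0)
  r <- pos; q <- 1L
  for (o in oracle_cigar_ops(cigar)) {
    if (o$op %in% c("M", "=", "X")) {
      cover <- c(cover, r:(r + o$len - 1L))
      qidx <- c(qidx, q:(q + o$len - 1L))
      r <- r + o$len; q <- q + o$len
    } else if (o$op == "D") {
      del <- c(del, r:(r + o$len - 1L))
      r <- r + o$len
    } else if (o$op == "N") {
      r <- r + o$len
    } else if (o$op %in% c("I", "S")) {
      q <- q + o$len
    }
  }
  list(cover = cover, qidx = qidx, del = del)
}

oracle_mapped <- function(records, chrom, min_mapq = NULL) {
  keep <- bitwAnd(records$flag, 4L) == 0L & records$rname == chrom
  if (!is.null(min_mapq)) keep <- keep & records$mapq >= min_mapq
  records[keep, , drop = FALSE]
}

# reads whose closed reference interval intersects [start, end]
oracle_overlaps <- function(records, chrom, start, end, min_mapq = NULL) {
  recs <- oracle_mapped(records, chrom, min_mapq)
  if (nrow(recs) == 0L) return(recs)
  span <- vapply(recs$cigar, oracle_ref_span, 0L)
  recs[recs$pos <= end & recs$pos + span - 1L >= start, , drop = FALSE]
}

oracle_depth <- function(records, chrom, start, end, min_mapq = NULL) {
  depth <- integer(end - start + 1L)
  recs <- oracle_mapped(records, chrom, min_mapq)
  for (i in seq_len(nrow(recs))) {
    cov <- oracle_covered(recs$pos[[i]], recs$cigar[[i]])$cover
    cov <- cov[cov >= start & cov <= end]
    depth[cov - start + 1L] <- depth[cov - start + 1L] + 1L
  }
  names(depth) <- as.character(start:end)
  depth
}

# pileup as (pos, ref_base, depth, sorted base multiset incl "*" markers),
# built from the original sequences
oracle_pileup <- function(records, refstr, chrom, start, end,
                          min_mapq = NULL) {
  recs <- oracle_mapped(records, chrom, min_mapq)
  bases <- rep(list(character(0)), end - start + 1L)
  for (i in seq_len(nrow(recs))) {
    cov <- oracle_covered(recs$pos[[i]], recs$cigar[[i]])
    sq <- strsplit(recs$seq[[i]], "", fixed = TRUE)[[1]]
    sel <- which(cov$cover >= start & cov$cover <= end)
    for (k in sel) {
      off <- cov$cover[[k]] - start + 1L
      bases[[off]] <- c(bases[[off]], toupper(sq[[cov$qidx[[k]]]]))
    }
    for (d in cov$del[cov$del >= start & cov$del <= end]) {
      off <- d - start + 1L
      bases[[off]] <- c(bases[[off]], "*")
    }
  }
  keep <- which(lengths(bases) > 0L)
  if (length(keep) == 0L) {
    return(data.frame(pos = integer(0), ref_base = character(0),
                      depth = integer(0), bases = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    pos = as.integer(start + keep - 1L),
    ref_base = substring(refstr, start + keep - 1L, start + keep - 1L),
    depth = vapply(bases[keep], function(b) sum(b != "*"), 0L),
    bases = vapply(bases[keep], function(b) paste(sort(b), collapse = ""), ""),
    stringsAsFactors = FALSE
  )
}

# linear scan of verbatim VCF data lines for a conjunctive query
oracle_vcf_query <- function(lines, chrom, pos, gt = NULL, rsid = NULL) {
  hits <- character(0)
  for (line in lines) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (f[[1]] != chrom || as.integer(f[[2]]) != pos) next
    if (!is.null(rsid) && f[[3]] != rsid) next
    if (!is.null(gt)) {
      fmt <- strsplit(f[[9]], ":", fixed = TRUE)[[1]]
      sv <- strsplit(f[[10]], ":", fixed = TRUE)[[1]]
      if (!identical(sv[[match("GT", fmt)]], gt)) next
    }
    hits <- c(hits, line)
  }
  hits
}
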