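#' @title Deterministic synthetic genomics fixtures
#'
#' @description
#' Generates toy reference genomes (FASTA), simulated aligned reads (SAM) and
#' simulated variants (VCF) as pure functions of a parameter set — the same
#' parameters always produce byte-identical files, on any platform, so every
#' chain module is testable without downloads. This is a test fixture
#' generator, not a sequencing simulator: bases are uniform, mutations are
#' applied per base independently, and there is no quality model (QUAL is a
#' constant character, which makes its deliberate loss in the chain visible
#' in round-trip diffs).
#'
#' @name synthetic
NULL

#' Simulation parameters
#'
#' @param seed Integer seed; each generator draws from its own substream
#'   (fixed offsets from `seed`), so regenerating one artifact never perturbs
#'   another.
#' @param chromosomes Named integer vector of chromosome lengths (bp).
#' @param n_reads Total reads to simulate.
#' @param read_length Read length in bp.
#' @param mismatch_rate,insertion_rate,deletion_rate Per-base event
#'   probabilities for mapped reads; indel lengths are geometric with mean 2,
#'   capped at `read_length / 4`.
#' @param softclip_rate Probability that a read end carries a soft-clip.
#' @param unmapped_fraction Fraction of reads emitted unmapped (FLAG 0x4,
#'   `rname` `*`).
#' @param n_variants Variant count for [simulate_vcf()].
#' @param het_fraction Probability a variant genotype is heterozygous (`0/1`
#'   rather than `1/1`).
#' @param rsid_fraction Fraction of variants assigned an `rs<k>` identifier
#'   (the rest get `.`).
#' @return A `genochain_sim_params` list.
#' @export
sim_params <- function(seed = 1L,
                       chromosomes = c(chr1 = 2000000L),
                       n_reads = 10000L,
                       read_length = 150L,
                       mismatch_rate = 0.01,
                       insertion_rate = 0.001,
                       deletion_rate = 0.001,
                       softclip_rate = 0.01,
                       unmapped_fraction = 0.02,
                       n_variants = 1000L,
                       het_fraction = 0.6,
                       rsid_fraction = 0.5) {
  rates <- c(mismatch_rate, insertion_rate, deletion_rate, softclip_rate,
             unmapped_fraction, het_fraction, rsid_fraction)
  if (any(rates < 0) || any(rates > 1)) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (any(chromosomes < 1L) || read_length < 1L) {
    stop("lengths must be >= 1", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed),
         chromosomes = vapply(chromosomes, as.integer, 0L),
         n_reads = as.integer(n_reads), read_length = as.integer(read_length),
         mismatch_rate = mismatch_rate, insertion_rate = insertion_rate,
         deletion_rate = deletion_rate, softclip_rate = softclip_rate,
         unmapped_fraction = unmapped_fraction,
         n_variants = as.integer(n_variants), het_fraction = het_fraction,
         rsid_fraction = rsid_fraction),
    class = "genochain_sim_params"
  )
}

BASES <- c("A", "C", "G", "T")

with_substream <- function(params, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((params$seed + offset) %% 2147483647L)
  force(expr)
}

#' Generate a synthetic reference genome
#'
#' One FASTA record per configured chromosome, uniform random bases over
#' A/C/G/T at exactly the declared lengths.
#'
#' @param params [sim_params()].
#' @param path Optional output FASTA path.
#' @return A `DNAStringSet`; written to `path` when given.
#' @export
make_reference <- function(params, path = NULL) {
  ref <- with_substream(params, 0L, {
    seqs <- vapply(params$chromosomes, function(len) {
      paste(sample(BASES, len, replace = TRUE), collapse = "")
    }, "")
    Biostrings::DNAStringSet(seqs)
  })
  names(ref) <- names(params$chromosomes)
  if (!is.null(path)) Biostrings::writeXStringSet(ref, path, width = 70L)
  ref
}

geom_len <- function(cap) min(1L + stats::rgeom(1L, 0.5), max(1L, cap))

# one mapped read against a chromosome sequence (character scalar); returns
# the SAM fields that depend on the alignment. The aligned portion always
# starts and ends with M; indel events occur between aligned bases.
sim_mapped_read <- function(refstr, params, ref_len = nchar(refstr)) {
  rl <- params$read_length
  cap <- max(1L, rl %/% 4L)
  lead <- if (stats::runif(1) < params$softclip_rate / 2) {
    min(geom_len(cap) + 2L, cap)
  } else 0L
  trail <- if (stats::runif(1) < params$softclip_rate / 2) {
    min(geom_len(cap) + 2L, cap)
  } else 0L
  if (lead + trail >= rl) { lead <- 0L; trail <- 0L }   # degenerate short reads
  target <- rl - lead - trail          # aligned query bases
  start <- sample.int(ref_len - 2L * rl, 1L)

  mism <- stats::runif(target) < params$mismatch_rate
  ins_after <- stats::runif(target) < params$insertion_rate
  del_after <- stats::runif(target) < params$deletion_rate
  ins_after[[target]] <- FALSE; del_after[[target]] <- FALSE

  op <- character(0); len <- integer(0); pieces <- character(0)
  add <- function(o, L) {
    n <- length(op)
    if (n > 0L && op[[n]] == o) len[[n]] <<- len[[n]] + L
    else { op <<- c(op, o); len <<- c(len, L) }
  }
  if (lead > 0L) {
    add("S", lead)
    pieces <- c(pieces, paste(sample(BASES, lead, replace = TRUE),
                              collapse = ""))
  }
  r <- start; prev <- 0L
  for (e in c(which(ins_after | del_after), target)) {
    L <- e - prev
    if (L > 0L) {
      seg <- substr(refstr, r, r + L - 1L)
      for (i in which(mism[(prev + 1L):e])) {
        b <- substr(seg, i, i)
        substr(seg, i, i) <- sample(setdiff(BASES, b), 1L)
      }
      add("M", L); pieces <- c(pieces, seg); r <- r + L
    }
    if (e < target && ins_after[[e]]) {
      Li <- geom_len(cap)
      add("I", Li)
      pieces <- c(pieces, paste(sample(BASES, Li, replace = TRUE),
                                collapse = ""))
    }
    if (e < target && del_after[[e]]) {
      Ld <- geom_len(cap)
      add("D", Ld); r <- r + Ld
    }
    prev <- e
  }
  if (trail > 0L) {
    add("S", trail)
    pieces <- c(pieces, paste(sample(BASES, trail, replace = TRUE),
                              collapse = ""))
  }
  list(pos = start, cigar = paste0(len, op, collapse = ""),
       seq = paste(pieces, collapse = ""),
       mapq = sample(0:60, 1L))
}

#' Simulate aligned reads
#'
#' Emits `n_reads` SAM records against the given reference: mapped reads
#' start uniformly along the genome (chromosomes weighted by length) and are
#' mutated at the configured per-base rates with CIGAR, FLAG and MAPQ set
#' consistently; `round(n_reads * unmapped_fraction)` reads are unmapped
#' (FLAG 0x4, `rname` `*`, random sequence). QUAL is the constant `I`.
#'
#' @param reference `DNAStringSet` or FASTA path (from [make_reference()]).
#' @param params [sim_params()]; every chromosome must be at least twice the
#'   read length.
#' @param path Optional output SAM path.
#' @return A `list(header, records)` as from [read_sam()]; written to `path`
#'   when given.
#' @export
simulate_reads <- function(reference, params, path = NULL) {
  ref <- read_reference(reference)
  if (min(Biostrings::width(ref)) < 2L * params$read_length) {
    stop("every chromosome must be at least twice the read length",
         call. = FALSE)
  }
  chroms <- names(ref)
  widths <- Biostrings::width(ref)
  refstrs <- as.character(ref)

  sam <- with_substream(params, 1L, {
    n <- params$n_reads
    n_un <- round(n * params$unmapped_fraction)
    is_unmapped <- sample(rep(c(FALSE, TRUE), c(n - n_un, n_un)))
    flag <- integer(n); rname <- character(n); pos <- integer(n)
    mapq <- integer(n); cigar <- character(n); sq <- character(n)
    for (k in seq_len(n)) {
      if (is_unmapped[[k]]) {
        flag[[k]] <- 4L; rname[[k]] <- "*"; pos[[k]] <- 0L
        mapq[[k]] <- 0L; cigar[[k]] <- "*"
        sq[[k]] <- paste(sample(BASES, params$read_length, replace = TRUE),
                         collapse = "")
      } else {
        ci <- sample.int(length(chroms), 1L, prob = widths)
        rd <- sim_mapped_read(refstrs[[ci]], params, widths[[ci]])
        flag[[k]] <- 0L; rname[[k]] <- chroms[[ci]]; pos[[k]] <- rd$pos
        mapq[[k]] <- rd$mapq; cigar[[k]] <- rd$cigar; sq[[k]] <- rd$seq
      }
    }
    list(
      header = c("@HD\tVN:1.6\tSO:unknown",
                 paste0("@SQ\tSN:", chroms, "\tLN:", widths)),
      records = data.frame(
        qname = sprintf("read%06d", seq_len(n)), flag = flag, rname = rname,
        pos = pos, mapq = mapq, cigar = cigar, rnext = "*", pnext = 0L,
        tlen = 0L, seq = sq, qual = strrep("I", nchar(sq)), tags = "",
        stringsAsFactors = FALSE)
    )
  })
  if (!is.null(path)) write_sam(sam$header, sam$records, path)
  sam
}

#' Simulate a single-sample VCF
#'
#' Draws `n_variants` variants at distinct positions: a mixture of SNPs
#' (70%), small indels (20%) and symbolic structural-variant alleles (10%,
#' `<DEL>` with `SVTYPE`/`END` INFO). REF alleles are taken from the
#' reference; genotypes are `0/1` with probability `het_fraction`, else
#' `1/1`; a `rsid_fraction` share of variants get `rs<k>` identifiers.
#'
#' @inheritParams simulate_reads
#' @param path Optional output VCF path.
#' @return A `list(header, lines)` of verbatim VCF text; written to `path`
#'   when given.
#' @export
simulate_vcf <- function(reference, params, path = NULL) {
  ref <- read_reference(reference)
  chroms <- names(ref)
  widths <- Biostrings::width(ref)
  if (params$n_variants > sum(widths - 20L)) {
    stop("n_variants exceeds available positions", call. = FALSE)
  }
  vcf <- with_substream(params, 2L, {
    nv <- params$n_variants
    ci <- sample(seq_along(chroms), nv, replace = TRUE, prob = widths)
    pos <- integer(nv)
    for (i in seq_along(chroms)) {
      sel <- which(ci == i)
      if (length(sel)) {
        pos[sel] <- sample.int(widths[[i]] - 20L, length(sel))
      }
    }
    o <- order(ci, pos)
    ci <- ci[o]; pos <- pos[o]
    kind <- sample(c("snp", "indel", "sv"), nv, replace = TRUE,
                   prob = c(0.7, 0.2, 0.1))
    lines <- character(nv)
    rs_k <- 0L
    for (v in seq_len(nv)) {
      cn <- chroms[[ci[[v]]]]
      p <- pos[[v]]
      base <- as.character(Biostrings::subseq(ref[[cn]], p, p))
      info <- "."
      if (kind[[v]] == "snp") {
        refa <- base
        alta <- sample(setdiff(BASES, base), 1L)
      } else if (kind[[v]] == "indel") {
        if (stats::runif(1) < 0.5) {            # insertion
          refa <- base
          alta <- paste0(base, paste(sample(BASES, geom_len(6L),
                                            replace = TRUE), collapse = ""))
        } else {                                # deletion
          L <- geom_len(6L)
          refa <- as.character(Biostrings::subseq(ref[[cn]], p, p + L))
          alta <- base
        }
      } else {                                  # symbolic SV
        L <- sample(50:5000, 1L)
        refa <- base
        alta <- "<DEL>"
        info <- paste0("SVTYPE=DEL;END=", min(p + L, widths[[ci[[v]]]]))
      }
      gt <- if (stats::runif(1) < params$het_fraction) "0/1" else "1/1"
      rsid <- if (stats::runif(1) < params$rsid_fraction) {
        rs_k <- rs_k + 1L
        paste0("rs", 100000L + rs_k)
      } else "."
      lines[[v]] <- paste(cn, p, rsid, refa, alta,
                          sample(20:99, 1L), "PASS", info, "GT", gt,
                          sep = "\t")
    }
    header <- c(
      "##fileformat=VCFv4.2",
      "##source=genochain-simulator",
      paste0("##contig=<ID=", chroms, ",length=", widths, ">"),
      "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
      "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE1"
    )
    list(header = header, lines = lines)
  })
  if (!is.null(path)) writeLines(c(vcf$header, vcf$lines), path)
  vcf
}
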