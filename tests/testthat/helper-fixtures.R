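# Fixture builders shared across test files. Everything is generated in code
# at test time; nothing is read from disk except what the tests themselves
# write to tempdirs.

new_chain_dir <- function(env = parent.frame()) {
  file.path(withr::local_tempdir(.local_envir = env), "chain")
}

# a hand-rolled SAM record with sensible defaults
sam_rec <- function(qname = "r1", flag = 0L, rname = "chrA", pos = 1L,
                    mapq = 30L, cigar = "10M", rnext = "*", pnext = 0L,
                    tlen = 0L, seq = strrep("A", 10L), qual = NULL,
                    tags = "") {
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = mapq, cigar = cigar, rnext = rnext, pnext = pnext,
             tlen = tlen, seq = seq,
             qual = if (is.null(qual)) strrep("I", nchar(seq)) else qual,
             tags = tags, stringsAsFactors = FALSE)
}

sam_header_for <- function(ref) {
  c("@HD\tVN:1.6\tSO:unknown",
    paste0("@SQ\tSN:", names(ref), "\tLN:", Biostrings::width(ref)))
}

# a small simulated world: reference + reads + a built, populated chain
small_world <- function(env = parent.frame(), seed = 11L, n_reads = 300L,
                        chrom_len = 100000L, bin_length = 10000L,
                        read_length = 100L, ...) {
  params <- sim_params(seed = seed, chromosomes = c(chrA = chrom_len),
                       n_reads = n_reads, read_length = read_length, ...)
  ref <- make_reference(params)
  sam <- simulate_reads(ref, params)
  cfg <- chain_config(c(chrA = chrom_len), bin_length, read_length,
                      reference_id = ref)
  rc <- build_read_chain(new_chain_dir(env), cfg)
  report <- insert_alignments(rc, sam, ref)
  list(params = params, ref = ref, sam = sam, cfg = cfg, rc = rc,
       report = report)
}
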