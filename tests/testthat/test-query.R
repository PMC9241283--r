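# region analytics vs independent brute-force oracles

test_that("a region maps to its intersecting bins plus one upstream", {
  cfg <- chain_config(c(chr1 = 4000000L), 1000000L, 150L)
  expect_identical(streams_for(cfg, "chr1", 1, 50)$stream, "chr1stream1")
  expect_identical(streams_for(cfg, "chr1", 1000100, 1000200)$stream,
                   c("chr1stream1", "chr1stream2"))
  expect_identical(streams_for(cfg, "chr1", 2500000, 3200000)$stream,
                   c("chr1stream2", "chr1stream3", "chr1stream4"))
  expect_identical(streams_for(cfg, "chr1", 1000100, 1000200)$upstream,
                   c(TRUE, FALSE))
  expect_error(streams_for(cfg, "chr1", 0, 10), "invalid region")
  expect_error(streams_for(cfg, "chr1", 10, 4000001), "invalid region")
  expect_error(streams_for(cfg, "chrX", 1, 10), "not configured")
})

test_that("reads spanning a bin boundary are found from the downstream bin", {
  p <- sim_params(seed = 17L, chromosomes = c(chrA = 5000L), n_reads = 1L,
                  read_length = 100L, mismatch_rate = 0, insertion_rate = 0,
                  deletion_rate = 0, softclip_rate = 0, unmapped_fraction = 0)
  ref <- make_reference(p)
  cfg <- chain_config(c(chrA = 5000L), 1000L, 100L, reference_id = ref)
  rc <- build_read_chain(new_chain_dir(), cfg)
  refstr <- as.character(ref[[1]])
  rec <- sam_rec("straddler", 0L, "chrA", 950L, cigar = "100M",
                 seq = substr(refstr, 950, 1049))
  insert_alignments(rc, list(header = character(0), records = rec), ref)
  # stored once, in the bin of its start, keyed FLANK=1
  expect_identical(nrow(list_stream_key_items(rc$store, "chrAstream1",
                                              "FLANK=1")), 1L)
  expect_identical(nrow(list_stream_items(rc$store, "chrAstream2")), 0L)
  # a query confined to bin 2 still returns it
  got <- query_reads(rc, "chrA", 1010, 1020, ref)
  expect_identical(got$qname, "straddler")
  expect_identical(got$seq, substr(refstr, 950, 1049))
  # and an empty region stays empty
  expect_identical(nrow(query_reads(rc, "chrA", 3000, 3100, ref)), 0L)
})

test_that("deletions contribute zero depth at the deleted positions", {
  p <- sim_params(seed = 17L, chromosomes = c(chrA = 5000L))
  ref <- make_reference(p)
  refstr <- as.character(ref[[1]])
  cfg <- chain_config(c(chrA = 5000L), 1000L, 100L, reference_id = ref)
  rc <- build_read_chain(new_chain_dir(), cfg)
  seq8 <- paste0(substr(refstr, 1, 4), substr(refstr, 7, 10))
  rec <- sam_rec("del1", 0L, "chrA", 1L, cigar = "4M2D4M", seq = seq8)
  insert_alignments(rc, list(header = character(0), records = rec), ref)
  d <- query_depth(rc, "chrA", 1, 10)
  expect_identical(unname(d), c(1L, 1L, 1L, 1L, 0L, 0L, 1L, 1L, 1L, 1L))
  # the pileup shows the deletion marker but keeps depth consistent
  pu <- pileup(rc, "chrA", 1, 10, ref)
  expect_identical(pu$pos, 1:10)
  expect_identical(pu$depth, c(1L, 1L, 1L, 1L, 0L, 0L, 1L, 1L, 1L, 1L))
  expect_identical(pu$bases[5:6], c("*", "*"))
})

test_that("a pileup column shows each read's observed base over the reference allele", {
  p <- sim_params(seed = 23L, chromosomes = c(chrA = 5000L))
  ref <- make_reference(p)
  refstr <- as.character(ref[[1]])
  cfg <- chain_config(c(chrA = 5000L), 1000L, 100L, reference_id = ref)
  rc <- build_read_chain(new_chain_dir(), cfg)
  refbase <- substr(refstr, 105, 105)
  alt <- setdiff(c("A", "C", "G", "T"), refbase)[[1]]
  snp_seq <- substr(refstr, 101, 110)
  substr(snp_seq, 5, 5) <- alt
  recs <- rbind(
    sam_rec("wt", 0L, "chrA", 101L, seq = substr(refstr, 101, 110)),
    sam_rec("mut", 0L, "chrA", 101L, seq = snp_seq)
  )
  insert_alignments(rc, list(header = character(0), records = recs), ref)
  pu <- pileup(rc, "chrA", 105, 105, ref)
  expect_identical(pu$depth, 2L)
  expect_identical(pu$ref_base, refbase)
  expect_identical(pu$bases, paste0(refbase, alt))   # publication order
})

test_that("query_reads, query_depth and pileup agree with brute-force scans over random regions", {
  w <- small_world(seed = 47L, n_reads = 1000L, chrom_len = 100000L,
                   bin_length = 5000L, unmapped_fraction = 0.02)
  rc <- w$rc; recs <- w$sam$records
  refstr <- as.character(w$ref[[1]])
  set.seed(101)
  n_regions <- 40L
  starts <- sample.int(100000L - 600L, n_regions)
  widths <- sample(c(0L, 0L, 50L, 300L, 600L), n_regions, replace = TRUE)
  # force several bin-boundary straddlers and a chromosome-start region
  starts[1:4] <- c(4990L, 9950L, 14999L, 1L)
  widths[1:4] <- c(40L, 200L, 2L, 100L)
  for (i in seq_len(n_regions)) {
    s <- starts[[i]]; e <- s + widths[[i]]
    mq <- if (i %% 3L == 0L) 30L else NULL

    got <- query_reads(rc, "chrA", s, e, w$ref, min_mapq = mq)
    want <- oracle_overlaps(recs, "chrA", s, e, min_mapq = mq)
    expect_setequal(paste(got$qname, got$pos), paste(want$qname, want$pos))
    # regenerated sequences equal the originals
    m <- match(got$qname, want$qname)
    expect_identical(got$seq, want$seq[m])

    expect_identical(query_depth(rc, "chrA", s, e, min_mapq = mq),
                     oracle_depth(recs, "chrA", s, e, min_mapq = mq))

    pu <- pileup(rc, "chrA", s, e, w$ref, min_mapq = mq)
    want_pu <- oracle_pileup(recs, refstr, "chrA", s, e, min_mapq = mq)
    expect_identical(pu$pos, want_pu$pos)
    expect_identical(pu$ref_base, want_pu$ref_base)
    expect_identical(pu$depth, want_pu$depth)
    expect_identical(vapply(strsplit(pu$bases, ""),
                            function(b) paste(sort(b), collapse = ""), ""),
                     want_pu$bases)
  }
})

test_that("queries touch only the streams their bins dictate", {
  w <- small_world(seed = 53L, n_reads = 200L, chrom_len = 100000L,
                   bin_length = 10000L)
  rc <- w$rc
  allowed <- streams_for(w$cfg, "chrA", 34000, 36000)$stream
  chain_read_log(rc$store, TRUE)
  query_depth(rc, "chrA", 34000, 36000)
  touched <- unique(rc$store$read_log)
  chain_read_log(rc$store, FALSE)
  expect_true(all(touched %in% allowed))
})

test_that("total depth over the chromosome equals the aligned-base mass of stored reads", {
  w <- small_world(seed = 59L, n_reads = 150L, chrom_len = 20000L,
                   bin_length = 2000L, unmapped_fraction = 0.05)
  total_depth <- sum(query_depth(w$rc, "chrA", 1, 20000))
  mapped <- oracle_mapped(w$sam$records, "chrA")
  aligned_mass <- sum(vapply(mapped$cigar, function(cg) {
    s <- 0L
    for (o in oracle_cigar_ops(cg)) if (o$op %in% c("M", "=", "X")) s <- s + o$len
    s
  }, 0L))
  expect_identical(total_depth, as.integer(aligned_mass))
})

test_that("a rebuilt alignment file reproduces the input except QUAL", {
  w <- small_world(seed = 61L, n_reads = 400L, unmapped_fraction = 0.03)
  out <- file.path(withr::local_tempdir(), "rebuilt.sam")
  build_alignment_file(w$rc, w$ref, out)
  back <- read_sam(out)

  expect_identical(back$header, w$sam$header)   # byte-for-byte
  expect_identical(nrow(back$records), nrow(w$sam$records))

  a <- w$sam$records[order(w$sam$records$qname), ]
  b <- back$records[order(back$records$qname), ]
  for (col in c("qname", "flag", "rname", "pos", "mapq", "rnext",
                "pnext", "tlen", "seq", "tags")) {
    expect_identical(b[[col]], a[[col]])
  }
  # CIGARs stored normalized ("="/"X" folded into M); simulated input is
  # already in normalized form, so they round-trip identically here
  expect_identical(b$cigar, a$cigar)
  expect_true(all(b$qual == "*"))

  # coordinate sorted, unmapped last
  mapped_rows <- back$records$flag != 4L
  expect_false(is.unsorted(back$records$pos[mapped_rows]))
  expect_true(all(which(!mapped_rows) > max(which(mapped_rows))))

  # BAM output is readable by standard tooling
  bam <- file.path(withr::local_tempdir(), "rebuilt.bam")
  build_alignment_file(w$rc, w$ref, bam)
  cnt <- Rsamtools::countBam(bam)
  expect_identical(cnt$records, nrow(w$sam$records))
})
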