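Package: genochain
Title: Blockchain-Style Storage and On-Chain Analysis of Genomic Reads and Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stores reference-aligned sequencing reads (SAM/BAM) and genetic
    variants (VCF) inside append-only, hash-chained key:value data streams, the
    way a private blockchain platform with data streams would, and analyses them
    on-chain. Reads are compressed against a reference genome by keeping only
    the bases that differ (a CRAM-style difference field called the modcigar)
    and are filed into streams binned by genomic position, with a FLANK key
    marking reads that spill into the next bin, so region queries touch only
    the relevant bins. Provides read queries, CIGAR-aware depth, pileup, and
    full alignment-file reconstruction, plus a single-stream variant chain with
    conjunctive position/genotype/rsID queries, chain integrity verification
    against tampering, permissioned publishing, resumable insertion after
    storage errors, and a deterministic synthetic FASTA/SAM/VCF generator for
    self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    jsonlite,
    Biostrings,
    Rsamtools
Suggests:
    GenomicAlignments,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
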