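# genochain

Blockchain-style storage and on-chain analysis of genomic reads and variants.

## The problem

Whoever holds a personal genome — the aligned read stack (SAM/BAM) and the
variant calls (VCF) — needs storage that is tamper-evident, access-controlled,
and still *queryable*: a clinician should be able to ask for the reads or the
sequencing depth over a locus without downloading and re-indexing the whole
file. Append-only, hash-chained key:value data streams (the data model of
private blockchain platforms) give integrity and permissioned, timestamped
access, but they are a terrible fit for raw reads if used naively: a read is
an *interval* on the reference, and a flat key:value stream cannot answer
range queries, while storing full sequences and quality strings on a
replicated ledger is prohibitively large.

`genochain` addresses both obstacles with two ideas on top of a
self-contained, file-backed stream store that emulates those blockchain
stream semantics (publish/retrieve-by-key/blocks) in a single process:

1. **Reference-based compression (the modcigar).** A mapped read's sequence
   is replaced by the *difference* between the read and the reference — the
   CRAM idea, rendered in plain text. A modcigar is a `;`-joined list of
   tokens `<query-offset><op><bases>` with ops `X` (mismatch run), `I`
   (insertion) and `S` (soft clip); `12XA;45IACG` means "an `A` replacing the
   reference base at 0-based read offset 12, and `ACG` inserted at offset
   45". An empty modcigar means the read matches the reference exactly.
   Reference + CIGAR + modcigar reconstruct the sequence losslessly; quality
   strings are deliberately discarded. On typical short-read data this at
   least halves the plaintext record size.

2. **Position-binned streams.** A read chain holds one stream per
   fixed-length genomic interval (`<chrom>stream<j>`, bin *j* covering
   `[(j-1)·B + 1, j·B]` for bin length *B* — a 248,956,422 bp chromosome at
   1 Mbp bins gets ⌈248,956,422/10⁶⌉ = 249 streams). A read is filed in the
   bin of its start position, keyed `FLANK=1` if its alignment spills into
   the next bin. A region query therefore touches only the intersecting bins
   plus one bin upstream — never the rest of the chain. Two further streams
   hold the verbatim SAM header plus chain settings (`metaData`) and
   unmapped/unplaced reads with their sequences intact
   (`unmappedANDcontigs`).

On this layout the package computes, directly from chain data: region read
queries (sequences regenerated on the fly), CIGAR-aware per-position depth
(a deletion in a read contributes 0 at the deleted positions), mpileup-like
pileup columns, and full coordinate-sorted SAM/BAM reconstruction. A variant
chain stores a single-sample VCF in one `allVariantData` stream keyed by
`POS:<chrom>:<pos>`, `GT:<genotype>` and `ID:<rsid>`, answering conjunctive
(AND) queries. Every publication is a transaction; blocks seal every *n*
transactions and link by SHA-256; `verify_chain()` recomputes every digest
from the persisted bytes, so any single-byte tamper of stored payloads or
block metadata is detected and localized to its block. Permissions
(read/write/admin per identity) are themselves on-chain, timestamped items.

A deterministic synthetic-data module (`sim_params()`, `make_reference()`,
`simulate_reads()`, `simulate_vcf()`) generates FASTA/SAM/VCF fixtures so
everything above is testable offline.

## Worked example

```r
library(genochain)

params <- sim_params(seed = 42, chromosomes = c(chr1 = 2000000L), n_reads = 5000)
ref <- make_reference(params)
sam <- simulate_reads(ref, params)

cfg <- chain_config(c(chr1 = 2000000L), bin_length = 100000L,
                    read_length = 150L, reference_id = ref)
rc <- build_read_chain("demo_chain", cfg)
insert_alignments(rc, sam, ref)
#> inserted 5000 records (4900 mapped, 100 unmapped/contig, 5 FLANK=1) + 2 header lines

verify_chain(rc$store)
#> chain OK: 5029 items in 7 blocks, all digests verified

query_reads(rc, "chr1", 999900, 1000100, ref)[, c("qname", "pos", "mapq", "cigar")]
#>        qname    pos mapq    cigar
#> 1 read000749 999999   14 7M1D143M

query_depth(rc, "chr1", 1000003, 1000009)
#> 1000003 1000004 1000005 1000006 1000007 1000008 1000009
#>       1       1       1       0       1       1       1

pileup(rc, "chr1", 1000004, 1000008, ref)
#>   chrom     pos ref_base depth bases
#> 1  chr1 1000004        G     1     G
#> 2  chr1 1000005        G     1     G
#> 3  chr1 1000006        G     0     *
#> 4  chr1 1000007        A     1     A
#> 5  chr1 1000008        C     1     C
```

The insertion report says how reads were routed: 4,900 mapped reads into the
20 binned streams, 100 unmapped reads into `unmappedANDcontigs`, 5 reads
whose alignment crosses a 100 kb bin boundary (`FLANK=1`). The one read
overlapping `chr1:999900-1000100` carries a 1 bp deletion (`7M1D143M`)
starting at position 999,999: depth drops to 0 at the deleted base
1,000,006, and the pileup renders that read as the `*` deletion marker there
while the flanking columns show its (reference-matching) bases. Its sequence
column (not shown) was regenerated from the reference and the on-chain
modcigar — no sequence was stored. `build_alignment_file(rc, ref,
"out.bam")` reconstructs the whole file, identical to the input in every
field except QUAL (`*`).

A command-line wrapper with the same operations (plus variant chains,
grants, and fixture generation) ships at
`system.file("cli", "genochain.R", package = "genochain")`.

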