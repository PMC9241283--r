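---
title: "Methods: chain design, reference-difference encoding, and on-chain analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chain design, reference-difference encoding, and on-chain analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genochain)
```

This vignette is the package's own account of how it works: the data model
of the chain store, the reference-difference encoding of reads, the binned
indexing that makes region queries cheap, the analytics computed on-chain,
what the synthetic-data generator does and does not emulate, and the
numerical and design choices made where the design was genuinely open.

## 1. The chain store

A chain is a directory holding three text artifacts: a self-describing
header (`chain.json`: chain name, hash algorithm, block size), an
append-only item log (`items.log`, one line per published item: counter,
transaction id, stream, publisher, blocktime, keys, hex-encoded payload) and
a block log (`blocks.log`: height, timestamp, previous hash, own hash,
sealed transaction ids). Everything else — the stream registry, per-key
index, effective permissions — is derived data rebuilt by replaying the logs
on open, and deliberately outside the integrity surface.

**Items and transactions.** An item has a publisher identity, zero or more
retrieval keys (each 1–256 printable ASCII characters, with whitespace and
single/double quotes excluded — key strings appear verbatim in log lines and
query interfaces, so shell- and quoting-hostile characters are kept out of
the alphabet by contract), and an opaque payload. Its transaction id is

```
txid = SHA-256(stream ␟ publisher ␟ sorted(keys) ␟ counter ␟ payload-bytes)
```

The chain-wide monotonic counter makes txids unique even for byte-identical
payloads, and — because wall-clock time is *not* part of the digest — makes
insertion deterministic: inserting the same file into two fresh chains
yields identical txid sequences, which the tests rely on. The blocktime
recorded next to each item is operational metadata outside the digest, the
one persisted field whose mutation verification cannot see.

**Blocks.** Pending transactions are sealed into a block every `block_size`
publications (default 1,000) or on an explicit `mine_pending()`. This
*logical* sealing replaces the 15-second target-block-time a wall-clock
blockchain node would use; it keeps tests deterministic while preserving the
structure that matters — batching, hash linkage, confirmations. A block's
digest covers its height, timestamp, transaction list and the previous
block's digest; the genesis predecessor is the all-zero digest. An item's
confirmation count is computed at read time as (number of blocks) − (its
block's height), 0 while pending — nothing is rewritten when new blocks
seal.

**Verification.** `verify_chain()` re-reads both logs from disk and
recomputes every txid from stored bytes, every block digest, every
prev-hash link, and the resolution of every sealed txid to a logged item.
A flipped byte in a payload changes the recomputed txid, which invalidates
the block carrying that transaction; the report names the earliest bad
height. Corruption is reported, never raised.

**Permissions.** Identities play roles (`read`, `write`, `admin`); grants
and revocations are themselves items in a reserved `_permissions` stream, so
every access change is timestamped on-chain, and the effective permission is
the latest record per (identity, role). "Nodes" (owner, sequencer,
clinician) are modelled as identities with permissions, not processes:
networking, consensus among miners, and wallets are out of scope. One
process, one directory, one chain.

## 2. The modcigar: reference-difference encoding

A mapped read is stored without its sequence and quality string. What is
kept is the CIGAR (which the aligner already produced) and a *modcigar*:
the ordered list of places where the read differs from the reference,
serialized as `<0-based query offset><op><bases>` tokens joined by `;`,
with ops

- `X` — one contiguous run of mismatching bases inside an aligned (M/`=`/X)
  segment, carrying the read's bases;
- `I` — the bases of one insertion segment;
- `S` — the bases of one soft-clip segment (soft-clipped bases are absent
  from the reference, so every `S` CIGAR segment must carry a token).

The grammar is original to this package (one token per contiguous differing
run; offsets strictly increasing; serialization canonical, so parse ∘
serialize is the identity). Decoding walks the CIGAR over the reference
window, copies reference bases for aligned positions, overwrites mismatch
runs, splices insertions and clips, and skips deleted/skipped (D/N)
reference bases; it validates that every I/S segment receives exactly one
token of exactly its length and that X tokens fall inside aligned segments.
`decode(encode(read))` is the identity on every read the property tests
generate, across mismatch/indel/soft-clip rates from 0 to saturation and
read lengths down to 1.

Choices worth recording:

- **Both mismatches and insertions are recorded.** Without mismatch tokens
  the sequence could not be reconstructed; minimality is preserved because
  a read matching the reference over all aligned segments encodes to the
  empty string.
- **Case and ambiguity.** Sequences are uppercased before comparison (a
  case-only difference is not a mismatch); `N` versus a non-`N` base *is* a
  mismatch, so reconstruction reproduces `N`s faithfully.
- **CIGAR normalization.** `=`/`X` ops are accepted on input and folded into
  `M` for storage (the modcigar carries the mismatch information); hard
  clips carry no bases anywhere.
- **Quality strings are discarded irrecoverably.** Reconstruction emits the
  SAM missing-quality sentinel `*`. This is the main loss the storage
  reduction buys; round-trip equivalence is therefore defined as "every
  field except QUAL".

## 3. Read chains: binned streams and FLANK

`chain_config()` fixes the chromosome table, the bin length *B* and the
declared maximum read length *R*, with the invariant **B ≥ R**: a read's
alignment can then span at most two consecutive bins, so a single boolean
key per read suffices. Bin *j* of a chromosome covers the closed interval
`[(j−1)·B + 1, j·B]`; a chromosome of length L has ⌈L/B⌉ bins (249 for a
248,956,422 bp chromosome at B = 1 Mbp). Reads are filed by start
coordinate; the key is `FLANK=1` exactly when the read's reference end (per
CIGAR reference span) lies in the next interval, `FLANK=0` otherwise. A read
that would span three or more bins is a hard error — by the config invariant
it cannot occur for well-formed input.

Routing at insertion: a record goes to `unmappedANDcontigs` if its unmapped
FLAG bit (0x4) is set, its reference name is `*`, **or** its reference name
is not in the configured chromosome table (the practical reading of
"unmapped reads and contigs"); its sequence is kept verbatim so it can be
realigned later. Everything else is encoded and binned. Secondary and
supplementary alignments are stored like primary ones; duplicates are not
collapsed. Header lines go to `metaData` line-by-line in order, so their
concatenation is byte-identical to the input header; the serialized
configuration and payload-grammar version are also `metaData` items.

The on-chain payload is tab-separated plain text: the nine mandatory
non-sequence SAM fields, then the modcigar (binned streams) or the verbatim
sequence (`unmappedANDcontigs`), then any optional SAM tags verbatim. Tags
are kept because dropping them would make the rebuild lossy in a way users
would notice (read groups, NM/MD, etc.) at negligible storage cost.

**Storage probing and resumability.** During insertion the free space of
the filesystem holding the chain is probed every 1,000 records (pluggable
probe; the default shells out to `df`). When it falls under the threshold
the pending block is sealed, a checkpoint — the ordinal of the last fully
inserted unit (header lines count as units) — is persisted next to the
logs, and a classed `genochain_storage_error` is raised carrying the resume
point. Re-running with `resume = TRUE` skips exactly the already-inserted
ordinals; because txids are deterministic, the resumed chain is
stream-for-stream identical to an uninterrupted insertion, which the
acceptance tests check item by item. An insert interrupted by anything
*other* than the storage probe (a crash, a kill) leaves no checkpoint and is
not resumable — rebuilding is the honest option there.

## 4. On-chain analytics

Every region query first computes `streams_for()`: the bins intersecting
`[start, end]` plus the single bin immediately upstream of the first (when
it exists), because a `FLANK=1` read starting there can reach into the
region. The upstream bin is read *only* through its `FLANK=1` key index —
by the two-bin invariant no `FLANK=0` read there can touch the region.
Candidates are then filtered by true closed-interval overlap (a read whose
end equals the query start overlaps; ends are computed from the CIGAR
reference span). The instrumented store (`chain_read_log()`) lets tests
assert that nothing outside `streams_for()` is ever touched, which is the
whole point of the binned layout: query cost scales with the queried bins'
contents, not the chain size.

- `query_reads()` returns the matching records with sequences regenerated
  (reference + CIGAR + modcigar); QUAL is `*`.
- `query_depth()` needs no reference: depth at a position counts reads whose
  CIGAR places a query base there (M/`=`/X). Deletions and skips contribute
  0 at their positions; insertions, clips and padding never cover a
  reference position. The MAPQ filter is inclusive (`mapq ≥ threshold`).
- `pileup()` emits one column per position with at least one aligned *or
  deleted* read: chromosome, position, reference base, depth, and the
  per-read observed bases in stream publication order, with `*` marking
  reads deleted at that position. Deletion markers are shown but excluded
  from depth, keeping `pileup` and `query_depth` consistent by
  construction.
- `build_alignment_file()` rebuilds the whole file: verbatim header,
  every binned record decoded, every unmapped record verbatim,
  coordinate-sorted with unmapped records last (what downstream tools
  expect from a sorted file), written as SAM or converted to BAM.

All three query operations are tested for exact agreement with brute-force
oracles that operate on the original input (an independent
character-by-character CIGAR walker over the original SAM records), over
randomized point and range queries including bin-boundary straddlers.

## 5. Variant chains

A variant chain is two streams: `metaData` (verbatim VCF header lines) and
`allVariantData` (one item per data line, payload verbatim). Variants are
point positions, so no binning is needed — the per-key index suffices, in
deliberate contrast to the read chain. Keys are `POS:<chrom>:<pos>`,
`GT:<genotype>` and `ID:<rsid>` (omitted for `.`). `query_variants()`
fetches by the POS key and applies genotype/rsID filters conjunctively.

Open points resolved here: repeated positions are *allowed* and all matches
returned (real VCFs repeat positions; files with unique positions behave as
a dictionary would). Genotype keys are verbatim, so `0/1` and `0|1` are
distinct and phasing is preserved; `normalize_phase = TRUE` folds the
separators at query time. Input is restricted to single-sample VCFs — the
use case is one personal genome, and a multi-sample file almost certainly
indicates the wrong input — and a malformed data line is skipped with its
line number reported while insertion continues, since one bad line should
not cost an hours-long insertion.

## 6. The synthetic-data generator

The generator exists so that every layer above is testable with no
downloads; its defaults are the package's study conditions: one 2 Mbp
chromosome, 10,000 reads of 150 bp, 1% per-base mismatches, 0.1%
insertions, 0.1% deletions, 1% soft-clip incidence, 2% unmapped reads;
1,000 variants (70% SNPs, 20% small indels, 10% symbolic `<DEL>` SVs,
matching the mix of variant classes a whole-genome personal VCF contains),
60% heterozygous, half carrying rsIDs. The 2 Mbp scale mirrors a
disease-locus-sized excerpt of a genome per chromosome and keeps the full
suite in the minutes range; all rates are parameters, not constants.

Determinism: each artifact (reference, reads, VCF) draws from its own
substream — a fixed offset from the user seed, with the RNG state restored
afterwards — so the same parameters give byte-identical files regardless of
generation order, and regenerating one artifact never perturbs another.
Mutations are applied per aligned base independently; indel lengths are
geometric with mean 2, capped at a quarter of the read length; reads always
begin and end with an aligned base (indels sit between aligned bases), so
generated CIGARs are well-formed by construction. QUAL is a constant
character, making its deliberate loss visible in round-trip diffs as the
only differing field.

What the generator does *not* emulate — position-dependent error profiles,
quality models, coverage biases, paired-end structure, reverse-strand
flags — bounds what green tests prove: correctness of storage, indexing,
reconstruction and query semantics on well-formed alignments, not
robustness to every artifact of real sequencers or aligners. Real BAM/VCF
input is handled through the same standard-format readers, but the
adversarial corners of real data (chimeric alignments, malformed tags,
exotic CIGAR combinations) are only covered to the extent the grammar above
covers them.

## 7. Numerical and degenerate-input choices

- Coordinates are 1-based inclusive everywhere (SAM convention); bin
  intervals and query regions are closed on both ends.
- The reference identifier stored in a chain digests names, lengths *and
  sequence content*, so a different genome with the same layout is refused
  at insert and query time.
- Queries against an empty region return empty frames, not errors; a
  never-used key returns an empty result; a no-match variant query is
  empty. Invalid regions (start < 1, end < start, end beyond the
  chromosome) are errors.
- Reads of length 1, empty modcigars, streams with zero items, and chains
  with zero blocks are all exercised by tests.
- Problem sizes in the test suite: the round-trip and storage checks run at
  the full 10,000-read study size; query-oracle equivalence runs on 1,000
  reads × 100 regions; integrity fuzzing flips 100 single bytes; these keep
  the suite at a few minutes on one CPU while testing the sizes the
  package's claims are stated at.

## 8. Known limitations

- Single process, single directory: no networking, consensus, mining
  diversity or wallets; immutability rests on digest verification, not on
  distributed replication.
- Quality strings are unrecoverable by design; tools that need QUAL must
  keep the original file.
- The wall-clock sealing mode of real platforms is reduced to logical
  batch sealing (plus explicit sealing); block timestamps are recorded but
  carry no consensus meaning.
- The modcigar wire format is this package's own; it is self-describing
  and versioned in `metaData`, but not bit-compatible with any external
  platform's storage.
- Multi-sample VCFs and non-positional read keys (query by name, by MAPQ
  bin) are out of scope; MAPQ participates as a filter, not an index.
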