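---
title: "BloomAlign: methods and design notes"
author: "BloomAlign authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BloomAlign: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BloomAlign)
```

# The problem

Aligning reads against a very large, or very fragmented, reference is
dominated by the cost of building and holding the reference index.  When the
reference is a draft assembly of millions of contigs, a single monolithic
index may not fit in memory at all.  BloomAlign splits the work: the target
set is partitioned into `P` balanced subsets, each subset is indexed and
aligned independently, and the partial SAM outputs are merged.  The crux is
that a read only needs to visit the partitions that could possibly align it
— and a Bloom filter over each partition's substring content answers exactly
that question with one-sided error.

The pipeline has five stages, all exposed individually and combined by
`runPipeline()`:

1. **distribute** — `planPartitions()`: balanced partitioning of targets,
   keeping assembly-graph-connected contigs together;
2. **index** — `buildFilter()`: one Bloom filter of canonical b-mers per
   partition (plus whatever index the per-partition aligner builds);
3. **dispatch** — `dispatchReads()`: route each read to every partition
   whose filter hits at least one of its b-mers; discard reads with no hit;
4. **align** — `alignPartition()`: per-partition alignment with a pluggable
   aligner (built-in exact-match mapper, or an external tool via a command
   template);
5. **merge** — `mergeBest()` / `mergeMulti()`: per-read selection of the
   best-quality record (or up to N distinct records) across partitions.

# Bloom filter model

A filter is a bit array of `m` bits with `k` seeded hash functions.
Inserting a key sets its `k` hashed bits; a query reports present iff all
`k` bits are set, so an inserted key is never missed (no false negatives).
After `n` insertions with `r = m/n` bits per element the false-positive
rate is

$$F = \left(1 - \left(1 - \tfrac{1}{m}\right)^{kn}\right)^k
    \approx \left(1 - e^{-k/r}\right)^k,$$

minimised over real `k` at `k = r ln 2`, where it equals `(0.6185)^r`.
These identities are computed by `bloomFPR()` and checked in the test
suite; the defaults are `r = 8` bits per b-mer and `k = optimalK(8) = 5`
(the floor of `r ln 2` — flooring, not rounding, is what yields the
conventional 5 at `r = 8`), giving `F ≈ 2.17 %`:

```{r}
optimalK(8)
bloomFPR(8, 5)
round(bloomFPR(16, 16 * log(2))^(1 / 16), 4)
```

Two design details matter for correctness downstream:

* **Canonical b-mers.** Both at build and at query time a b-mer is replaced
  by the lexicographic minimum of itself and its reverse complement
  (`canonicalBmer()`), so reverse-strand matches are never missed.  Windows
  containing `N` are skipped on both sides: an undefined base cannot seed
  an exact match.
* **Double hashing.** The `k` positions come from two independent seeded
  64-bit hashes `g1, g2` as `(g1 + i·g2) mod m`.  This is the standard
  constant-cost construction and behaves like `k` independent hashes for
  the purposes of the FPR model; the suite verifies the empirical FPR of a
  built filter against the analytic value to within three binomial
  standard deviations at `n = 10^5`.

`m` is set to `r` times the number of *insert events* (valid b-mer
positions, duplicates included), not distinct b-mers.  That matches the
`n` in the FPR formula above and is conservative: duplicated insertions
only lower the realised FPR.

# Dispatch and the choice of b

A read is dispatched to every partition whose filter contains at least one
of the read's canonical b-mers (stride 1); a read with no hit anywhere is
discarded.  The guarantee is one-sided: if a read has an exact match of
length at least `b` to either strand of a partition's targets, that
partition is always in the dispatch set.  For the guarantee to cover every
alignment the downstream aligner could report, `b` must not exceed `l`,
the aligner's minimum seed or exact-match length; `chooseB()` enforces
`b ≤ l` and defaults to `b = l`.  The package default is `l = 20` (a value
within the typical seed range of short-read aligners; no single canonical
default exists across tools), hence `b = 20`.

False-positive hits are benign but not free.  A read of length `L` makes up
to `L − b + 1` queries per partition, so the probability that a *wrong*
partition receives the read is roughly `1 − (1 − F)^(L−b+1)` — at the
defaults (`F ≈ 0.0217`, 100 bp reads) most reads are dispatched to several
partitions, and the dispatch stage trims work rather than eliminating it.
Raising `r` (and `k`) or aligning longer reads sharpens the filter; the
merge stage makes the final output invariant to the extra copies either
way.  Per partition the scan early-exits at the first hit, which changes
runtime only, never the dispatch set.

# Partitioning

Balancing uses best-fit decreasing with a fixed number of bins and no
capacity: items are sorted by decreasing weight (ties by ID) and each goes
to the currently least-loaded partition (ties by lowest index).  The
classic description places each item in the bin with minimum sufficient
remaining space, which presupposes a bin capacity; with `P` fixed and no
meaningful capacity, least-loaded assignment is the natural reading and is
the standard LPT heuristic for multiway number partitioning, whose
makespan is within 4/3 of optimal — a bound the suite verifies against
exhaustive enumeration on instances of up to 8 items and 4 partitions.
All tie-breaks are fixed so plans are bit-reproducible.

When an adjacency graph is supplied (two-column TSV of target-ID pairs,
`#` comments allowed), its connected components become the atomic items,
weighted by summed member length, so linked contigs always share a
partition.  Components are never split, even when one exceeds the ideal
per-partition load; the planner only warns about the resulting imbalance.
Targets absent from the graph are singleton components; graph nodes absent
from the target set are an error, to fail loudly on inconsistent input
pairs.

# The built-in aligner

The built-in mapper (`exactMap()`) is intentionally minimal: an exact-match
seed-and-extend mapper in the spirit of exact-matching read mappers, not a
Smith–Waterman.  It indexes every l-mer of the partition's targets, seeds
every l-mer of the read in both orientations, extends each hit to the
maximal exact match on its diagonal, and reports the longest match with
soft-clipped flanks (`xS yM zS`), choosing on ties the leftmost offset in
the oriented read, then target input order, then smaller target position,
then the forward strand.  MAPQ is a two-valued convention — 60 when the
maximal match length is achieved at exactly one (target, position, strand),
0 otherwise — because true MAPQ semantics belong to whatever production
aligner is wrapped; the match length is reported as the `AS` tag so the
merger can rank equal-MAPQ records.  Soft clips (not hard clips) preserve
SEQ for the merger.  External aligners plug in through shell command
templates with `{target}`/`{reads}` placeholders (`externalAdapter()`;
presets for common tools are included but no binary is required
anywhere in the test suite, which uses a mock adapter instead).

# Merging

"Best quality" is interpreted as the lexicographic maximum of
(MAPQ, AS); neither SAM nor the dispatch model defines it more precisely,
and the AS tie-break lets score-reporting aligners disambiguate equal
MAPQs.  Remaining ties break deterministically (partition index, target
name, position, strand), so the merge is independent of stream arrival
order.  In best mode every read yields exactly one output record —
mapped, or flag-4 unmapped when nothing aligned (including reads discarded
at dispatch, whose IDs are carried through `discarded.txt` precisely so
the final SAM can account for them).  Multi mode emits up to N distinct
records — distinctness on (rname, pos, strand, CIGAR) — with flag 0x100 on
the non-primary ones.

One semantic gap is inherited from partitioned alignment itself: a read
repetitive *across* partitions can be reported unique (MAPQ 60) by each
partition's aligner, and the merge tie-break then picks one copy
arbitrarily (but deterministically).  `flagCrossPartitionTies = TRUE`
zeroes MAPQ in exactly that situation.  The default leaves records
untouched, which preserves equivalence with unpartitioned alignment
whenever reads are not repetitive across partition boundaries — and when a
graph keeps overlapping contigs co-partitioned, the repetitive copies land
in the same partition and the local aligner resolves them exactly as a
monolithic one would.

# The synthetic generator

The generator emulates the draft-assembly use case end to end: a uniform
i.i.d. random genome (`genGenome()`), fragmented into contigs at jittered
breakpoints (`fragmentGenome()`), with reads sampled length-weighted from
the contigs (`simulateReads()`).  Adjacent contigs share `overlap` bases
and are linked by an adjacency edge, mirroring assembler overlap graphs.
When an edge is withheld (`keepEdges < 1`, used to create several graph
components) the corresponding sequence overlap is dropped too, so distinct
components are sequence-independent — withholding only the edge would
leave hidden cross-component repeats that no graph-aware partitioner could
know about.  The degenerate setting `overlap = 0, keepEdges = 0` is the
unrelated-targets (static reference) scenario.

Defaults, chosen once to be representative and used throughout the tests:
genome 100 kb, 8 contigs, overlap 50 bp, 10^4 reads of 100 bp, substitution
rate 0.01, strands Bernoulli(0.5).  The overlap is deliberately smaller
than the read length so that a full-length error-free read always has a
unique best locus; the error model is substitutions-only because the
built-in aligner is exact-match (an indel would merely soft-clip the
shorter side, exercising nothing new).  The truth table (source contig,
0-based offset, strand, substitution count) makes dispatch recall and
mapping accuracy scorable with no external data.

What the generator does *not* model: realistic base composition or
repeats, indels, quality-score profiles, paired-end structure, coverage
biases.  Passing tests therefore demonstrate the correctness of the
partition/dispatch/align/merge logic — conservation, no-false-negative
dispatch, equivalence with unpartitioned alignment — not the behaviour of
production aligners on repetitive real genomes.

# Numerical and interface choices

* Coordinates are 0-based half-open internally; conversion to SAM's
  1-based happens only at serialisation.  Partition indices are 1-based
  throughout the R interface.
* Hashing is FNV-1a over bytes with a 64-bit avalanche finaliser; the two
  double-hashing base hashes come from one user seed, and all filters
  queried together must share that seed (enforced).
* `optimalK()` floors `r ln 2` and clamps at 1.
* Degenerate inputs: empty item lists give all-zero-load plans; `P`
  larger than the atomic item count leaves empty partitions (warning);
  targets shorter than `b` yield an empty filter (warning); reads shorter
  than `b` are discarded; empty partitions produce header-only SAMs.
* Everything is deterministic given (inputs, seed, P): fixed tie-breaks
  everywhere, RNG state isolated inside the generator functions.

# Problem sizes used by the automated checks

The suite runs entirely on generated data: FPR calibration with 10^5
inserted and 10^5 queried 20-mers; dispatch recall on the default 100 kb /
8-contig fixture with 10^4 error-free reads at P ∈ {2, 4, 8}; pipeline
equivalence against direct alignment with 5 × 10^3 reads (1 % substitution
errors) for P ∈ {1, 2, 4, 8}, in both the static and the graph-linked
scenario; partition quality against exhaustive optima on ≤ 8 items and
component atomicity over 10^3 random graphs.  These sizes keep the whole
suite in the order of a minute while leaving every estimate's sampling
error far below the tested tolerances.

# Known limitations

* MAPQ is never recalibrated across partitions (see the merge section);
  `flagCrossPartitionTies` is a flag, not a fix.
* No overlap-padding of partition boundaries is implemented: a read
  overhanging a contig end soft-clips exactly as it would against the
  unpartitioned contigs, but boundary effects inherent to fragmented
  references are not mitigated.
* The built-in aligner reports a single record per read and no gapped
  alignment; multi-record output requires an external aligner that emits
  several records per read.
* SAM text only; BAM/CRAM conversion and coordinate sorting are left to
  samtools downstream.
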