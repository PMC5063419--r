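---
title: "Methods: de novo 3' adapter prediction for small RNA reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: de novo 3' adapter prediction for small RNA reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adapterscout)
```

## The model

A small RNA sequencing read is, to first approximation, a short biological
insert (16–30 nt) followed by the 3′ adapter, read to a fixed cycle count.
The working assumption of this package is therefore that **the most
frequent k-mers in a read sample originate from the adapter**: every
adapter-bearing read contributes the same adapter prefix, while genomic
inserts are diverse. Prediction reduces to finding the set of k-mers that
(a) recur at near-identical, near-maximal frequency, and (b) chain into a
single sequence by suffix–prefix overlap.

The per-run pipeline is: count all k-mers over the first `sample_size`
reads (default 50,000, in file order — the head of a FASTQ is cheap to
stream and depth beyond this adds little signal); drop k-mers containing a
homopolymer run of length ≥ ⌊k/2⌋; drop k-mers whose frequency ratio
*r* = *f(S)*/*f(s)* against the most abundant survivor exceeds *R*;
assemble the survivors by exact (k−1)-overlap; score each assembly as the
summed member frequency divided by the **pre-filter** window total of the
run. Normalizing by the run's total window count — rather than by the
post-filter total — keeps scores on a common scale across different k and
R, which is what makes them summable in iterative mode.

### Why these assumptions can fail

Three library classes violate the model, and the package inherits the
corresponding limitations by design:

* **Adapter-dimer (ligation-product) libraries** — when most reads are 5′
  and 3′ adapters ligated without an insert, the most frequent k-mers span
  the 5′ adapter too, and frequency alone cannot separate the two. The
  synthetic generator can emulate this class (`dimer_fraction`) precisely
  so that the failure mode is testable, but no correction is attempted.
* **Long-insert libraries** — if the RNA fraction is longer than the read,
  few reads ever reach the adapter and there is nothing to count. Only the
  mapping-rate check of exhaustive mode can recognize this situation.
* **Homopolymeric adapters** — a poly(A) 3′ adapter is removed by the
  low-complexity filter itself; detecting such adapters would require
  distinguishing them from fragmented mRNA poly(A) tails, which frequency
  cannot do. Out of scope.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `k` | 9 | k-mer length. Long enough that random 9-mers rarely recur at depth 50,000; short enough that the adapter prefix of nearly every read contributes intact windows. |
| `R` | 1.4 | frequency-ratio cutoff (dimensionless, > 1). Adapter k-mers occur at close to the adapter frequency, so their mutual ratios stay near 1; 1.4 tolerates end-of-read attrition without admitting background. |
| iterative grid | {9, 11} × {1.2, 1.3, 1.4} | settings whose per-run scores are tallied; the best single setting occasionally misranks the adapter, but rarely in a majority of six runs. |
| `sample_size` | 50,000 reads | the prediction sample; first-N in file order, not random. |
| `min_insert` | 16 nt | shortest clipped insert submitted to the mapper; below the plausible length of a real small RNA. |
| quality cutoff | 20% mapping rate | the poor-library warning line in exhaustive mode; boundary inclusive (exactly 20% passes). |
| Mott cutoff | opt-in, 10 or 20 | quality trimming is **off** by default — raw reads keep more adapter sequence and predict better; trimming is applied after sampling when enabled. |

## Numerical and procedural choices

Where the procedure leaves genuine freedom, this implementation fixes it
as follows.

* **Homopolymer threshold** ⌊k/2⌋ (k = 9 → runs of ≥ 4 are removed):
  the floor reading is the stricter of the two roundings and removes the
  4-base runs that dominate low-complexity artifacts at the default k.
  For k < 4 the run threshold is clamped to 2, below which "homopolymer
  run" ceases to be meaningful.
* **Ratio boundary**: discard strictly when *r* > *R*, so *r* = *R*
  survives; the most abundant k-mer always survives (its ratio is 1).
* **Assembly** is greedy chain extension: seed at the highest-count unused
  k-mer, extend rightward, then leftward, one (k−1)-overlap at a time,
  preferring the higher-count neighbour at a branch; a k-mer is used at
  most once, which also guarantees termination on cyclic overlap graphs.
  On overlap graphs that are disjoint unions of simple paths — the
  expected structure when survivors come from one adapter — greedy
  extension provably returns the exact path merges, and the test suite
  checks this against an independent path-decomposition oracle. Full De
  Bruijn graph resolution with branch disambiguation is deliberately not
  attempted.
* **Candidate ordering**: score descending, then summed member count, then
  lexicographic — deterministic across platforms.
* **Iterative tallying** is by exact string identity. A shorter assembly
  is *not* merged into a longer one containing it; prefix-merging would be
  an undocumented extension with its own failure modes. Consequently a
  k = 11 assembly and its k = 9 counterpart tally separately unless they
  assemble to the same string.
* **`N` handling**: windows containing `N` are excluded from both the
  counts and the window total, so N-rich libraries do not deflate scores.
* **Mott tie-breaking**: when several truncation points achieve the same
  maximal positive running sum, the one closest to the 3′ end wins,
  retaining more bases (and thus more adapter signal). The suite checks
  the trimmer against a brute-force enumeration of all truncation points.
* **Clipping** searches the leftmost exact occurrence of the adapter's
  7-mer prefix: the junction is the first place the prefix can occur, and
  leftmost minimizes retained adapter sequence. Matching is exact;
  mismatch-tolerant clipping is a non-goal.
* **Denominators**: both the clipped and the mapped fraction are relative
  to the number of sampled input reads. This makes `mapped ≤ clipped` an
  invariant and puts both numbers of a library on one basis. Only clipped
  reads of length ≥ `min_insert` are submitted to the mapper.
* **Exhaustive grid depth**: each (k, R) run contributes its top candidate
  only, deduplicated by exact string equality before any mapper run. The
  `candidates` argument of `exhaustive_search()` lets a user evaluate a
  deeper or hand-chosen set.
* **Already-processed rule**: raw reads win when their mapping rate is at
  least the best clipped candidate's *and* at least 20%. The mapping rate
  is the sole arbiter, and the 20% floor prevents a junk library (where
  everything maps at ~0%) from being declared "processed".
* **Phred offset** is auto-detected by the minimum-code rule (any quality
  character below ASCII 64 implies offset 33) and can be forced by flag,
  since older public libraries mix encodings.

## What the synthetic generator emulates

`library_spec()`/`make_library()` build seeded libraries over a uniform
random toy genome (default 10 kb): each read is a genomic insert
(18–26 nt, either strand) plus the optionally barcoded adapter, truncated
to the cycle count (default 36); per-cycle Phred means decline linearly
(defaults 38 → 30, Gaussian noise σ = 3, clamped to [2, 40]), emulating
the early-versus-late quality contrast of public libraries without
modelling any specific instrument. Read classes — adapter-bearing,
one fixed abundant small RNA (still adapter-ligated, as in real libraries
where a single miRNA can reach ~30% of reads), adapter dimers, and
adapter-free reads — are allocated by largest-remainder quota and
shuffled, so emitted fractions match the spec within one read. Adapter-free
reads stay at their insert length, as in a library whose adapters were
removed upstream. Random ground-truth adapters reject homopolymer runs of
≥ 4 nt, as designed ligation adapters do; an adapter that the
low-complexity filter is built to discard is not a realistic test of
recovery. The same rule applies to random barcodes across the
barcode–adapter junction (`random_barcode()`), since the barcoded oligo of
a de-multiplexed library is one designed sequence. The defaults (depth 50,000, 90% adapter-bearing reads) reflect
the common case in public data, where the large majority of libraries
show over 60% adapter-bearing reads.

What it does **not** emulate: sequencing errors in the bases,
instrument-specific quality strings, multiplexed pools needing
de-multiplexing, and genome repeat structure (a uniform random genome has
no repeats, so the exact-match stub mapper sees essentially no ambiguous
placements). Passing the recovery tests therefore demonstrates the
algorithm's behaviour under its own model assumptions, not robustness to
base-calling error; on real data the exact 7-mer clip rate degrades with
the per-base error rate.

The exact-match stub mapper reports a read as mapped iff the read or its
reverse complement occurs verbatim in the toy genome — the same contract
as a real aligner run in perfect-match mode, at toy-genome scale — and
emits minimal SAM so the whole exhaustive path (template substitution,
subprocess, SAM flag parsing) is exercised.

## Problem sizes

The recovery checks run 20 libraries per scenario at depth 50,000 —
the sampling depth the predictor is designed around — with distinct random
21-nt adapters. Processed-library classification uses 20 fixtures at depth
5,000: the verdict is a mapping-rate comparison and is already stable at
that depth. The oracle suites use 1,000 random reads (Mott), 200 random
path-shaped k-mer sets (assembly), and 1,000 random tables (filters).

## Known limitations

Besides the three failure classes above: adapters shorter than k cannot
be represented by a k-mer of the default length (the grid is configurable,
e.g. adding k = 8, but short adapters remain fragile); prediction operates
on the first reads of the file, so a library whose head is unrepresentative
(e.g. sorted reads) should be sampled upstream; and the exhaustive mode's
runtime is dominated by the user's mapper, one invocation per deduplicated
candidate plus one for the raw reads.
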