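---
title: "Bidirectional wavefront alignment under a memory budget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional wavefront alignment under a memory budget}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biwave)
```

## The problem

Global pairwise alignment of two sequences `Q` (query, length `n`) and `R`
(reference, length `m`) under edit penalties — match 0, mismatch `X`,
insertion `I`, deletion `D` — is classically solved by filling an
`(n+1)×(m+1)` dynamic-programming matrix, which is quadratic in time and
memory regardless of how similar the sequences are. The wavefront algorithm
(WFA) instead computes cells in increasing order of score, storing only the
furthest-reaching cell per diagonal per score, which costs `O(ns)` time and
`O(s²)` memory for optimal score `s`; its bidirectional variant (BiWFA)
lowers the memory to `O(s)` by advancing a forward and a backward frontier
until they meet. `biwave` implements both, restructured as an iterative,
memory-budgeted pipeline modelled on processing-in-memory hardware: a small
fast scratch tier (64 KB per worker by default) holds the live wavefronts
and the base-case solver, everything larger streams through a bulk tier
whose traffic is counted by an access ledger.

## The wavefront model

The package fixes 0-based, half-open coordinates with diagonal
`k = h − v`, where `h` is the reference offset and `v = h − k` the query
offset; a wavefront stores, for one score, the furthest-reaching `h` per
diagonal in `[lo, hi]`, with a sentinel below every valid offset marking
unreachable diagonals. Two primitives drive the search:

* **extend** — every offset advances by the longest common prefix of the
  remaining suffixes on its diagonal (free matches; the inner loop is the
  only compiled code in the package);
* **compute** — the next wavefront takes, per diagonal, the best of the
  mismatch (`prev[k] + 1`), deletion (`prev[k−1] + 1`) and insertion
  (`prev[k+1]`, offset unchanged) predecessors, with predecessors whose
  cells have run out of the consumed characters masked out before the
  maximum.

The terminal cell is `k = m − n` at offset `m`; the first score whose
extended wavefront reaches it is optimal. The kernels require uniform
penalties (`X = I = D`, default 1, i.e. edit distance): one wavefront step
advances the score by exactly one penalty unit, which is what makes the
two-frontier meeting argument below exact. General `{X, I, D}` penalties are
supported by the full-matrix oracle `nw_align()` and by the CIGAR algebra;
gap-affine scoring is out of scope.

Traceback ties are broken mismatch, then deletion, then insertion, giving
deterministic transcripts; when aligners are compared only score equality is
asserted, since any optimal transcript is acceptable.

## The meeting rule and why it needs no correction

`biwfa_find_breakpoint()` advances whichever frontier has the lower score
(ties advance forward) and checks after every single step whether some
diagonal is covered jointly: forward offset `h_f` plus backward offset
`h_b` (measured on the reversed sequences) at least `m`. Because every
combined score `s_f + s_r` is visited exactly once, the first overlap yields
the optimal score exactly:

* *never late*: split any optimal path at the point where its prefix cost
  equals `s_f`; furthest-reaching maximality puts both frontiers at or past
  that point, so overlap is detected by `s_f + s_r = s`;
* *never early*: the unit-cost DP satisfies `D(i−1, j−1) ≤ D(i, j)` along
  every diagonal, so cutting at the forward furthest-reaching point of the
  overlapping diagonal costs at most `s_f` for the prefix and at most `s_r`
  for the suffix.

Those two bounds also force the two halves at the returned breakpoint to be
*exactly* optimal with scores `s_f` and `s_r` — the property the unrolled
driver relies on, and the property the test suite re-derives with the DP
oracle on both halves of hundreds of random pairs. No ±1 adjustment of the
combined score at the meeting step is needed under unit costs; this
resolution was validated against the oracle rather than assumed. The rule
would not carry over unchanged to non-uniform penalties (prefix costs then
step by more than one unit), which is the second reason the kernels insist
on uniform penalties.

Empty queries or references bypass the search: the backward frontier is
undefined on an empty sequence, so the trivial all-indel breakpoint at
`(0, 0)` is returned directly.

## The unrolled driver

`align_unrolled()` replaces BiWFA's recursion with an explicit work queue of
segments, each a pair of half-open intervals plus an inherited score bound.
The bound is exact, not an estimate — it is the half score of the parent's
breakpoint — so a segment is re-run only to find *its* breakpoint, never to
re-measure its score. A segment becomes a **base case** when a full WFA of
score `4×bound` fits the fast tier: a score-`s` run retains wavefronts
`0..s`, the score-`t` wavefront spanning `2t + 1` diagonals, `(s+1)²`
elements in total, so the rule is `(4·bound + 1)² · element_bytes ≤
fast_capacity_bytes`. With the default 64 KB tier and 4-byte offsets this
admits bounds up to 31 (a score-124 WFA, 15 625 elements, 62 500 bytes).
Base cases run entirely in the fast tier and therefore incur no bulk
wavefront traffic; the space the four live bidirectional buffers occupied is
notionally repurposed for the retained wavefront set.

Termination is guaranteed: balanced alternation keeps the two half scores
within one unit of each other, so both children of a score-`s` split have
bounds at most `⌈s/2⌉ < s` for `s ≥ 2`, and segments with score ≤ 1 are
forced into the base case regardless of the budget, so even pathologically
small budgets cannot loop. Zero-score and empty segments emit their
transcript directly without invoking a kernel. Parts carry their position in
the tiling; assembly (`assemble_output()`) concatenates in order-index
order, merging runs across boundaries, so no post-hoc reshuffling occurs.

## The memory model

The ledger counts logical accesses — element touches and block transfers —
not cycles or latency; all timing questions are hardware-bound and outside
the model. The counted quantities:

* **kernel accounting** — the separate compute-then-extend path loads 3
  wavefronts and writes 2 per element (5 bulk accesses); the fused
  compute+extend step reads 2 and writes 1 (3 accesses, a 40% reduction).
  Both modes produce bitwise-identical wavefronts; fusion is an accounting
  statement about traffic, which is why the per-element ratio is exact
  rather than approximate. The accounting is charged per wavefront element
  computed; block-granularity counts are kept separately.
* **transfer sizing** — per kernel invocation, the modelled transfer size
  starts at 8 bytes and grows by powers of two as the wavefront grows,
  capped by the fast buffer and the 2048-byte transfer limit, and never
  decreases within one invocation. Each BiWFA launch starts afresh at 8
  bytes, since its wavefronts start small again.
* **spilling** — wavefronts larger than their fast-tier allocation (a
  quarter of the capacity, one of the four live buffers) spill their
  overflow to the bulk tier; spilled elements are charged and grow with the
  optimal score.
* **sequence reads** — reverse reads (used conceptually by the backward
  frontier) are served from an alignment-padded store in 16-character
  blocks rounded to 8-byte boundaries, without materialising a reversed
  copy of the sequence.

## The synthetic generator

`generate_pair()` emulates fixed-length, fixed-error simulated workloads:
a uniform random reference of the requested length, and a query produced by
applying `round(length × error_rate)` edits at distinct uniform positions —
mismatch to a different symbol, deletion, or insertion after the position.
The default `indel_fraction = 2/3` splits edits evenly between mismatch,
insertion and deletion. Each pair is reproducible from `(seed, index)`
alone, and generation saves and restores the caller's RNG state. The
canonical study grid is lengths {150, 1 000, 10 000, 100 000} at error
rates {5%, 10%}; a heterogeneous mode draws lengths log-uniformly between a
minimum and maximum to exercise the scheduler with unbalanced work.

Edits can cancel or merge (a deletion next to an insertion of the same
symbol, two edits in one LCP run), so the optimal score is bounded above by
the applied edit count and in practice sits a few percent below it. What
the generator does **not** emulate: realistic indel length distributions
(every indel is a single symbol), sequencing-quality structure, coverage
biases, or homopolymer-dependent error hotspots. Tests passing on this
generator therefore demonstrate algorithmic correctness and the memory
model's properties, not robustness to every artefact of real sequencing
data — though the aligners are exact for any input, so only the *measured
distributions* (scores, spill counts, recovery fractions), not correctness,
depend on the generator's realism.

## The scheduler

`run_batches()` models the batch execution scheme: worker slots draw pair
ids from a shared monotone counter (`dynamic_assign()`), align under the
plan's nominal score cap, and flag pairs that exceed it. Flagged pairs are
re-aligned from scratch by an unrestricted fallback (`wfa_align()` with no
cap and no memory constraint) — hybrid recovery. Recovery of batch `i` is
interleaved after the start of batch `i + 1` in the event log, modelling
compute/recovery overlap without real concurrency; workers are sequential
simulated slots, so runs are bit-for-bit reproducible. The cap defaults to
unlimited and is deliberately left as user configuration: the right value
depends on the score distribution of the workload, and the package reports
the recovered fraction so users can tune it.

## Numerical and design choices

* Offsets are 32-bit integers; the sentinel is `−2³⁰`, ordered below every
  valid offset and never dereferenced, so the compute maximum stays
  branch-free.
* The overlap diagonal, when several overlap simultaneously, is the lowest
  index — any choice is correct, one is fixed for determinism.
* `base_case_threshold` uses `≤`, so a budget sized exactly for the
  `(4s+1)²` element count admits the segment.
* The DP oracle guards its matrix at 10⁸ cells; it exists for verification,
  not scale.
* Problem sizes in the test suite: 500 random pairs up to 256 bp at 0–30%
  error for the oracle-equivalence sweep, 2 000 bp pairs for the
  memory-scaling measurements, and a single 100 000 bp pair at 5% error for
  the scale demonstration — sizes chosen so the whole suite exercises every
  pipeline regime (no split, shallow split, deep split, spill) while
  remaining comfortable on a laptop.

## Known limitations

* Uniform penalties only in the wavefront kernels; no gap-affine or
  two-piece models, no protein scoring matrices.
* The memory model counts accesses; it does not simulate contention,
  latency, or instruction mix, so it reproduces access-ratio claims, not
  throughput claims.
* The scheduler models assignment and recovery semantics sequentially; it
  makes no statement about wall-clock scaling.
* `nw_align` with non-uniform penalties is the only aligner for such
  penalty sets, and it is quadratic.
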