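---
title: "Blocked, memory-bounded pairwise inference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blocked, memory-bounded pairwise inference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockinfer)
```

## The computation

Embedding-based protein–protein interaction (PPI) prediction reduces to a
pairwise inference problem: given per-protein embeddings — one real matrix
of shape `length × dim` per protein, produced upstream by a protein
language model and treated here as opaque — score every candidate pair
with a model `f(E_u, E_v) → [0, 1]`. For a catalog of $n$ proteins the
all-pairs universe has $\binom{n}{2}$ members, and the embeddings of a
eukaryotic proteome run to hundreds of gigabytes. The two naive regimes
both fail at scale: preloading everything is memory-bound; loading each
pair on demand reads every embedding $O(n)$ times.

`blockinfer` interpolates between them with a *blocked* traversal. The
catalog is cut into $B$ contiguous blocks of near-equal size (the first
$n \bmod B$ blocks get $\lceil n/B \rceil$ proteins, the rest
$\lfloor n/B \rfloor$). Every unordered protein pair lies in exactly one
block pair $(i, j)$, $i \le j$, so visiting each block pair once and
scoring its cross (or within-block) pairs visits each protein pair
exactly once. The per-step working set is two blocks, i.e. $O(n/B)$
memory.

## Serpentine traversal and the three-block bound

Block pairs are visited row by row with alternating column direction:
row $i$ covers $j = i, \dots, B$ ascending when $i$ is odd and
$j = B, \dots, i$ descending when $i$ is even. Two properties follow, and
both are certified by `simulate_memory()` replaying any schedule:

* **One load per transition.** Consecutive steps share a block everywhere
  except the diagonal-to-diagonal transition $(i,i) \to (i+1,i+1)$ at even
  row ends — and a diagonal step occupies only one block slot, so even
  there a single load suffices. `serpentine_schedule()` annotates every
  step with its loads and evicts; `|loads| ≤ 1` after the first step for
  every $B$ (checked exhaustively to $B = 128$ in the test suite).
* **Three resident blocks.** With the eviction policy below, the resident
  set never exceeds $\min(B, 3)$: the two blocks being scored plus the one
  block prefetched for the next step.

The eviction policy is deterministic: after step $t$ is satisfied, every
resident block required by neither step $t$ nor step $t+1$ is released.
Capacity is exactly three block slots. This is the simplest policy that
achieves the bound; an LRU cache could retain more blocks when $B$ is
small, but would make residency depend on history rather than on the
schedule alone, and the schedule-annotated form lets the planner
(`plan` subcommand, `schedule_table()`) print the entire residency
history without touching any data.

Bipartite mode uses the same serpentine rule over the $p \times q$ grid
of (A-block, B-block) pairs; blocks of the two catalogs are distinct
identities, so the same $\le 1$ load and $\le 3$ residency bounds hold.

Load volume grows linearly in $B$ at fixed $n$ — each of the
$O(B^2/2)$ steps loads at most one block of size $\approx n/B$, giving a
$\le (B(B+1)/2 + 1)\,\lceil n/B \rceil$ protein bound — while scoring
work is constant in $B$. The practical optimum is therefore the smallest
memory budget whose load time stays below scoring time; the planner
reports both quantities so users can choose $B$ without running anything.

## Engine architecture

`run_inference()` separates the three concerns that serialize a naive
implementation:

1. a **coordinator** that follows the schedule, loads blocks from the
   HDF5 store, and enumerates each step's pair tasks;
2. a **worker pool** (`n_workers` forked processes via the `parallel`
   package) that scores task chunks, reading the resident embeddings from
   copy-on-write shared memory — the portable generalization of
   one-process-per-GPU to any pool of scoring slots;
3. a single **writer** owning both output files, so rows are whole lines
   and the files carry exactly one header under any worker count.

While a step's chunks are in flight, the coordinator applies the next
step's loads/evicts, overlapping I/O with scoring; during that overlap
the physical working set is $\mathrm{need}(t) \cup \mathrm{need}(t+1)$,
which the serpentine order keeps at three blocks or fewer. With
`n_workers = 1` scoring is done in-process and no overlap is attempted.
Task chunks are capped so that at most `buffer_capacity` tasks are in
flight at once (backpressure). A worker failure aborts the entire run:
silently skipping pairs would break the exactly-once contract, and a
partial output file that looks complete is worse than a loud failure.

The memory bound is *enforced*, not just derived: every load registers
with a `memory_accountant()` whose capacity is $\min(B, 3)$ in
full-block modes, and a load that would exceed capacity aborts the run
with a diagnostic. Byte accounting is `length × dim × 4` per protein
(embeddings are stored and accounted as 32-bit floats).

### Modes

* **all_pairs** — every unordered pair of distinct proteins. Self-pairs
  $(u, u)$ are excluded by default (an `include_self` flag exists): the
  natural pair universe of interactome scans is $\binom{n}{2}$, and all
  of the benchmark universe sizes the package reproduces are of that
  form. Diagonal block pairs are visited once and their within-block
  pairs enumerated once.
* **some_pairs** — an explicit candidate list. Pairs are bucketed once,
  up front, by normalized block pair; at each step exactly the bucket's
  pairs are enqueued. This is output-equivalent to testing every
  enumerated pair against a membership matrix but never scans pairs that
  were not requested. Whole blocks are still loaded — predictable I/O,
  and the right choice when candidates are dense.
* **sparse** — same bucketing, but each step loads only the proteins its
  bucket names, and releases them after the step. Partial blocks are not
  retained or prefetched across steps: a block's needed subset differs
  from step to step, so cross-step reuse would complicate residency
  accounting for a saving that is small exactly when sparsity is high
  (the regime the mode exists for). The resident protein set therefore
  equals exactly the in-flight block pair's requirement. Empty buckets
  skip the step without touching the store.
* **bipartite** — all cross pairs between two catalogs (e.g. a symbiont
  against its host proteome), with one shared or two separate stores.
  Cross-catalog pairs are never flipped: the A-protein is always first.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_blocks` (B) | 1 | memory/IO tradeoff; 1 reproduces preload-everything behavior |
| `n_workers` (W) | 1 | scoring processes; output set is invariant to W |
| `threshold` | 0.5 | score cutoff for the positives file, in [0, 1] |
| `buffer_capacity` | 4096 | max pair tasks in flight (backpressure) |
| `dim` (fixtures) | 32 | embedding dimensionality; free parameter of the store |
| `max_length` | 1000 aa | FASTA catalog length filter, the usual cap of embedding models |

Defaults `B = W = 1` deliberately reproduce the serial behavior unless
the user opts into blocking or parallelism.

## The synthetic data generator

`generate_synthetic_store()` draws protein lengths uniformly from a range
(default 50–200 residues for fixtures) and fills embeddings with i.i.d.
standard normals at `dim = 32`, written as float32 HDF5 datasets; seeds
make stores byte-reproducible. `sample_pair_fraction()` draws
$\lfloor \text{fraction} \times \binom{n}{2} \rfloor$ distinct pairs
uniformly — the floor rule is what makes sampled-set sizes exactly
reproducible — with an optional coverage repair that swaps uncovered
proteins into sampled pairs (provably feasible whenever the sample has at
least $\lceil n/2 \rceil$ pairs, since a pair set with all degrees
$\le 1$ covers only $2k$ proteins).

What the generator emulates is the *shape* of real inputs: keyed
variable-length arrays, realistic catalog/pair-list/store file formats,
arbitrary pair densities. What it does not emulate: real embedding
geometry (language-model embeddings are highly structured, not isotropic
noise), realistic length distributions, or a trained scorer. Passing
tests therefore demonstrate that scheduling, loading, scoring and
writing are *exact* — every requested pair scored once, outputs identical
to the serial reference, memory bounded — for any scorer; they say
nothing about predictive accuracy, which belongs to the upstream model.

## Numerical and degenerate-input choices

* Pair counts use closed forms with integral intermediates
  ($n/2 \cdot (n-1)$ with the even factor halved first), exact in doubles
  far beyond any proteome size; inputs are validated as non-negative
  whole numbers.
* Sample sizes apply the floor after a one-part-in-$10^{12}$ relative
  nudge so that binary representation of fractions like 0.3 cannot drop
  a unit below the mathematical floor.
* Sampling decodes linear indices of the row-major pair triangle via the
  closed-form inverse, then corrects with a bounded walk against exact
  integer offsets — immune to `sqrt` edge error.
* Scores are written with six decimals; set comparisons in the tests use
  that written precision.
* Degenerate cases are first-class: $B = 1$ (single block, one load),
  singleton blocks, empty candidate sets (valid, empty output), empty
  stores, thresholds of 0 and above 1 (positives = all, positives =
  none).
* The RNG state of the caller is never disturbed: seeded operations
  save and restore `.Random.seed`.

## Problem sizes used in the checks

The test suite runs entirely on generated fixtures: catalogs of 4–30
proteins for exhaustive coverage sweeps (every admissible $B$, all modes),
a 20-protein catalog for the $(B, W)$ output-equality grid, and schedule
properties checked for all $B \le 128$. The acceptance script additionally
materializes the two benchmark-scale pair samples (19.7M and 22.2M pairs
over 12 563 and 38 486 proteins) — sizes chosen because their universes
are the ones whose printed counts the counting operations must reproduce
exactly.

## Known limitations

* Workers use `fork()`; on platforms without fork semantics the engine
  degrades to `n_workers = 1` behavior (all tests of parallel paths run
  on fork-capable systems).
* Output row order is completion order under `n_workers > 1`; use
  `sorted = TRUE` (or compare sets) when determinism of order matters.
* No distributed multi-node scheduling: the unit of parallelism is a
  process on one host.
* The sparse mode's per-step reload policy can re-read a protein once per
  block pair that names it; for dense candidate sets `some_pairs` is the
  better choice (as its whole-block loads are sequential and bounded).
* Scores are assumed to cost much more than comparisons; for trivially
  cheap scorers the enumeration overhead dominates and blocking buys
  nothing (but costs correctness nothing either).
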