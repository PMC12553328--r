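# blockinfer

Blocked, memory-bounded pairwise protein–protein interaction (PPI)
inference in R.

## The problem

Embedding-based PPI predictors score a pair of proteins from their
per-protein embeddings — one `L × d` matrix per protein, one row per
residue. Network- and proteome-level analyses need *every* pair scored:
a catalog of *n* proteins has *n(n−1)/2* candidate pairs, and holding all
embeddings in memory at once costs tens to hundreds of gigabytes for
eukaryotic proteomes. Scoring pairs one at a time with just-in-time
loading avoids the memory cost but bottlenecks on I/O.

`blockinfer` implements the blocked schedule that resolves this tradeoff.
The catalog is partitioned into *B* contiguous blocks, and block pairs
`(i, j)`, `i ≤ j`, are traversed in a **serpentine** order: row `i`
ascends `j = i..B` when `i` is odd and descends `j = B..i` when `i` is
even. Consecutive steps then never require two new blocks, so

* at most **one new block** of embeddings is loaded per step, and
* at most **three blocks** are resident in memory at any time — the two
  being scored plus the one being prefetched — independent of *B*.

Memory therefore scales as `O(n/B)` while every one of the `n(n−1)/2`
pairs is still scored exactly once. A coordinator process loads blocks
and enqueues pair tasks, a pool of forked worker processes scores them
from copy-on-write shared memory while the next block loads, and a single
writer streams thresholded predictions to disk. The scorer is pluggable
(`pair_scorer`); the package ships a deterministic mock scorer,
`logistic(mean(E1) + mean(E2))`, so the machinery can be verified
bit-exactly against a serial reference implementation.

Four modes cover the standard inference tasks:

| mode         | pairs scored                              | loading          |
|--------------|-------------------------------------------|------------------|
| `all_pairs`  | every unordered pair of distinct proteins | whole blocks     |
| `some_pairs` | an explicit candidate list (TSV)          | whole blocks     |
| `sparse`     | an explicit candidate list                | only the proteins each block pair names |
| `bipartite`  | every cross pair between two catalogs     | whole blocks, two stores |

Embeddings live in an HDF5 store, one float32 dataset per protein id.

## Worked example

```r
library(blockinfer)

# synthetic catalog + HDF5 embedding store (20 proteins, dim 32)
dir <- tempfile(); dir.create(dir)
fx <- generate_synthetic_store(sprintf("prot%02d", 1:20),
                               file.path(dir, "embeddings.h5"),
                               length_range = c(50, 200), seed = 7)

# plan: 5 blocks -> 15 block-pair steps, peak 3 resident blocks
simulate_memory(serpentine_schedule(5), block_partition(fx$catalog, 5))
#> <memory_ledger> peak 3 resident blocks, 10 loads, 40 proteins loaded

# blocked run, 2 workers
cfg <- engine_config("all_pairs", n_blocks = 5, n_workers = 2,
                     output_prefix = file.path(dir, "preds"))
run_inference(cfg, fx$catalog, fx$store)
#> <bpi_run:all_pairs> B=5 W=2 | 190 pairs scored, 93 positive | peak 3 resident blocks, 10 loads

# identical record set to the preload-everything serial reference
ref <- serial_reference(fx$catalog, fx$store)
got <- read_predictions(file.path(dir, "preds.tsv"))
setequal(sprintf("%s %s %.6f", got$id1, got$id2, got$score),
         sprintf("%s %s %.6f", ref$id1, ref$id2, ref$score))
#> [1] TRUE
```

All 190 = C(20, 2) pairs are scored exactly once; the run held at most 3
of the 5 blocks in memory and loaded 10 blocks in total; 93 pairs met the
default 0.5 score threshold and were also written to `preds.positive.tsv`.

The same engine is exposed as a command-line tool:

```sh
exec/blockinfer predict --proteins catalog.txt --embeddings emb.h5 \
    --blocks 64 --workers 4 --output preds
exec/blockinfer predict --pairs candidates.tsv --embeddings emb.h5 --sparse_loading
exec/blockinfer predict_bipartite --proteins a.txt --proteins2 b.txt --embeddings emb.h5
exec/blockinfer plan --blocks 64 --count 6282
exec/blockinfer make-fixtures --out-dir fx --n-proteins 100 --pair-fraction 0.25
```

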