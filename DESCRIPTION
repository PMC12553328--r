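Package: blockinfer
Title: Blocked, Memory-Bounded Pairwise Protein Interaction Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An out-of-core scheduler and worker-pool engine for large-scale
    pairwise protein-protein interaction inference from per-protein embeddings.
    Proteins are partitioned into contiguous blocks and block pairs are
    traversed in a serpentine order so that at most one new block of embeddings
    is loaded per step and at most three blocks are ever resident in memory.
    A pluggable pairwise scorer is driven through a loader / worker-pool /
    single-writer architecture in four modes: all-pairs within one catalog,
    an explicit candidate pair list, a sparse-loading variant that loads only
    the proteins named by the current block pair, and bipartite cross-proteome
    prediction between two catalogs. Includes a serial reference
    implementation used as the correctness oracle, a schedule planner with a
    memory-ledger simulator, and a synthetic fixture generator (catalogs,
    HDF5 embedding stores, sampled pair sets).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    parallel,
    rhdf5,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
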