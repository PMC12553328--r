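test_that("the mock scorer is the logistic of summed embedding means, symmetric", {
  s <- mock_scorer()
  z1 <- matrix(0, 3, 4); z2 <- matrix(0, 7, 4)
  expect_identical(score_pair(s, z1, z2), 0.5)
  m1 <- matrix(1, 5, 2); m2 <- matrix(1, 2, 2)
  expect_equal(score_pair(s, m1, m2), plogis(2))
  e1 <- matrix(rnorm(12), 3, 4); e2 <- matrix(rnorm(20), 5, 4)
  expect_identical(score_pair(s, e1, e2), score_pair(s, e2, e1))
  expect_error(score_pair(s, matrix(0, 0, 4), e2), "empty")
  sd <- mock_scorer(dim = 4L)
  expect_error(score_pair(sd, matrix(0, 3, 5), e2), "dim 4")
})

test_that("serial reference scores all pairs once, in canonical order", {
  fx <- make_fixture(4, seed = 11L)
  ref <- serial_reference(fx$catalog, fx$store)
  expect_identical(nrow(ref), 6L)
  expect_identical(sprintf("%s|%s", ref$id1, ref$id2), all_pair_keys(fx$catalog))
  expect_true(all(ref$score >= 0 & ref$score <= 1))

  # empty candidate set: empty output, success
  ps <- candidate_pairs(character(0), character(0), fx$catalog)
  expect_identical(nrow(serial_reference(fx$catalog, fx$store, pairs = ps)), 0L)
})

test_that("blocked multi-worker output sets equal the serial reference across the (B, W) grid", {
  fx <- make_fixture(20, seed = 1L)
  ref_key <- pred_key(serial_reference(fx$catalog, fx$store))
  for (B in c(1L, 2L, 3L, 5L)) for (W in c(1L, 2L, 4L)) {
    cfg <- engine_config("all_pairs", n_blocks = B, n_workers = W,
                         output_prefix = file.path(fx$dir,
                                                   sprintf("g%d_%d", B, W)))
    run <- run_inference(cfg, fx$catalog, fx$store)
    expect_identical(run$pairs_scored, 190L)
    expect_lte(run$peak_resident_blocks, min(B, 3L))
    got <- read_predictions(run$files$full)
    expect_identical(pred_key(got), ref_key,
                     label = sprintf("B=%d W=%d", B, W))
  }
})

test_that("some-pairs and sparse runs score exactly the candidate list", {
  fx <- make_fixture(15, seed = 2L)
  pos <- sample_pair_fraction(15, 0.3, seed = 9L)
  ps <- candidate_pairs(fx$ids[pos[, 1L]], fx$ids[pos[, 2L]], fx$catalog)
  ref_key <- pred_key(serial_reference(fx$catalog, fx$store, pairs = ps))
  for (mode in c("some_pairs", "sparse")) for (B in c(1L, 4L)) {
    cfg <- engine_config(mode, n_blocks = B, n_workers = 2L,
                         output_prefix = file.path(fx$dir,
                                                   paste0(mode, B)))
    run <- run_inference(cfg, fx$catalog, fx$store, pairs = ps)
    expect_identical(run$pairs_scored, nrow(ps))
    got <- read_predictions(run$files$full)
    expect_identical(pred_key(got), ref_key,
                     label = sprintf("%s B=%d", mode, B))
  }
})

test_that("sparse mode loads only the proteins the current block pair names", {
  fx <- make_fixture(12, seed = 6L)
  # one candidate pair spanning blocks 1 and 4 of 4
  ps <- candidate_pairs(fx$ids[1L], fx$ids[12L], fx$catalog)
  cfg <- engine_config("sparse", n_blocks = 4L,
                       output_prefix = file.path(fx$dir, "sp"))
  run <- run_inference(cfg, fx$catalog, fx$store, pairs = ps)
  expect_identical(run$pairs_scored, 1L)
  expect_identical(run$loaded_proteins, 2)  # not 6 (two full blocks)
  expect_identical(run$total_loads, 2L)
  lens <- fx$catalog$lengths[c(1L, 12L)]
  expect_identical(run$loaded_bytes, sum(lens) * 8 * 4)
})

test_that("bipartite runs equal the serial cross-pair reference, shared or separate stores", {
  fxA <- make_fixture(8, seed = 21L, prefix = "a")
  fxB <- make_fixture(5, seed = 22L, prefix = "b")
  ref <- serial_reference(fxA$catalog, fxA$store, catalog2 = fxB$catalog,
                          store2 = fxB$store)
  expect_identical(nrow(ref), 40L)
  cfg <- engine_config("bipartite", n_blocks = 3L, n_workers = 2L,
                       output_prefix = file.path(fxA$dir, "bi"))
  run <- run_inference(cfg, fxA$catalog, fxA$store, catalog2 = fxB$catalog,
                       store2 = fxB$store)
  expect_identical(run$pairs_scored, 40L)
  expect_lte(run$peak_resident_blocks, 3L)
  expect_identical(pred_key(read_predictions(run$files$full)), pred_key(ref))

  # one shared store holding both proteomes gives identical records
  shared <- tempfile(fileext = ".h5")
  embs <- c(lapply(fxA$ids, fetch_embedding, store = fxA$store),
            lapply(fxB$ids, fetch_embedding, store = fxB$store))
  names(embs) <- c(fxA$ids, fxB$ids)
  sh_store <- write_embedding_store(embs, shared)
  cfg2 <- engine_config("bipartite", n_blocks = 3L,
                        output_prefix = file.path(fxA$dir, "bish"))
  run2 <- run_inference(cfg2, fxA$catalog, sh_store, catalog2 = fxB$catalog)
  expect_identical(pred_key(read_predictions(run2$files$full)), pred_key(ref))
})

test_that("thresholding splits the positives file; extreme thresholds behave", {
  fx <- make_fixture(8, seed = 31L)
  ref <- serial_reference(fx$catalog, fx$store)
  t0 <- sort(ref$score)[14L]  # 15 of 28 scores sit at or above this
  cfg <- engine_config("all_pairs", n_blocks = 2L, threshold = t0,
                       output_prefix = file.path(fx$dir, "thr"))
  run <- run_inference(cfg, fx$catalog, fx$store)
  pos <- read_predictions(run$files$positive)
  full <- read_predictions(run$files$full)
  expect_identical(nrow(full), 28L)
  expect_identical(run$n_positive, sum(ref$score >= t0))
  expect_identical(nrow(pos), run$n_positive)

  # above any score: positives empty, full file intact
  cfg_hi <- engine_config("all_pairs", threshold = 1.1,
                          output_prefix = file.path(fx$dir, "hi"))
  run_hi <- run_inference(cfg_hi, fx$catalog, fx$store)
  expect_identical(nrow(read_predictions(run_hi$files$positive)), 0L)
  expect_identical(nrow(read_predictions(run_hi$files$full)), 28L)

  # zero: positives = full
  cfg_lo <- engine_config("all_pairs", threshold = 0,
                          output_prefix = file.path(fx$dir, "lo"))
  run_lo <- run_inference(cfg_lo, fx$catalog, fx$store)
  expect_identical(run_lo$n_positive, 28L)
})

test_that("output files carry one header and whole rows under many workers", {
  fx <- make_fixture(16, seed = 41L)
  cfg <- engine_config("all_pairs", n_blocks = 4L, n_workers = 4L,
                       buffer_capacity = 8L,
                       output_prefix = file.path(fx$dir, "w"))
  run <- run_inference(cfg, fx$catalog, fx$store)
  lines <- readLines(run$files$full)
  expect_identical(sum(lines == "id1\tid2\tscore"), 1L)
  expect_identical(lines[1L], "id1\tid2\tscore")
  body <- lines[-1L]
  expect_identical(length(body), 120L)
  expect_true(all(grepl("^[^\t]+\t[^\t]+\t[01]\\.[0-9]{6}$", body)))
})

test_that("sorted runs write rows in canonical catalog order", {
  fx <- make_fixture(10, seed = 51L)
  cfg <- engine_config("all_pairs", n_blocks = 3L, n_workers = 2L,
                       sorted = TRUE,
                       output_prefix = file.path(fx$dir, "srt"))
  run <- run_inference(cfg, fx$catalog, fx$store)
  got <- read_predictions(run$files$full)
  expect_identical(sprintf("%s|%s", got$id1, got$id2),
                   all_pair_keys(fx$catalog))
})

test_that("a failing scorer aborts the whole run and names the pair", {
  fx <- make_fixture(6, seed = 61L)
  poison <- fx$ids[4L]
  bad <- pair_scorer(function(e1, e2) {
    if (abs(nrow(e1) - fx$catalog$lengths[4L]) == 0 ||
        abs(nrow(e2) - fx$catalog$lengths[4L]) == 0) stop("poisoned")
    0.5
  })
  for (W in c(1L, 2L)) {
    cfg <- engine_config("all_pairs", n_blocks = 2L, n_workers = W,
                         output_prefix = file.path(fx$dir, paste0("f", W)))
    expect_error(run_inference(cfg, fx$catalog, fx$store, scorer = bad),
                 "scoring failed|worker failed")
  }
})

test_that("missing embeddings fail validation before any scoring begins", {
  fx <- make_fixture(6, seed = 71L)
  ghostcat <- protein_catalog(c(fx$ids, "ghost1"))
  cfg <- engine_config("all_pairs", output_prefix = file.path(fx$dir, "v"))
  expect_error(run_inference(cfg, ghostcat, fx$store),
               "pre-run validation.*ghost1")
})

test_that("run summaries report loads and residency consistent with the simulated ledger", {
  fx <- make_fixture(18, seed = 81L)
  for (B in c(1L, 3L, 6L)) {
    cfg <- engine_config("all_pairs", n_blocks = B,
                         output_prefix = file.path(fx$dir, paste0("s", B)))
    run <- run_inference(cfg, fx$catalog, fx$store)
    led <- simulate_memory(serpentine_schedule(B),
                           block_partition(fx$catalog, B))
    expect_identical(run$total_loads, led$total_loads)
    expect_identical(run$loaded_proteins, led$load_volume_proteins)
    expect_lte(run$peak_resident_blocks, min(B, 3L))
    # log file mirrors the summary
    log <- read.delim(paste0(cfg$output_prefix, ".log"), header = FALSE,
                      colClasses = "character")
    expect_identical(log$V2[log$V1 == "pairs_scored"],
                     as.character(run$pairs_scored))
  }
})
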