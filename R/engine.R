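#' Engine configuration
#'
#' Bundles the knobs of a blocked inference run. `n_blocks` trades memory
#' for load overhead (more blocks, less resident memory, more loads);
#' `n_workers` is the size of the scoring worker pool (the generalization of
#' one-process-per-GPU to any pool of scoring slots); `buffer_capacity`
#' bounds how many pair tasks the coordinator may hold in flight at once.
#'
#' @param mode One of `"all_pairs"`, `"some_pairs"`, `"sparse"`,
#'   `"bipartite"`.
#' @param n_blocks Number of catalog blocks `B >= 1` (for bipartite mode,
#'   applied to each catalog, capped at its size).
#' @param n_workers Scoring worker processes, `>= 1`.
#' @param threshold Positive-call threshold in [0, 1].
#' @param buffer_capacity Maximum pair tasks in flight, `>= 1`.
#' @param output_prefix Path prefix for the output files.
#' @param sorted Re-sort output canonically after the run (row order is
#'   otherwise completion order, nondeterministic under `n_workers > 1`).
#' @param include_self Score self-pairs `(u, u)` in all-pairs mode.
#' @param verbose Emit a progress line per completed block pair to stderr.
#' @return An `engine_config`.
#' @export
engine_config <- function(mode = c("all_pairs", "some_pairs", "sparse",
                                   "bipartite"),
                          n_blocks = 1L, n_workers = 1L, threshold = 0.5,
                          buffer_capacity = 4096L,
                          output_prefix = tempfile("predictions"),
                          sorted = FALSE, include_self = FALSE,
                          verbose = FALSE) {
  mode <- match.arg(mode)
  n_blocks <- as.integer(assert_count(n_blocks, "n_blocks"))
  n_workers <- as.integer(assert_count(n_workers, "n_workers"))
  buffer_capacity <- as.integer(assert_count(buffer_capacity,
                                             "buffer_capacity"))
  if (n_blocks < 1L || n_workers < 1L || buffer_capacity < 1L) {
    stop("`n_blocks`, `n_workers` and `buffer_capacity` must be >= 1",
         call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0) {
    stop("`threshold` must be a single non-negative number", call. = FALSE)
  }
  structure(
    list(mode = mode, n_blocks = n_blocks, n_workers = n_workers,
         threshold = threshold, buffer_capacity = buffer_capacity,
         output_prefix = output_prefix, sorted = sorted,
         include_self = include_self, verbose = verbose),
    class = "engine_config")
}

#' Serial reference inference
#'
#' The single-process oracle: preloads every required embedding, iterates
#' the requested pairs in canonical order, scores each once. Its output set
#' defines correctness for every blocked, multi-worker configuration — for
#' any `B` and worker count, [run_inference()] must produce exactly this set
#' of records (scores bit-equal for a deterministic scorer).
#'
#' @param catalog A [protein_catalog()] (first catalog in bipartite mode).
#' @param store An [open_embedding_store()] (first store in bipartite mode).
#' @param pairs Optional [candidate_pairs()]; when given, exactly these
#'   pairs are scored, otherwise all pairs (or all cross pairs in bipartite
#'   mode).
#' @param scorer A [pair_scorer()]; defaults to the [mock_scorer()].
#' @param catalog2,store2 Second catalog and store for bipartite mode
#'   (`store2` defaults to `store` for a shared-store run).
#' @param include_self Score self-pairs in all-pairs mode.
#' @return data.frame with columns `id1`, `id2`, `score`, in canonical pair
#'   order.
#' @export
serial_reference <- function(catalog, store, pairs = NULL,
                             scorer = mock_scorer(), catalog2 = NULL,
                             store2 = NULL, include_self = FALSE) {
  stopifnot(inherits(catalog, "protein_catalog"),
            inherits(store, "embedding_store"))
  bipartite <- !is.null(catalog2)
  if (bipartite && is.null(store2)) store2 <- store

  tasks <- if (!is.null(pairs)) {
    data.frame(id1 = pairs$id1, id2 = pairs$id2, stringsAsFactors = FALSE)
  } else if (bipartite) {
    g <- expand.grid(id2 = catalog2$ids, id1 = catalog$ids,
                     stringsAsFactors = FALSE)[, c("id1", "id2")]
    rownames(g) <- NULL
    g
  } else {
    part1 <- block_partition(catalog, 1L)
    enumerate_step_pairs("all_pairs", part1, 1L, 1L,
                         include_self = include_self)
  }

  need1 <- unique(if (bipartite) tasks$id1 else c(tasks$id1, tasks$id2))
  need2 <- if (bipartite) unique(tasks$id2) else character(0)
  validate_in_store(need1, store)
  if (bipartite) validate_in_store(need2, store2)

  recs <- lapply(need1, function(id) fetch_embedding(store, id))
  names(recs) <- need1
  if (bipartite) {
    recs2 <- lapply(need2, function(id) fetch_embedding(store2, id))
    names(recs2) <- need2
  } else {
    recs2 <- recs
  }

  score <- vapply(seq_len(nrow(tasks)), function(r) {
    score_pair(scorer, recs[[tasks$id1[r]]], recs2[[tasks$id2[r]]])
  }, numeric(1))
  data.frame(id1 = tasks$id1, id2 = tasks$id2, score = score,
             stringsAsFactors = FALSE)
}

validate_in_store <- function(ids, store) {
  absent <- setdiff(ids, store$ids)
  if (length(absent) > 0L) {
    stop("pre-run validation failed; proteins missing from embedding store: ",
         paste(utils::head(absent, 5L), collapse = ", "),
         if (length(absent) > 5L) sprintf(" (and %d more)", length(absent) - 5L),
         call. = FALSE)
  }
  invisible(ids)
}

#' Run blocked, multi-worker pairwise inference
#'
#' The full engine: partitions the catalog(s) into blocks, traverses block
#' pairs in serpentine order (at most one new block loaded per step, at most
#' three blocks resident — enforced at run time by the memory accountant),
#' enumerates each step's pair tasks, scores them on a pool of forked worker
#' processes that read the resident embeddings from shared memory, and
#' streams all records through a single writer. While a step's tasks are in
#' flight, the coordinator prefetches the next step's block, overlapping
#' loading with scoring.
#'
#' Modes: `all_pairs` scores every unordered pair of distinct catalog
#' proteins; `some_pairs` scores exactly a candidate list, still loading
#' whole blocks; `sparse` additionally loads only the proteins named by the
#' current block pair's candidates; `bipartite` scores every cross pair
#' between two catalogs. Every requested pair is scored exactly once; a
#' worker failure aborts the whole run (fail-fast) rather than silently
#' dropping pairs.
#'
#' @param config An [engine_config()].
#' @param catalog,store,pairs,scorer,catalog2,store2 As in
#'   [serial_reference()]; `pairs` is required for `some_pairs`/`sparse`
#'   and forbidden for `all_pairs`/`bipartite`.
#' @return A `bpi_run` summary: pairs scored, positives, peak resident
#'   blocks, total block loads, load volume, output file paths.
#' @seealso [serial_reference()] for the correctness oracle.
#' @export
run_inference <- function(config, catalog, store, pairs = NULL,
                          scorer = mock_scorer(), catalog2 = NULL,
                          store2 = NULL) {
  stopifnot(inherits(config, "engine_config"),
            inherits(catalog, "protein_catalog"),
            inherits(store, "embedding_store"))
  mode <- config$mode
  if (mode %in% c("some_pairs", "sparse") && is.null(pairs)) {
    stop(mode, " mode requires a candidate pair set", call. = FALSE)
  }
  if (mode %in% c("all_pairs", "bipartite") && !is.null(pairs)) {
    stop(mode, " mode does not take a candidate pair set", call. = FALSE)
  }
  if (mode == "bipartite") {
    if (is.null(catalog2)) stop("bipartite mode requires `catalog2`",
                                call. = FALSE)
    if (is.null(store2)) store2 <- store
    overlap <- intersect(catalog$ids, catalog2$ids)
    if (length(overlap) > 0L) {
      warning("ids present in both catalogs (first-set embeddings used for ",
              "set A): ", paste(utils::head(overlap, 5L), collapse = ", "),
              call. = FALSE)
    }
  } else if (!is.null(catalog2)) {
    stop("`catalog2` is only meaningful in bipartite mode", call. = FALSE)
  }

  # --- plan ------------------------------------------------------------
  if (mode == "bipartite") {
    p <- min(config$n_blocks, length(catalog))
    q <- min(config$n_blocks, length(catalog2))
    partition <- block_partition(catalog, p)
    partition2 <- block_partition(catalog2, q)
    schedule <- bipartite_schedule(p, q)
    capacity <- min(p + q, 3L)
  } else {
    partition <- block_partition(catalog, config$n_blocks)
    partition2 <- NULL
    schedule <- serpentine_schedule(config$n_blocks)
    capacity <- min(config$n_blocks, 3L)
  }
  buckets <- if (mode %in% c("some_pairs", "sparse")) {
    bucket_pairs(pairs, partition)
  }

  # --- pre-run validation ----------------------------------------------
  if (mode == "all_pairs") {
    validate_in_store(catalog$ids, store)
  } else if (mode == "bipartite") {
    validate_in_store(catalog$ids, store)
    validate_in_store(catalog2$ids, store2)
  } else {
    validate_in_store(unique(c(pairs$id1, pairs$id2)), store)
  }

  acct <- memory_accountant(capacity)
  writer <- prediction_writer(config$output_prefix, config$threshold)
  on.exit(try(writer$close(), silent = TRUE), add = TRUE)

  if (mode == "sparse") {
    run_sparse(config, schedule, partition, buckets, store, scorer, acct,
               writer)
  } else {
    run_full_block(config, mode, schedule, partition, partition2, buckets,
                   store, store2, scorer, acct, writer)
  }

  on.exit()
  files <- writer$close()
  summary <- structure(
    list(mode = mode, n_blocks = config$n_blocks,
         n_workers = config$n_workers,
         threshold = config$threshold,
         pairs_scored = files$n_written,
         n_positive = files$n_positive,
         peak_resident_blocks = acct$peak_blocks,
         total_loads = acct$total_loads,
         loaded_proteins = acct$loaded_proteins,
         loaded_bytes = acct$loaded_bytes,
         files = files[c("full", "positive")]),
    class = "bpi_run")
  if (config$sorted) sort_outputs(summary, catalog, catalog2)
  write_run_log(summary, paste0(config$output_prefix, ".log"))
  summary
}

# Full-block traversal (all_pairs / some_pairs / bipartite): follow the
# schedule's load/evict annotations exactly, overlapping the next step's
# load with the current step's in-flight scoring.
run_full_block <- function(config, mode, schedule, partition, partition2,
                           buckets, store, store2, scorer, acct, writer) {
  n_steps <- length(schedule)
  resident <- new.env(parent = emptyenv())
  state <- new.env(parent = emptyenv())
  state$entered <- 0L

  enter <- function(t) {
    for (lab in schedule$loads[[t]]) {
      resident[[lab]] <- load_block_by_label(lab, partition, partition2,
                                             store, store2, acct)
    }
  }
  exit <- function(t) {
    for (lab in schedule$evicts[[t]]) {
      evict_block(acct, lab)
      rm(list = lab, envir = resident)
    }
  }
  advance_to <- function(t) {
    while (state$entered < t) {
      if (state$entered > 0L) exit(state$entered)
      state$entered <- state$entered + 1L
      enter(state$entered)
    }
  }

  for (t in seq_len(n_steps)) {
    advance_to(t)
    i <- schedule$i[t]; j <- schedule$j[t]
    li <- schedule$labels_i[t]; lj <- schedule$labels_j[t]
    tasks <- enumerate_step_pairs(mode, partition, i, j, buckets = buckets,
                                  partition2 = partition2,
                                  include_self = config$include_self)
    recs <- resident[[li]]$records
    if (lj != li) recs <- c(recs, resident[[lj]]$records)
    score_and_write(tasks, recs, scorer, config, writer,
                    prefetch = function() if (t < n_steps) advance_to(t + 1L))
    if (config$verbose) {
      message(sprintf("[%s] block pair %d/%d (%s,%s): %d pairs scored",
                      mode, t, n_steps, li, lj, nrow(tasks)))
    }
  }
  advance_to(n_steps)
  exit(n_steps)
}

# Sparse-loading traversal: per block pair, load only the proteins named by
# that bucket's candidates, score, then release them; empty buckets are
# skipped without touching the store.
run_sparse <- function(config, schedule, partition, buckets, store, scorer,
                       acct, writer) {
  for (t in seq_len(length(schedule))) {
    i <- schedule$i[t]; j <- schedule$j[t]
    sel <- sparse_selection(buckets, i, j)
    if (length(sel$first) == 0L && length(sel$second) == 0L) next
    b1 <- load_block(store, partition, i, selection = sel$first,
                     accountant = acct, label = as.character(i))
    recs <- b1$records
    if (j != i) {
      b2 <- load_block(store, partition, j, selection = sel$second,
                       accountant = acct, label = as.character(j))
      recs <- c(recs, b2$records)
    }
    tasks <- enumerate_step_pairs("sparse", partition, i, j,
                                  buckets = buckets)
    score_and_write(tasks, recs, scorer, config, writer,
                    prefetch = function() NULL)
    evict_block(acct, as.character(i))
    if (j != i) evict_block(acct, as.character(j))
    if (config$verbose) {
      message(sprintf("[sparse] block pair %d/%d (%d,%d): %d pairs scored",
                      t, length(schedule), i, j, nrow(tasks)))
    }
  }
}

# Score one step's tasks on the worker pool and hand results to the single
# writer. Tasks are cut into chunks so that at most `buffer_capacity` tasks
# are in flight; with more than one worker the chunks run as forked
# processes (copy-on-write shared embeddings) and the next block is
# prefetched while the first wave is in flight.
score_and_write <- function(tasks, recs, scorer, config, writer, prefetch) {
  n <- nrow(tasks)
  if (n == 0L) { prefetch(); return(invisible(NULL)) }
  W <- config$n_workers
  chunk_size <- max(1L, min(ceiling(n / W),
                            config$buffer_capacity %/% W))
  starts <- seq.int(1L, n, by = chunk_size)
  chunks <- lapply(starts, function(s) {
    tasks[s:min(s + chunk_size - 1L, n), , drop = FALSE]
  })

  score_chunk <- function(chunk) {
    out <- numeric(nrow(chunk))
    for (r in seq_len(nrow(chunk))) {
      out[r] <- tryCatch(
        score_pair(scorer, recs[[chunk$id1[r]]], recs[[chunk$id2[r]]]),
        error = function(e) {
          stop(sprintf("scoring failed for pair (%s, %s): %s",
                       chunk$id1[r], chunk$id2[r], conditionMessage(e)),
               call. = FALSE)
        })
    }
    out
  }

  prefetched <- FALSE
  if (W == 1L) {
    prefetch(); prefetched <- TRUE
    for (chunk in chunks) {
      chunk$score <- score_chunk(chunk)
      writer$write(chunk)
    }
    return(invisible(NULL))
  }

  k <- 1L
  while (k <= length(chunks)) {
    wave <- chunks[seq.int(k, min(k + W - 1L, length(chunks)))]
    jobs <- lapply(wave, function(chunk) {
      parallel::mcparallel(try(score_chunk(chunk), silent = TRUE))
    })
    if (!prefetched) { prefetch(); prefetched <- TRUE }
    res <- parallel::mccollect(jobs, wait = TRUE)
    for (w in seq_along(wave)) {
      scores <- res[[w]]
      if (is.null(scores) || inherits(scores, "try-error")) {
        stop("worker failed; aborting run: ",
             if (is.null(scores)) "worker process died" else
               trimws(as.character(scores)), call. = FALSE)
      }
      chunk <- wave[[w]]
      chunk$score <- scores
      writer$write(chunk)
    }
    k <- k + length(wave)
  }
  invisible(NULL)
}

load_block_by_label <- function(label, partition, partition2, store, store2,
                                acct) {
  if (startsWith(label, "A")) {
    load_block(store, partition, as.integer(sub("^A", "", label)),
               accountant = acct, label = label)
  } else if (startsWith(label, "B") && !is.null(partition2)) {
    load_block(store2, partition2, as.integer(sub("^B", "", label)),
               accountant = acct, label = label)
  } else {
    load_block(store, partition, as.integer(label), accountant = acct,
               label = label)
  }
}

# Canonical re-sort of the two output files (by catalog position of id1,
# then id2), for runs asked for deterministic row order.
sort_outputs <- function(summary, catalog, catalog2 = NULL) {
  cat2 <- if (is.null(catalog2)) catalog else catalog2
  for (path in unlist(summary$files)) {
    df <- read_predictions(path)
    o <- order(match(df$id1, catalog$ids), match(df$id2, cat2$ids))
    df <- df[o, , drop = FALSE]
    con <- file(path, open = "wt")
    writeLines("id1\tid2\tscore", con)
    if (nrow(df) > 0L) {
      writeLines(sprintf("%s\t%s\t%.6f", df$id1, df$id2, df$score), con)
    }
    close(con)
  }
  invisible(summary)
}

write_run_log <- function(summary, path) {
  lines <- c(
    sprintf("mode\t%s", summary$mode),
    sprintf("blocks\t%d", summary$n_blocks),
    sprintf("workers\t%d", summary$n_workers),
    sprintf("threshold\t%g", summary$threshold),
    sprintf("pairs_scored\t%d", summary$pairs_scored),
    sprintf("positives\t%d", summary$n_positive),
    sprintf("peak_resident_blocks\t%d", summary$peak_resident_blocks),
    sprintf("total_block_loads\t%d", summary$total_loads),
    sprintf("loaded_proteins\t%g", summary$loaded_proteins),
    sprintf("loaded_bytes\t%g", summary$loaded_bytes))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.bpi_run <- function(x, ...) {
  cat(sprintf(
    paste0("<bpi_run:%s> B=%d W=%d | %d pairs scored, %d positive | ",
           "peak %d resident blocks, %d loads\n"),
    x$mode, x$n_blocks, x$n_workers, x$pairs_scored, x$n_positive,
    x$peak_resident_blocks, x$total_loads))
  invisible(x)
}
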