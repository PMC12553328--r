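#' Serpentine schedule over all block pairs
#'
#' Emits every block pair `(i, j)` with `1 <= i <= j <= B` exactly once.
#' Rows are visited in order; within row `i` the column `j` ascends from `i`
#' to `B` when `i` is odd and descends from `B` to `i` when `i` is even.
#' Consecutive steps therefore share at least one block, so at most one new
#' block must be loaded per transition, and — with the eviction policy
#' annotated onto the steps — at most three blocks are ever resident.
#'
#' Each step is annotated with the blocks newly loaded before it executes and
#' the blocks evicted once it is no longer needed. The eviction policy is
#' deterministic: after satisfying step `t`, every resident block required by
#' neither step `t` nor step `t + 1` is released.
#'
#' @param n_blocks Number of blocks `B >= 1`.
#' @return A `block_schedule` (see [schedule_table()] for a tabular view).
#' @examples
#' s <- serpentine_schedule(3)
#' schedule_table(s)[, c("i", "j")]
#' @export
serpentine_schedule <- function(n_blocks) {
  B <- as.integer(assert_count(n_blocks, "n_blocks"))
  if (B < 1L) stop("`n_blocks` must be at least 1", call. = FALSE)
  i <- integer(0); j <- integer(0)
  for (r in seq_len(B)) {
    cols <- if (r %% 2L == 1L) r:B else B:r
    i <- c(i, rep.int(r, length(cols)))
    j <- c(j, cols)
  }
  new_schedule(kind = "all_pairs", i = i, j = j,
               labels_i = as.character(i), labels_j = as.character(j),
               dims = c(n_blocks = B))
}

#' Serpentine schedule over bipartite block pairs
#'
#' Emits every cross block pair `(a, b)` with `a` in `1..p` (first catalog)
#' and `b` in `1..q` (second catalog) exactly once, traversing `b` ascending
#' on odd rows and descending on even rows so at most one new block is loaded
#' per transition. Blocks of the two catalogs are distinct identities, written
#' `A1..Ap` and `B1..Bq` in reports.
#'
#' @param p,q Block counts for the two catalogs.
#' @return A `block_schedule`.
#' @export
bipartite_schedule <- function(p, q) {
  p <- as.integer(assert_count(p, "p"))
  q <- as.integer(assert_count(q, "q"))
  if (p < 1L || q < 1L) stop("block counts must be at least 1", call. = FALSE)
  a <- integer(0); b <- integer(0)
  for (r in seq_len(p)) {
    cols <- if (r %% 2L == 1L) 1L:q else q:1L
    a <- c(a, rep.int(r, q))
    b <- c(b, cols)
  }
  new_schedule(kind = "bipartite", i = a, j = b,
               labels_i = paste0("A", a), labels_j = paste0("B", b),
               dims = c(p = p, q = q))
}

# Annotate a step sequence with loads/evicts under the keep-if-needed-now-or-
# next eviction policy, and record the resident set after each step.
new_schedule <- function(kind, i, j, labels_i, labels_j, dims) {
  n <- length(i)
  need <- lapply(seq_len(n), function(t) unique(c(labels_i[t], labels_j[t])))
  loads <- evicts <- resident <- vector("list", n)
  res <- character(0)
  for (t in seq_len(n)) {
    loads[[t]] <- setdiff(need[[t]], res)
    res <- c(res, loads[[t]])
    keep <- if (t < n) union(need[[t]], need[[t + 1L]]) else need[[t]]
    evicts[[t]] <- setdiff(res, keep)
    res <- setdiff(res, evicts[[t]])
    resident[[t]] <- res
  }
  structure(
    list(kind = kind, i = i, j = j,
         labels_i = labels_i, labels_j = labels_j,
         loads = loads, evicts = evicts, resident = resident,
         dims = dims),
    class = "block_schedule")
}

#' @export
length.block_schedule <- function(x) length(x$i)

#' @export
print.block_schedule <- function(x, ...) {
  led <- simulate_memory(x)
  cat(sprintf(
    "<block_schedule:%s> %d steps, %d loads, peak %d resident blocks\n",
    x$kind, length(x), led$total_loads, led$peak_resident_blocks))
  invisible(x)
}

#' Tabular view of a block-pair schedule
#'
#' One row per step: step number, block indices, blocks loaded before the
#' step, blocks evicted after it, and the resident count while the step is
#' executing (after its loads, before its evicts). Suitable for TSV export by
#' the `plan` subcommand.
#'
#' @param schedule A `block_schedule`.
#' @return A data.frame with columns `step`, `i`, `j`, `loads`, `evicts`,
#'   `resident_count`; multi-block cells are comma-joined.
#' @export
schedule_table <- function(schedule) {
  stopifnot(inherits(schedule, "block_schedule"))
  n <- length(schedule)
  data.frame(
    step = seq_len(n),
    i = schedule$i,
    j = schedule$j,
    loads = vapply(schedule$loads, paste, character(1), collapse = ","),
    evicts = vapply(schedule$evicts, paste, character(1), collapse = ","),
    resident_count = vapply(seq_len(n), function(t) {
      length(union(schedule$resident[[t]], schedule$evicts[[t]]))
    }, integer(1)),
    stringsAsFactors = FALSE)
}

#' Replay a schedule's loads and evicts into a memory ledger
#'
#' Simulates the residency history a schedule implies, without touching any
#' embeddings: per-step resident sets, the peak number of simultaneously
#' resident blocks, the total number of block loads, and — when partitions
#' are supplied — the total load volume in proteins (and bytes, when the
#' partitions carry catalogs with lengths and `dim` is given).
#'
#' For serpentine all-pairs schedules the peak is at most `min(B, 3)` and the
#' total number of loads at most `B(B+1)/2 + 1`; the simulator verifies, at
#' every step, that the step's own blocks are resident when it executes and
#' raises a schedule-integrity error otherwise.
#'
#' @param schedule A `block_schedule`.
#' @param partition Optional [block_partition()] for the (first) catalog,
#'   used to convert block loads into protein counts.
#' @param partition2 Optional partition of the second catalog (bipartite).
#' @param dim Optional embedding dimensionality for byte accounting
#'   (4-byte floats).
#' @return An object of class `memory_ledger` with fields `resident_trace`,
#'   `peak_resident_blocks`, `total_loads`, `load_volume_proteins`,
#'   `load_volume_bytes`.
#' @examples
#' simulate_memory(serpentine_schedule(64))$peak_resident_blocks # 3
#' @export
simulate_memory <- function(schedule, partition = NULL, partition2 = NULL,
                            dim = NULL) {
  stopifnot(inherits(schedule, "block_schedule"))
  n <- length(schedule)
  res <- character(0)
  trace <- vector("list", n)
  peak <- 0L
  total_loads <- 0L
  vol_proteins <- if (is.null(partition)) NA_real_ else 0
  vol_bytes <- if (is.null(partition) || is.null(dim) ||
                   is.null(partition$catalog$lengths)) NA_real_ else 0
  for (t in seq_len(n)) {
    res <- c(res, schedule$loads[[t]])
    need <- unique(c(schedule$labels_i[t], schedule$labels_j[t]))
    if (!all(need %in% res)) {
      stop(sprintf(
        "schedule integrity violated at step %d: block(s) %s not resident",
        t, paste(setdiff(need, res), collapse = ", ")), call. = FALSE)
    }
    total_loads <- total_loads + length(schedule$loads[[t]])
    peak <- max(peak, length(res))
    for (lab in schedule$loads[[t]]) {
      info <- block_label_info(lab, partition, partition2)
      if (!is.na(vol_proteins)) vol_proteins <- vol_proteins + info$n
      if (!is.na(vol_bytes)) vol_bytes <- vol_bytes + info$residues * dim * 4
    }
    res <- setdiff(res, schedule$evicts[[t]])
    trace[[t]] <- res
  }
  structure(
    list(resident_trace = trace,
         peak_resident_blocks = peak,
         total_loads = total_loads,
         load_volume_proteins = vol_proteins,
         load_volume_bytes = vol_bytes),
    class = "memory_ledger")
}

# Resolve a block label ("3", "A2", "B5") to its partition slice size and
# residue total.
block_label_info <- function(label, partition, partition2) {
  if (is.null(partition)) return(list(n = NA_integer_, residues = NA_real_))
  part <- partition
  idx <- label
  if (grepl("^A", label)) {
    idx <- sub("^A", "", label)
  } else if (grepl("^B", label)) {
    part <- if (is.null(partition2)) partition else partition2
    idx <- sub("^B", "", label)
  }
  b <- as.integer(idx)
  pos <- block_positions(part, b)
  residues <- if (is.null(part$catalog$lengths)) NA_real_ else
    sum(part$catalog$lengths[pos])
  list(n = length(pos), residues = residues)
}

#' @export
print.memory_ledger <- function(x, ...) {
  cat(sprintf(
    "<memory_ledger> peak %d resident blocks, %d loads, %s proteins loaded\n",
    x$peak_resident_blocks, x$total_loads,
    if (is.na(x$load_volume_proteins)) "?" else
      format(x$load_volume_proteins, big.mark = ",")))
  invisible(x)
}
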