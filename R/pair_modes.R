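#' Candidate pair set
#'
#' A validated, canonicalized, de-duplicated set of protein id pairs against
#' one catalog (some-pairs / sparse modes) or two catalogs (bipartite mode).
#' Within one catalog a pair is stored with the lower catalog position first;
#' across two catalogs the first-catalog protein is always first and pairs
#' are never flipped.
#'
#' @param id1,id2 Character vectors of protein ids, one pair per element.
#' @param catalog The [protein_catalog()] the ids must belong to.
#' @param catalog2 Optional second catalog (bipartite); `id1` entries must
#'   then come from `catalog` and `id2` entries from `catalog2`.
#' @param allow_self Keep self-pairs `(u, u)` (single-catalog only).
#' @return An object of class `candidate_pairs`: data.frame with columns
#'   `id1`, `id2`, `pos1`, `pos2` (catalog positions), plus attributes
#'   `bipartite` and `n_dropped` (duplicates removed).
#' @export
candidate_pairs <- function(id1, id2, catalog, catalog2 = NULL,
                            allow_self = FALSE) {
  stopifnot(inherits(catalog, "protein_catalog"))
  id1 <- as.character(id1); id2 <- as.character(id2)
  if (length(id1) != length(id2)) {
    stop("`id1` and `id2` must have equal length", call. = FALSE)
  }
  bipartite <- !is.null(catalog2)

  pos1 <- match(id1, catalog$ids)
  pos2 <- match(id2, if (bipartite) catalog2$ids else catalog$ids)
  unknown <- unique(c(id1[is.na(pos1)], id2[is.na(pos2)]))
  if (length(unknown) > 0L) {
    stop("pair list references ids absent from the catalog",
         if (bipartite) "s" else "", ": ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }

  if (!bipartite) {
    flip <- pos1 > pos2
    tmp <- pos1[flip]; pos1[flip] <- pos2[flip]; pos2[flip] <- tmp
    tmp <- id1[flip]; id1[flip] <- id2[flip]; id2[flip] <- tmp
    if (!allow_self && any(pos1 == pos2)) {
      keep <- pos1 != pos2
      id1 <- id1[keep]; id2 <- id2[keep]
      pos1 <- pos1[keep]; pos2 <- pos2[keep]
    }
  }

  dup <- duplicated(cbind(pos1, pos2))
  n_dropped <- sum(dup)
  df <- data.frame(id1 = id1[!dup], id2 = id2[!dup],
                   pos1 = pos1[!dup], pos2 = pos2[!dup],
                   stringsAsFactors = FALSE)
  o <- order(df$pos1, df$pos2)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("candidate_pairs", "data.frame"),
            bipartite = bipartite, n_dropped = n_dropped)
}

#' Read a candidate pair list from TSV
#'
#' Two tab-separated id columns, no header; blank lines and lines starting
#' with `#` are ignored. Rows are canonicalized and de-duplicated (the
#' number of dropped duplicates is recorded in attribute `n_dropped` and
#' logged); ids absent from the catalog(s) raise a validation error naming
#' the offenders, malformed rows a parse error with the line number.
#'
#' @param path Pair list file.
#' @inheritParams candidate_pairs
#' @param quiet Suppress the duplicate-count message.
#' @return A [candidate_pairs()] set.
#' @export
read_pairs <- function(path, catalog, catalog2 = NULL, allow_self = FALSE,
                       quiet = FALSE) {
  if (!file.exists(path)) stop("pair file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  rows <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed pair row at line %d of %s (need 2 tab-separated ids)",
                 rows[bad[1L]], path), call. = FALSE)
  }
  id1 <- vapply(fields, `[[`, character(1), 1L)
  id2 <- vapply(fields, `[[`, character(1), 2L)
  ps <- candidate_pairs(id1, id2, catalog, catalog2, allow_self = allow_self)
  if (!quiet && attr(ps, "n_dropped") > 0L) {
    message(sprintf("read_pairs: dropped %d duplicate pair(s)",
                    attr(ps, "n_dropped")))
  }
  ps
}

#' Assign candidate pairs to block-pair buckets
#'
#' Each pair `(u, v)` belongs to exactly one bucket, keyed by the block pair
#' `(block(u), block(v))` normalized to `i <= j` (single catalog) or by
#' `(block_A(u), block_B(v))` (bipartite; never normalized across sets).
#' Buckets are built once up front so that the scheduler can skip loading
#' work for empty block pairs and sparse mode can derive per-block protein
#' selections.
#'
#' @param pairs A [candidate_pairs()] set.
#' @param partition Catalog partition (first catalog in bipartite mode).
#' @param partition2 Second-catalog partition (bipartite only).
#' @return A `pair_buckets` object: named list of integer row-index vectors
#'   into `pairs`, with names `"i,j"`; attributes keep the pair set and
#'   partitions.
#' @export
bucket_pairs <- function(pairs, partition, partition2 = NULL) {
  stopifnot(inherits(pairs, "candidate_pairs"),
            inherits(partition, "block_partition"))
  bipartite <- isTRUE(attr(pairs, "bipartite"))
  if (bipartite && is.null(partition2)) {
    stop("bipartite pair set needs `partition2`", call. = FALSE)
  }
  b1 <- block_of(partition, pairs$pos1)
  b2 <- block_of(if (bipartite) partition2 else partition, pairs$pos2)
  if (!bipartite) {
    lo <- pmin(b1, b2); hi <- pmax(b1, b2)
    b1 <- lo; b2 <- hi
  }
  key <- paste(b1, b2, sep = ",")
  buckets <- split(seq_len(nrow(pairs)), key)
  structure(buckets, class = "pair_buckets", pairs = pairs,
            bipartite = bipartite)
}

bucket_rows <- function(buckets, i, j) {
  buckets[[paste(i, j, sep = ",")]]
}

#' Proteins each block must load for one block pair (sparse mode)
#'
#' Returns exactly the proteins of each block that appear in the bucket's
#' candidate pairs for block pair `(i, j)` — the selections sparse-loading
#' mode passes to [load_block()]. An empty bucket yields empty selections
#' and the step can be skipped entirely.
#'
#' @param buckets A [bucket_pairs()] result.
#' @param i,j Block pair (normalized `i <= j`, or `(A-block, B-block)`).
#' @return List with character vectors `first` and `second`; for a diagonal
#'   block pair both name the same block and are identical.
#' @export
sparse_selection <- function(buckets, i, j) {
  stopifnot(inherits(buckets, "pair_buckets"))
  rows <- bucket_rows(buckets, i, j)
  pairs <- attr(buckets, "pairs")
  if (is.null(rows)) {
    return(list(first = character(0), second = character(0)))
  }
  if (!attr(buckets, "bipartite") && i == j) {
    both <- unique(c(pairs$id1[rows], pairs$id2[rows]))
    return(list(first = both, second = both))
  }
  list(first = unique(pairs$id1[rows]), second = unique(pairs$id2[rows]))
}

#' Pair tasks for one schedule step
#'
#' Enumerates the protein pairs a block-pair step must score, per mode:
#' \describe{
#'   \item{all_pairs}{every cross pair of the two blocks for `i < j`; every
#'     unordered pair of distinct proteins within the block for `i = j`
#'     (self-pairs `(u, u)` only when `include_self`).}
#'   \item{some_pairs / sparse}{exactly the bucket's candidate pairs.}
#'   \item{bipartite}{every cross pair between the step's A-block and
#'     B-block.}
#' }
#' Flattened over a whole schedule, the union of these tasks is exactly the
#' requested pair set, each pair once — the engine's central correctness
#' property.
#'
#' @param mode One of `"all_pairs"`, `"some_pairs"`, `"sparse"`,
#'   `"bipartite"`.
#' @param partition Catalog partition (first catalog in bipartite mode).
#' @param i,j The step's block pair.
#' @param buckets [bucket_pairs()] result (`some_pairs` / `sparse`).
#' @param partition2 Second-catalog partition (bipartite).
#' @param include_self Include within-block self-pairs (all_pairs only).
#' @return data.frame with columns `id1`, `id2` in canonical order.
#' @export
enumerate_step_pairs <- function(mode = c("all_pairs", "some_pairs", "sparse",
                                          "bipartite"),
                                 partition, i, j, buckets = NULL,
                                 partition2 = NULL, include_self = FALSE) {
  mode <- match.arg(mode)
  if (mode %in% c("some_pairs", "sparse")) {
    stopifnot(inherits(buckets, "pair_buckets"))
    rows <- bucket_rows(buckets, i, j)
    pairs <- attr(buckets, "pairs")
    return(data.frame(id1 = pairs$id1[rows], id2 = pairs$id2[rows],
                      stringsAsFactors = FALSE))
  }
  if (mode == "bipartite") {
    a_ids <- block_members(partition, i)
    b_ids <- block_members(partition2, j)
    grid <- expand.grid(id2 = b_ids, id1 = a_ids,
                        stringsAsFactors = FALSE)[, c("id1", "id2")]
    rownames(grid) <- NULL
    return(grid)
  }
  # all_pairs
  if (i != j) {
    a_ids <- block_members(partition, i)
    b_ids <- block_members(partition, j)
    grid <- expand.grid(id2 = b_ids, id1 = a_ids,
                        stringsAsFactors = FALSE)[, c("id1", "id2")]
    rownames(grid) <- NULL
    return(grid)
  }
  ids <- block_members(partition, i)
  n <- length(ids)
  if (n == 0L) return(data.frame(id1 = character(0), id2 = character(0)))
  idx <- which(upper.tri(matrix(0, n, n), diag = include_self),
               arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  data.frame(id1 = ids[idx[, "row"]], id2 = ids[idx[, "col"]],
             stringsAsFactors = FALSE)
}
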