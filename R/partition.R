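#' Partition a catalog into contiguous, balanced blocks
#'
#' Splits the catalog into `n_blocks` contiguous slices in catalog order.
#' Sizes are balanced to within one protein: with `n` proteins and `B`
#' blocks, the first `n mod B` blocks hold `ceiling(n / B)` proteins and the
#' remainder hold `floor(n / B)`. Contiguity keeps loading a block a single
#' sequential scan of the embedding store.
#'
#' @param catalog A [protein_catalog()], or a plain protein count for purely
#'   combinatorial work.
#' @param n_blocks Number of blocks `B`, between 1 and the catalog size.
#' @return An object of class `block_partition` with fields `n_blocks`,
#'   `boundaries` (B + 1 monotone 0-based positions delimiting half-open
#'   slices) and `catalog` (NULL when constructed from a bare count).
#' @examples
#' block_sizes(block_partition(10, 3)) # 4 3 3
#' @export
block_partition <- function(catalog, n_blocks) {
  if (inherits(catalog, "protein_catalog")) {
    n <- length(catalog)
  } else {
    n <- as.integer(assert_count(catalog, "catalog"))
    catalog <- NULL
  }
  n_blocks <- as.integer(assert_count(n_blocks, "n_blocks"))
  if (n_blocks < 1L || n_blocks > n) {
    stop(sprintf("`n_blocks` must be between 1 and the catalog size (%d)", n),
         call. = FALSE)
  }
  base <- n %/% n_blocks
  extra <- n %% n_blocks
  sizes <- rep(c(base + 1L, base), c(extra, n_blocks - extra))
  structure(
    list(n_blocks = n_blocks,
         boundaries = cumsum(c(0L, sizes)),
         catalog = catalog),
    class = "block_partition")
}

#' Block sizes of a partition
#' @param partition A [block_partition()].
#' @return Integer vector of per-block protein counts.
#' @export
block_sizes <- function(partition) {
  stopifnot(inherits(partition, "block_partition"))
  diff(partition$boundaries)
}

#' Catalog positions belonging to a block
#' @param partition A [block_partition()].
#' @param block_index 1-based block index.
#' @return Integer vector of 1-based catalog positions.
#' @export
block_positions <- function(partition, block_index) {
  stopifnot(inherits(partition, "block_partition"))
  b <- as.integer(block_index)
  if (b < 1L || b > partition$n_blocks) {
    stop("block index out of range", call. = FALSE)
  }
  seq.int(partition$boundaries[b] + 1L, partition$boundaries[b + 1L])
}

#' Protein ids belonging to a block
#' @inheritParams block_positions
#' @return Character vector of ids (requires a catalog-backed partition).
#' @export
block_members <- function(partition, block_index) {
  if (is.null(partition$catalog)) {
    stop("partition was built from a bare count; no ids available",
         call. = FALSE)
  }
  partition$catalog$ids[block_positions(partition, block_index)]
}

#' Block assignment of catalog positions
#' @param partition A [block_partition()].
#' @param positions 1-based catalog positions.
#' @return Integer vector of 1-based block indices.
#' @export
block_of <- function(partition, positions) {
  stopifnot(inherits(partition, "block_partition"))
  findInterval(positions - 1L, partition$boundaries,
               rightmost.closed = FALSE, left.open = FALSE)
}

#' @export
print.block_partition <- function(x, ...) {
  s <- block_sizes(x)
  cat(sprintf("<block_partition> %d proteins in %d blocks (sizes %d-%d)\n",
              sum(s), x$n_blocks, min(s), max(s)))
  invisible(x)
}
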