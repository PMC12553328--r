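#' Sample a fixed fraction of the all-pairs universe
#'
#' Draws `floor(fraction * choose(n, 2))` distinct unordered pairs of distinct
#' proteins uniformly at random from the pair universe of an `n`-protein
#' catalog. The draw is reproducible under `seed` and leaves the caller's RNG
#' state untouched.
#'
#' With `ensure_coverage = TRUE` the sample is post-processed so that every
#' protein appears in at least one pair: each uncovered protein is paired
#' (uncovered proteins with each other first, a random partner for a leftover
#' odd one) and an equal number of redundant pairs — pairs both of whose
#' members occur elsewhere in the sample — is removed, keeping the sample size
#' exact. If the requested sample is smaller than `ceiling(n / 2)` pairs,
#' coverage is impossible and an error is raised.
#'
#' @param n Catalog size (at least 2).
#' @param fraction Fraction of the pair universe to draw, in (0, 1].
#' @param seed Integer seed controlling the draw.
#' @param ensure_coverage Require every protein to appear in the sample.
#' @return A two-column integer matrix of 1-based catalog positions, one row
#'   per pair, canonically ordered (`i < j`, rows sorted by `i` then `j`).
#'   Attributes `n`, `fraction` and `seed` record the call.
#' @examples
#' p <- sample_pair_fraction(10, 0.5, seed = 1)
#' nrow(p) # floor(0.5 * 45) = 22
#' @export
sample_pair_fraction <- function(n, fraction, seed, ensure_coverage = FALSE) {
  n <- assert_count(n, "n")
  if (n < 2) stop("need at least 2 proteins to form pairs", call. = FALSE)
  if (length(fraction) != 1L || !is.numeric(fraction) || !is.finite(fraction) ||
      fraction <= 0 || fraction > 1) {
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  }
  universe <- count_all_pairs(n)
  # floor of the exact product; nudge past binary representation error of
  # `fraction` (e.g. 0.3 * 10 evaluating to 2.9999...96)
  k <- floor(fraction * universe * (1 + 1e-12) + 1e-9)
  if (ensure_coverage && k < ceiling(n / 2)) {
    stop(sprintf(
      "coverage infeasible: %d pairs cannot cover %d proteins (need >= %d)",
      k, n, ceiling(n / 2)), call. = FALSE)
  }

  with_seed(seed, {
    idx <- sample_distinct_indices(universe, k)
    pairs <- decode_pair_index(idx, n)
    if (ensure_coverage && k > 0) pairs <- repair_coverage(pairs, n)
  })

  o <- order(pairs[, 1L], pairs[, 2L])
  pairs <- pairs[o, , drop = FALSE]
  dimnames(pairs) <- list(NULL, c("i", "j"))
  structure(pairs, n = as.integer(n), fraction = fraction, seed = seed)
}

# k distinct uniform draws from 0 .. (universe - 1). sample.int covers any
# universe addressable as an R integer; beyond that fall back to rejection
# sampling (fine while k << universe, which is the only regime where a
# universe that large is sampled at all).
sample_distinct_indices <- function(universe, k) {
  if (k == 0) return(numeric(0))
  if (universe <= .Machine$integer.max) {
    return(as.double(sample.int(universe, k)) - 1)
  }
  got <- numeric(0)
  while (length(got) < k) {
    need <- k - length(got)
    got <- unique(c(got, floor(runif(ceiling(need * 1.05)) * universe)))
  }
  got[seq_len(k)]
}

# Map 0-based linear indices of the row-major upper triangle (i < j) of an
# n x n grid back to 1-based (i, j). Row r (0-based) starts at offset
# r*(n-1) - r*(r-1)/2; the closed-form inverse via sqrt is corrected by a
# bounded walk to guard against floating-point edge error.
decode_pair_index <- function(idx, n) {
  if (length(idx) == 0) {
    return(matrix(integer(0), ncol = 2L))
  }
  row_offset <- function(r) r * (n - 1) - r * (r - 1) / 2
  a <- 2 * n - 1
  r <- floor((a - sqrt(a * a - 8 * idx)) / 2)
  r <- pmin(pmax(r, 0), n - 2)
  for (pass in 1:3) {
    over <- row_offset(r) > idx
    r[over] <- r[over] - 1
    under <- row_offset(r + 1) <= idx
    r[under] <- r[under] + 1
    if (!any(over) && !any(under)) break
  }
  j <- idx - row_offset(r) + r + 1
  cbind(as.integer(r) + 1L, as.integer(j) + 1L)
}

# Guarantee every protein 1..n occurs in `pairs` without changing nrow.
# Each uncovered protein displaces one endpoint of a pair whose endpoint
# has degree >= 2, so no protein loses coverage and the new pair cannot
# duplicate an existing one (the uncovered protein appears nowhere yet).
# With k >= ceiling(n / 2) pairs such an endpoint always exists while any
# protein is uncovered (all degrees <= 1 would cover only 2k < n proteins).
repair_coverage <- function(pairs, n) {
  deg <- tabulate(pairs, nbins = n)
  uncovered <- which(deg == 0L)
  if (length(uncovered) == 0L) return(pairs)
  if (length(uncovered) > 1L) {
    uncovered <- uncovered[sample.int(length(uncovered))]
  }
  for (u in uncovered) {
    slack1 <- deg[pairs[, 1L]] > 1L
    slack2 <- deg[pairs[, 2L]] > 1L
    eligible <- which(slack1 | slack2)
    if (length(eligible) == 0L) {
      stop("coverage infeasible: sample too small to cover every protein",
           call. = FALSE)
    }
    r <- eligible[sample.int(length(eligible), 1L)]
    side <- if (deg[pairs[r, 1L]] > 1L) 1L else 2L
    old <- pairs[r, side]
    deg[old] <- deg[old] - 1L
    deg[u] <- 1L
    pairs[r, side] <- u
    pairs[r, ] <- sort(pairs[r, ])
  }
  pairs
}

# Evaluate `expr` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
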