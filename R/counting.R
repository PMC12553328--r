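#' Number of unordered pairs of distinct proteins
#'
#' The size of the all-pairs universe for a catalog of `n` proteins:
#' \eqn{n(n-1)/2}. Self-pairs are excluded.
#'
#' Arithmetic keeps every intermediate integral (the even factor is halved
#' first), so the result is exact in double precision for any realistic
#' catalog size (exact up to `2^53`, i.e. `n` beyond 1e8).
#'
#' @param n Non-negative protein count.
#' @return The pair count as a double holding an exact integer value.
#' @examples
#' count_all_pairs(6282) # 19728621
#' @export
count_all_pairs <- function(n) {
  n <- assert_count(n, "n")
  if (n %% 2 == 0) (n / 2) * (n - 1) else n * ((n - 1) / 2)
}

#' Number of cross pairs between two protein sets
#'
#' The bipartite pair universe between a catalog of `m` and a catalog of
#' `n` proteins: \eqn{m \times n}, exact.
#'
#' @param m,n Non-negative protein counts for the two sets.
#' @return The product as a double holding an exact integer value.
#' @examples
#' count_bipartite_pairs(928, 12563) # 11658464
#' @export
count_bipartite_pairs <- function(m, n) {
  m <- assert_count(m, "m")
  n <- assert_count(n, "n")
  m * n
}

#' Density of the bipartite cross-pair set within the pooled all-pairs universe
#'
#' When two protein sets of sizes `m` and `n` are pooled into one catalog of
#' `m + n` proteins, only \eqn{mn} of the \eqn{\binom{m+n}{2}} unordered pairs
#' cross the two sets. This returns that share as a percentage; callers may
#' round to an integer percent.
#'
#' @param m,n Set sizes; `m + n` must be at least 2.
#' @return Percentage in (0, 100].
#' @examples
#' round(pair_density_percent(928, 12563)) # 13
#' @export
pair_density_percent <- function(m, n) {
  m <- assert_count(m, "m")
  n <- assert_count(n, "n")
  if (m + n < 2L) {
    stop("pair universe of fewer than 2 proteins has no pairs", call. = FALSE)
  }
  100 * count_bipartite_pairs(m, n) / count_all_pairs(m + n)
}

# Shared validation for counting arguments: single finite non-negative whole
# number, returned as double.
assert_count <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < 0 ||
      x != trunc(x)) {
    stop(sprintf("`%s` must be a single non-negative integer", name),
         call. = FALSE)
  }
  as.double(x)
}
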