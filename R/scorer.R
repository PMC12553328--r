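#' Pairwise scorer interface
#'
#' The engine is agnostic to the prediction model: any object of class
#' `pair_scorer` can be plugged in. A scorer wraps a function of two
#' embedding matrices returning a score in [0, 1], plus an optional declared
#' embedding dimensionality that incoming arrays are checked against.
#'
#' @param fn `function(e1, e2)` returning a single numeric in [0, 1].
#' @param dim Optional embedding dimensionality the scorer expects; arrays
#'   with a different number of columns raise a scorer error.
#' @param name Human-readable scorer name for logs.
#' @return A `pair_scorer`.
#' @export
pair_scorer <- function(fn, dim = NULL, name = "custom") {
  stopifnot(is.function(fn))
  structure(list(fn = fn, dim = if (is.null(dim)) NULL else as.integer(dim),
                 name = name),
            class = "pair_scorer")
}

#' Deterministic mock scorer
#'
#' `logistic(mean(E1) + mean(E2))`: symmetric in its arguments,
#' deterministic, spans (0, 1), and cheap — a stand-in for a trained PPI
#' model that lets the scheduling, loading and writing machinery be
#' exercised and verified exactly (blocked output must be bit-identical to
#' the serial reference).
#'
#' @inheritParams pair_scorer
#' @return A `pair_scorer`.
#' @examples
#' s <- mock_scorer()
#' score_pair(s, matrix(0, 3, 2), matrix(0, 5, 2)) # 0.5
#' @export
mock_scorer <- function(dim = NULL) {
  pair_scorer(function(e1, e2) stats::plogis(mean(e1) + mean(e2)),
              dim = dim, name = "mock-logistic")
}

#' Score one pair of embeddings
#'
#' @param scorer A [pair_scorer()].
#' @param e1,e2 Non-empty embedding matrices (`length x dim`).
#' @return Score in [0, 1].
#' @export
score_pair <- function(scorer, e1, e2) {
  stopifnot(inherits(scorer, "pair_scorer"))
  if (length(e1) == 0L || length(e2) == 0L) {
    stop("cannot score empty embeddings", call. = FALSE)
  }
  if (!is.null(scorer$dim) &&
      (ncol(e1) != scorer$dim || ncol(e2) != scorer$dim)) {
    stop(sprintf("scorer expects dim %d, got %d and %d",
                 scorer$dim, ncol(e1), ncol(e2)), call. = FALSE)
  }
  s <- scorer$fn(e1, e2)
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0 || s > 1) {
    stop("scorer returned an invalid score (need a single value in [0, 1])",
         call. = FALSE)
  }
  as.double(s)
}
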