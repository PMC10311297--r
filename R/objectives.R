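#' Ensemble defect of a target in an ensemble
#'
#' The expected structure distance between the target `y*` and a
#' structure drawn from the Boltzmann ensemble,
#' `n - 2 * sum_{(i,j) in pairs(y*)} p_ij - sum_{j in unpaired(y*)} q_j`.
#' The identity with the expectation form holds because the distance
#' decomposes over positions; it lets the defect be computed from the
#' base-pair probability matrix without enumerating the ensemble.
#'
#' The returned value is the *unnormalized* defect in `[0, n]` (the
#' natural scale for the positional decomposition); divide by `n`, or
#' use [objective_value()], for the normalized version in `[0, 1]`.
#'
#' @param summary An `ensemble_summary` (from a backend's `ensemble()`).
#' @param y_star Target structure.
#' @return The expected number of incorrectly structured positions.
#' @export
ensemble_defect <- function(summary, y_star) {
  sum(positional_defect(summary, y_star))
}

#' Positional defect decomposition
#'
#' The probability that each position is incorrectly structured with
#' respect to the target: `1 - q_i` for positions unpaired in `y*`, and
#' `1 - p_ij` for positions paired to `j` in `y*`.  The vector sums to
#' the (unnormalized) ensemble defect; it drives defect-weighted
#' position sampling during the search.
#'
#' @inheritParams ensemble_defect
#' @return Numeric vector of length `n` with entries in `[0, 1]`.
#' @export
positional_defect <- function(summary, y_star) {
  y_star <- as_structure(y_star)
  if (y_star$n != summary$n)
    stop("summary and structure have different lengths")
  eps <- numeric(y_star$n)
  eps[y_star$unpaired] <- 1 - summary$unpaired[y_star$unpaired]
  if (nrow(y_star$pairs)) {
    i <- y_star$pairs[, 1L]; j <- y_star$pairs[, 2L]
    p <- summary$bpp[cbind(i, j)]
    eps[i] <- 1 - p
    eps[j] <- 1 - p
  }
  pmin(1, pmax(0, eps))
}

#' Design objective value
#'
#' The quantity the search minimizes, always in `[0, 1]`:
#' * `"prob"`: `1 - p(y* | x)`, one minus the equilibrium probability of
#'   the target;
#' * `"ned"`: the normalized ensemble defect, the mean probability that
#'   a position is incorrectly structured.
#'
#' Both vanish exactly when the ensemble is concentrated on the target.
#'
#' @param x RNA sequence.
#' @param y_star Target structure; must be compatible with `x`.
#' @param objective `"prob"` or `"ned"`.
#' @param backend A [fold_backend] (default: toy model).
#' @param summary Optional precomputed `ensemble_summary` for `x`
#'   (avoids refolding inside the search loop).
#' @return Objective value in `[0, 1]`.
#' @export
objective_value <- function(x, y_star, objective = c("prob", "ned"),
                            backend = toy_backend(), summary = NULL) {
  objective <- match.arg(objective)
  y_star <- as_structure(y_star)
  if (!is_compatible(x, y_star))
    stop("sequence is not compatible with the target structure")
  if (objective == "prob") {
    max(0, min(1, 1 - backend$prob(x, y_star)))
  } else {
    if (is.null(summary)) summary <- backend$ensemble(x)
    ensemble_defect(summary, y_star) / y_star$n
  }
}
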