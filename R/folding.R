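#' Partition function and base-pair probabilities
#'
#' Computes the ensemble summary of a sequence under the built-in
#' nearest-pair model with a McCaskill-style inside-outside dynamic
#' program in `O(n^3)` time: the log partition function `log Q(x)`, the
#' symmetric base-pair probability matrix `p[i, j]` and the per-position
#' unpaired probabilities `q[j] = 1 - sum_i p[i, j]`.  Cells are
#' rescaled per nucleotide so long sequences do not overflow.
#'
#' @param x RNA sequence.
#' @param model An [toy_energy_model()] object.
#' @return An object of class `ensemble_summary` with components `logQ`,
#'   `bpp` (n x n matrix), `unpaired` (length-n vector), `n`, and the
#'   `model` used.
#' @examples
#' s <- partition_function("GAAAC")
#' s$bpp[1, 5]  # probability that the hairpin pair forms
#' @export
partition_function <- function(x, model = toy_energy_model()) {
  codes <- seq_codes(x)
  res <- cpp_partition(codes, unname(model$emat), model$stack_bonus,
                       model$min_hairpin, model$RT)
  structure(
    list(logQ = res$logQ, Q = exp(res$logQ), bpp = res$bpp,
         unpaired = res$unpaired, n = length(codes), sequence = toupper(x),
         model = model),
    class = "ensemble_summary"
  )
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("Ensemble summary: n = %d, log Q = %.6g\n", x$n, x$logQ))
  invisible(x)
}

#' Equilibrium probability of a structure
#'
#' `p(y | x) = exp(-E(x, y) / RT) / Q(x)`, the Boltzmann probability
#' that the sequence adopts exactly this structure at equilibrium.
#' The structure must lie in the sequence's ensemble (all pairs
#' admissible, hairpins long enough); otherwise an error is raised.
#'
#' @inheritParams structure_energy
#' @return A probability in `[0, 1]`.
#' @export
prob_of_structure <- function(x, y, model = toy_energy_model()) {
  e <- structure_energy(x, y, model)   # errors if y is outside the ensemble
  s <- partition_function(x, model)
  exp(-e / model$RT - s$logQ)
}

#' All minimum free energy structures of a sequence
#'
#' Returns the complete argmin set via a zero-slack co-optimal
#' traceback, not just one representative: ties happen (e.g. by
#' symmetry) and the unique-MFE design criterion depends on them.
#'
#' @inheritParams partition_function
#' @param cap Safety cap on the number of co-optimal structures to
#'   enumerate (default `1e5`).
#' @return A character vector of dot-bracket strings, each attaining the
#'   minimum energy; the attribute `energy` holds that minimum.
#' @export
mfe_structures <- function(x, model = toy_energy_model(), cap = 1e5) {
  codes <- seq_codes(x)
  res <- cpp_mfe(codes, unname(model$emat), model$stack_bonus,
                 model$min_hairpin, model$RT, TRUE, cap)
  structure(sort(as.character(res$structures)), energy = res$emin)
}

#' Check the MFE and unique-MFE design criteria
#'
#' A sequence solves a target by the MFE criterion when the target is
#' one of its minimum free energy structures, and by the stricter
#' unique-MFE (uMFE) criterion when it is the only one, i.e. every other
#' structure in the ensemble has strictly higher energy.  Uniqueness is
#' decided by counting co-optimal structures with zero energy slack
#' (the dynamic-programming analogue of enumerating all tied optima),
#' not by an energy-gap heuristic.
#'
#' @param x RNA sequence.
#' @param y_star Target structure.
#' @param model An `energy_model`.
#' @return A list with logical components `satisfies_mfe` and
#'   `satisfies_umfe` (`satisfies_umfe` implies `satisfies_mfe`).
#' @export
check_criterion <- function(x, y_star, model = toy_energy_model()) {
  y_star <- as_structure(y_star)
  codes <- seq_codes(x)
  if (length(codes) != y_star$n)
    stop("sequence and structure have different lengths")
  res <- cpp_mfe(codes, unname(model$emat), model$stack_bonus,
                 model$min_hairpin, model$RT, FALSE, 0)
  e_star <- tryCatch(structure_energy(x, y_star, model),
                     error = function(e) Inf)
  is_mfe <- is.finite(e_star) && e_star <= res$emin + 1e-9
  list(satisfies_mfe = is_mfe,
       satisfies_umfe = is_mfe && res$n_optimal < 1.5)
}

#' Positional entropy of an ensemble
#'
#' Shannon entropy of each position's pairing distribution,
#' `S_i = -sum_j p_ij log p_ij - q_i log q_i` (natural log, with
#' `0 log 0 = 0`).  Low values mean the position's pairing status is
#' well determined in the ensemble.
#'
#' @param summary An `ensemble_summary` from [partition_function()].
#' @return A numeric vector of per-position entropies; the conventional
#'   scalar metric is their mean.
#' @export
positional_entropy <- function(summary) {
  stopifnot(inherits(summary, "ensemble_summary"))
  xlogx <- function(p) ifelse(p > 0, p * log(p), 0)
  rowSums(xlogx(summary$bpp)) * -1 - xlogx(summary$unpaired)
}
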