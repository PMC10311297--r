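#' Design run configuration
#'
#' Collects every knob of the iterative search.  Defaults follow the
#' method's standard setting: a frontier of `k = 10` candidates,
#' candidate-sampling temperature `T = 1`, position-sampling temperature
#' `T' = 2T`, at most `M = 5000` iterations, and early stopping when the
#' best objective drops below 0.01 or fails to improve for 2000
#' consecutive iterations.
#'
#' The five ablation switches disable one search ingredient each while
#' leaving the rest untouched: targeted initialization (`v1`), Boltzmann
#' candidate/position sampling (`v2`, uniform instead), structured
#' mutation (`v3`, single-base / single-pair mutation instead), the
#' multifrontier (`v4`, forces `k = 1`), and byproduct harvesting
#' (`v5`, only the final best sequence is criterion-checked).
#'
#' @param objective `"prob"` (one minus target probability) or `"ned"`
#'   (normalized ensemble defect).
#' @param k Frontier size (>= 1).
#' @param temp Candidate-sampling temperature `T` (> 0).
#' @param t_prime Position-sampling temperature `T'`; default `2 * temp`.
#' @param max_iters Iteration budget `M`.
#' @param converge_eps Stop when the best objective falls below this.
#' @param patience Stop after this many non-improving iterations.
#' @param seed Integer RNG seed, or `NULL` to leave the RNG state alone.
#' @param use_targeted_init,use_boltzmann_sampling,use_structured_mutation,multifrontier,collect_byproducts
#'   Ablation switches, all `TRUE` by default.
#' @return A `design_config` object.
#' @export
design_config <- function(objective = c("prob", "ned"), k = 10L, temp = 1.0,
                          t_prime = 2 * temp, max_iters = 5000L,
                          converge_eps = 0.01, patience = 2000L, seed = NULL,
                          use_targeted_init = TRUE,
                          use_boltzmann_sampling = TRUE,
                          use_structured_mutation = TRUE,
                          multifrontier = TRUE,
                          collect_byproducts = TRUE) {
  objective <- match.arg(objective)
  if (!multifrontier) k <- 1L
  stopifnot(k >= 1, temp > 0, t_prime > 0, max_iters >= 1,
            converge_eps >= 0, converge_eps < 1, patience >= 1)
  structure(
    list(objective = objective, k = as.integer(k), temp = temp,
         t_prime = t_prime, max_iters = as.integer(max_iters),
         converge_eps = converge_eps, patience = as.integer(patience),
         seed = seed,
         use_targeted_init = isTRUE(use_targeted_init),
         use_boltzmann_sampling = isTRUE(use_boltzmann_sampling),
         use_structured_mutation = isTRUE(use_structured_mutation),
         multifrontier = isTRUE(multifrontier),
         collect_byproducts = isTRUE(collect_byproducts)),
    class = "design_config"
  )
}

#' @export
print.design_config <- function(x, ...) {
  cat(sprintf(
    "Design config: objective=%s k=%d T=%g T'=%g M=%d eps=%g patience=%d\n",
    x$objective, x$k, x$temp, x$t_prime, x$max_iters, x$converge_eps,
    x$patience))
  off <- c("targeted init", "Boltzmann sampling", "structured mutation",
           "multifrontier", "byproducts")[
    !c(x$use_targeted_init, x$use_boltzmann_sampling,
       x$use_structured_mutation, x$multifrontier, x$collect_byproducts)]
  if (length(off)) cat("  ablated:", paste(off, collapse = ", "), "\n")
  invisible(x)
}

#' Targeted initialization
#'
#' Builds up to `k` distinct starting sequences from the target alone:
#' every unpaired position gets `A`, and each base pair independently
#' gets `(G, C)` or `(C, G)` with equal probability.  The two sides of
#' every helix are thus complementary, while distinct helices are
#' unlikely to be complementary to each other, which biases the initial
#' ensemble toward the target.  When the structure has `p` pairs only
#' `2^p` distinct sequences exist; if `k` exceeds that, the maximal
#' distinct set is returned with a warning.
#'
#' @param y_star Target structure.
#' @param k Number of distinct sequences requested.
#' @return Character vector of distinct sequences (length `min(k, 2^p)`).
#' @examples
#' set.seed(1)
#' targeted_init("(((...)))..(((...)))", 3)
#' @export
targeted_init <- function(y_star, k = 10L) {
  y_star <- as_structure(y_star)
  stopifnot(k >= 1)
  npairs <- nrow(y_star$pairs)
  total <- if (npairs < 31L) 2^npairs else Inf
  if (total < k) {
    warning(sprintf(
      "structure has %d pairs, only %d distinct targeted sequences exist",
      npairs, as.integer(total)))
    k <- as.integer(total)
  }
  out <- character(0)
  tries <- 0L
  while (length(out) < k && tries < 1000L * k) {
    b <- rep("A", y_star$n)
    if (npairs) {
      gc_first <- runif(npairs) < 0.5
      b[y_star$pairs[, 1L]] <- ifelse(gc_first, "G", "C")
      b[y_star$pairs[, 2L]] <- ifelse(gc_first, "C", "G")
    }
    out <- union(out, paste(b, collapse = ""))
    tries <- tries + 1L
  }
  out
}

# initialization with the targeting ablated: uniform pair types and bases
random_init <- function(y_star, k) {
  y_star <- as_structure(y_star)
  out <- character(0)
  tries <- 0L
  while (length(out) < k && tries < 1000L * k) {
    b <- rep("A", y_star$n)
    if (length(y_star$unpaired))
      b[y_star$unpaired] <- sample(RNA_BASES, length(y_star$unpaired),
                                   replace = TRUE)
    if (nrow(y_star$pairs)) {
      types <- sample.int(6L, nrow(y_star$pairs), replace = TRUE)
      b[y_star$pairs[, 1L]] <- PAIR_TYPES[types, 1L]
      b[y_star$pairs[, 2L]] <- PAIR_TYPES[types, 2L]
    }
    out <- union(out, paste(b, collapse = ""))
    tries <- tries + 1L
  }
  out
}

#' Sample a frontier candidate
#'
#' Draws one index from a frontier with selection probability
#' proportional to `exp((1 - f) / T)`, favouring low-objective
#' candidates; as `T -> 0` the draw concentrates on the best candidate
#' and as `T -> Inf` it becomes uniform.  With `boltzmann = FALSE`
#' (sampling ablation) the draw is uniform.
#'
#' @param objectives Numeric vector of frontier objective values.
#' @param temp Temperature `T` (> 0).
#' @param boltzmann Use the Boltzmann weights (default) or uniform.
#' @return A single index into `objectives`.
#' @export
sample_candidate <- function(objectives, temp = 1.0, boltzmann = TRUE) {
  stopifnot(length(objectives) >= 1, temp > 0)
  if (!boltzmann) return(sample.int(length(objectives), 1L))
  v <- (1 - objectives) / temp
  w <- exp(v - max(v))
  sample.int(length(objectives), 1L, prob = w)
}

#' Sample a mutation position
#'
#' Draws one sequence position with probability proportional to
#' `exp(eps_i / T')`, where `eps_i` is the positional defect, so
#' positions that are most often incorrectly structured in the ensemble
#' are mutated most often.  With `boltzmann = FALSE` the draw is
#' uniform.
#'
#' @param epsilon Positional defect vector (see [positional_defect()]).
#' @param t_prime Temperature `T'` (> 0).
#' @param boltzmann Use defect weighting (default) or uniform.
#' @return A single position index.
#' @export
sample_position <- function(epsilon, t_prime = 2.0, boltzmann = TRUE) {
  stopifnot(length(epsilon) >= 1, t_prime > 0)
  if (!boltzmann) return(sample.int(length(epsilon), 1L))
  v <- epsilon / t_prime
  w <- exp(v - max(v))
  sample.int(length(epsilon), 1L, prob = w)
}

#' Classify the local motif at a position of the target
#'
#' Determines which structured-mutation scenario applies when position
#' `i` is selected, as a deterministic function of the target structure
#' only:
#'
#' * paired positions: `"STACK_PLUS_DOUBLE_MISMATCH"` (pair with inner
#'   stacked pair and an inner mismatch at `i+2`/`j-2`), `"STACK"` (pair
#'   with inner stacked pair), `"PAIRED_DOUBLE_MISMATCH"` (pair with
#'   both inner neighbours unpaired) — tested in that order, preferring
#'   the largest defined local unit;
#' * unpaired positions interior to a pair `(i, j)`:
#'   `"UNPAIRED_DOUBLE_MISMATCH"` (both `i+1` and `j-1` unpaired),
#'   `"MISMATCH_5PRIME"` / `"MISMATCH_3PRIME"` (only one of them
#'   unpaired);
#' * anything else (deep loop interiors, exterior positions, irregular
#'   contexts such as a multiloop branch point): `"TRIVIAL"`.
#'
#' A `"TRIVIAL"` classification at an unpaired position mutates just
#' that base; at a paired position it mutates just that pair, so
#' compatibility with the target is always preserved.
#'
#' @param y_star Target structure.
#' @param i Position (1-based).
#' @return A scenario string.
#' @export
classify_site <- function(y_star, i) {
  mutation_sites(as_structure(y_star), i)$scenario
}

# scenario plus the pair/single position sets it mutates
mutation_sites <- function(y, p) {
  pt <- y$partner
  n <- y$n
  if (p < 1L || p > n) stop("position out of range")
  if (pt[p] != 0L) {
    i <- min(p, pt[p]); j <- max(p, pt[p])
    inner_stack <- i + 1L < j - 1L && pt[i + 1L] == j - 1L
    if (inner_stack && i + 2L < j - 2L && pt[i + 2L] == 0L && pt[j - 2L] == 0L)
      return(list(scenario = "STACK_PLUS_DOUBLE_MISMATCH",
                  pairs = rbind(c(i, j), c(i + 1L, j - 1L)),
                  singles = c(i + 2L, j - 2L)))
    if (inner_stack)
      return(list(scenario = "STACK",
                  pairs = rbind(c(i, j), c(i + 1L, j - 1L)),
                  singles = integer(0)))
    if (i + 1L < j - 1L && pt[i + 1L] == 0L && pt[j - 1L] == 0L)
      return(list(scenario = "PAIRED_DOUBLE_MISMATCH",
                  pairs = rbind(c(i, j)),
                  singles = c(i + 1L, j - 1L)))
    return(list(scenario = "TRIVIAL", pairs = rbind(c(i, j)),
                singles = integer(0)))
  }
  # unpaired: look for an enclosing pair with p adjacent on the inside
  if (p > 1L && pt[p - 1L] > p) {          # p == i + 1 of pair (i, j)
    i <- p - 1L; j <- pt[p - 1L]
    if (j - 1L > p && pt[j - 1L] == 0L)
      return(list(scenario = "UNPAIRED_DOUBLE_MISMATCH",
                  pairs = rbind(c(i, j)), singles = c(p, j - 1L)))
    if (j - 1L > p && pt[j - 1L] != 0L)
      return(list(scenario = "MISMATCH_5PRIME",
                  pairs = rbind(c(i, j)), singles = p))
  }
  if (p < n && pt[p + 1L] != 0L && pt[p + 1L] < p) {  # p == j - 1 of (i, j)
    j <- p + 1L; i <- pt[p + 1L]
    if (i + 1L < p && pt[i + 1L] == 0L)
      return(list(scenario = "UNPAIRED_DOUBLE_MISMATCH",
                  pairs = rbind(c(i, j)), singles = c(i + 1L, p)))
    if (i + 1L < p && pt[i + 1L] != 0L)
      return(list(scenario = "MISMATCH_3PRIME",
                  pairs = rbind(c(i, j)), singles = p))
  }
  list(scenario = "TRIVIAL", pairs = matrix(integer(0), 0, 2), singles = p)
}

#' Enumerate the full proposal space of a structured mutation
#'
#' Lists every sequence reachable by mutating the local motif at
#' position `i` (all joint assignments of the motif's pairs over the six
#' pair types and of its unpaired positions over the four bases), minus
#' the current assignment.  Used to verify the per-scenario proposal
#' counts (35 for a stack, 95 for pair + double mismatch, 575 for stack
#' + double mismatch, 23 for a single mismatch, 3 or 5 for trivial
#' sites) and to check that every proposal stays target-compatible.
#'
#' @param x Current sequence (compatible with `y_star`).
#' @param y_star Target structure.
#' @param i Selected position.
#' @return Character vector of distinct proposal sequences.
#' @export
enumerate_mutations <- function(x, y_star, i) {
  y_star <- as_structure(y_star)
  b <- seq_chars(x)
  if (length(b) != y_star$n)
    stop("sequence and structure have different lengths")
  sites <- mutation_sites(y_star, i)
  npair <- nrow(sites$pairs)
  nsingle <- length(sites$singles)
  grids <- c(rep(list(seq_len(6L)), npair), rep(list(RNA_BASES), nsingle))
  combos <- do.call(expand.grid,
                    c(grids, list(stringsAsFactors = FALSE)))
  out <- character(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    bb <- b
    if (npair) for (q in seq_len(npair)) {
      t <- combos[r, q][[1L]]
      bb[sites$pairs[q, 1L]] <- PAIR_TYPES[t, 1L]
      bb[sites$pairs[q, 2L]] <- PAIR_TYPES[t, 2L]
    }
    if (nsingle) for (q in seq_len(nsingle))
      bb[sites$singles[q]] <- combos[r, npair + q][[1L]]
    out[r] <- paste(bb, collapse = "")
  }
  setdiff(unique(out), paste(b, collapse = ""))
}

#' Apply one structured mutation
#'
#' Mutates the local motif containing position `i` jointly: every pair
#' of the motif is redrawn uniformly over the six admissible pair types
#' and every unpaired motif position uniformly over the four bases,
#' excluding only the current joint assignment (individual positions may
#' keep their base).  The result always differs from `x` and remains
#' compatible with the target.
#'
#' @inheritParams enumerate_mutations
#' @return A mutated sequence.
#' @export
structured_mutation <- function(x, y_star, i) {
  y_star <- as_structure(y_star)
  b <- seq_chars(x)
  sites <- mutation_sites(y_star, i)
  apply_motif_mutation(b, sites)
}

apply_motif_mutation <- function(b, sites) {
  npair <- nrow(sites$pairs)
  cur <- paste(b, collapse = "")
  repeat {
    bb <- b
    if (npair) for (q in seq_len(npair)) {
      t <- sample.int(6L, 1L)
      bb[sites$pairs[q, 1L]] <- PAIR_TYPES[t, 1L]
      bb[sites$pairs[q, 2L]] <- PAIR_TYPES[t, 2L]
    }
    for (p in sites$singles) bb[p] <- sample(RNA_BASES, 1L)
    out <- paste(bb, collapse = "")
    if (out != cur) return(out)
  }
}

# the ablated ("traditional") mutation: one base, or one pair, at i
trivial_mutation <- function(b, y, p) {
  pt <- y$partner
  if (pt[p] == 0L) {
    sites <- list(pairs = matrix(integer(0), 0, 2), singles = p)
  } else {
    sites <- list(pairs = rbind(c(min(p, pt[p]), max(p, pt[p]))),
                  singles = integer(0))
  }
  apply_motif_mutation(b, sites)
}

#' Run one RNA design search
#'
#' The full iterative search: `k` targeted starting sequences seed a
#' frontier of the lowest-objective distinct candidates seen so far;
#' each iteration Boltzmann-samples a frontier candidate, samples one of
#' its positions by positional defect, applies a structured mutation,
#' evaluates the mutant's objective, checks the MFE/uMFE criterion
#' (harvesting successes as byproducts), and updates the frontier.  The
#' run stops when the best objective drops below `converge_eps`, after
#' `patience` non-improving iterations, or at the iteration budget.
#'
#' Given the same target, configuration (including seed) and backend the
#' run is fully reproducible.
#'
#' @param y_star Target structure (`rna_structure` or dot-bracket).
#' @param config A [design_config()].
#' @param backend A [fold_backend].
#' @return A `design_result` list: `x_mfe` and `x_umfe` (character sets
#'   of harvested solutions, `x_umfe` a subset of `x_mfe`), `x_best`
#'   (data frame of final frontier candidates with objectives), `trace`
#'   (best objective after each iteration), `iterations_run`,
#'   `stop_reason` (`"converged"`, `"patience"` or `"max_iters"`),
#'   `n_evaluations`, and the `config`.
#' @examples
#' res <- design("(((...)))", design_config(seed = 1, max_iters = 100))
#' res$stop_reason
#' @export
design <- function(y_star, config = design_config(), backend = toy_backend()) {
  y_star <- as_structure(y_star)
  stopifnot(inherits(config, "design_config"),
            inherits(backend, "fold_backend"))
  if (!is.null(config$seed)) set.seed(config$seed)

  evaluate <- function(x) {
    summ <- backend$ensemble(x)
    eps <- positional_defect(summ, y_star)
    obj <- if (config$objective == "ned") {
      sum(eps) / y_star$n
    } else {
      max(0, min(1, 1 - backend$prob(x, y_star)))
    }
    list(objective = obj, epsilon = eps)
  }

  x_mfe <- character(0)
  x_umfe <- character(0)
  harvest <- function(x) {
    if (x %in% x_mfe) return(invisible())
    crit <- backend$criterion(x, y_star)
    if (isTRUE(crit$satisfies_mfe)) {
      x_mfe <<- c(x_mfe, x)
      if (isTRUE(crit$satisfies_umfe)) x_umfe <<- c(x_umfe, x)
    }
    invisible()
  }

  # frontier: sequences sorted by objective, ties broken by insertion
  # order (earlier wins); epsilon vectors kept for members only
  front_seq <- character(0)
  front_obj <- numeric(0)
  front_eps <- list()
  absorb <- function(x, ev) {
    if (x %in% front_seq) return(invisible())
    if (length(front_seq) < config$k) {
      pos <- length(front_seq) + 1L
    } else if (ev$objective < front_obj[length(front_obj)]) {
      front_seq <<- front_seq[-length(front_seq)]
      front_obj <<- front_obj[-length(front_obj)]
      front_eps[[length(front_eps)]] <<- NULL
      pos <- length(front_seq) + 1L
    } else {
      return(invisible())
    }
    at <- findInterval(ev$objective, front_obj) + 1L  # after ties
    front_seq <<- append(front_seq, x, after = at - 1L)
    front_obj <<- append(front_obj, ev$objective, after = at - 1L)
    front_eps <<- append(front_eps, list(ev$epsilon), after = at - 1L)
    invisible()
  }

  inits <- if (config$use_targeted_init) {
    # small targets admit fewer than k distinct targeted sequences;
    # start from all of them without complaint
    npairs <- nrow(y_star$pairs)
    n_init <- if (npairs < 31L) min(config$k, 2^npairs) else config$k
    targeted_init(y_star, n_init)
  } else {
    random_init(y_star, config$k)
  }
  n_eval <- 0L
  for (x0 in inits) {
    ev <- evaluate(x0)
    n_eval <- n_eval + 1L
    if (config$collect_byproducts) harvest(x0)
    absorb(x0, ev)
  }

  trace <- numeric(0)
  best <- front_obj[1L]
  stale <- 0L
  iters <- 0L
  stop_reason <- "max_iters"
  if (best < config$converge_eps) {
    stop_reason <- "converged"
  } else {
    for (t in seq_len(config$max_iters)) {
      iters <- t
      idx <- sample_candidate(front_obj, config$temp,
                              config$use_boltzmann_sampling)
      pos <- sample_position(front_eps[[idx]], config$t_prime,
                             config$use_boltzmann_sampling)
      x_new <- if (config$use_structured_mutation) {
        structured_mutation(front_seq[idx], y_star, pos)
      } else {
        trivial_mutation(seq_chars(front_seq[idx]), y_star, pos)
      }
      ev <- evaluate(x_new)
      n_eval <- n_eval + 1L
      if (config$collect_byproducts) harvest(x_new)
      absorb(x_new, ev)
      if (front_obj[1L] < best - 1e-15) {
        best <- front_obj[1L]
        stale <- 0L
      } else {
        stale <- stale + 1L
      }
      trace <- c(trace, best)
      if (best < config$converge_eps) { stop_reason <- "converged"; break }
      if (stale >= config$patience)   { stop_reason <- "patience";  break }
    }
  }

  if (!config$collect_byproducts) harvest(front_seq[1L])

  structure(
    list(x_mfe = x_mfe, x_umfe = x_umfe,
         x_best = data.frame(sequence = front_seq, objective = front_obj,
                             stringsAsFactors = FALSE),
         trace = trace, iterations_run = iters, stop_reason = stop_reason,
         n_evaluations = n_eval, target = y_star$dotbracket,
         config = config, backend = backend$name),
    class = "design_result"
  )
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("Design result for %s\n", x$target))
  cat(sprintf("  %d iterations (%s), %d evaluations\n",
              x$iterations_run, x$stop_reason, x$n_evaluations))
  cat(sprintf("  best objective %.6g (%s), |X_MFE| = %d, |X_uMFE| = %d\n",
              x$x_best$objective[1L], x$config$objective,
              length(x$x_mfe), length(x$x_umfe)))
  invisible(x)
}
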