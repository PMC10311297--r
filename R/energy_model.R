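#' The built-in nearest-pair energy model
#'
#' A deliberately small thermodynamic model in which every ensemble
#' quantity has an exact in-package oracle: the energy of a structure is
#' a sum of one term per base pair plus a bonus for each helix stack
#' (a pair whose inner neighbour is also paired).  The defaults make
#' G-C pairs and stacked helices the most stable motifs, qualitatively
#' like the Turner nearest-neighbour model, while staying simple enough
#' that the full ensemble can be enumerated for short sequences.
#'
#' Energies are in arbitrary "toy" units with the Boltzmann scale `RT`.
#'
#' @param pair_cg,pair_au,pair_gu Energy of a CG/GC, AU/UA and GU/UG
#'   pair respectively (defaults -3, -2, -1).
#' @param stack_bonus Energy added for each stacked pair, i.e. each pair
#'   `(i, j)` with `(i+1, j-1)` also paired (default -1).
#' @param min_hairpin Minimum number of unpaired bases enclosed by a
#'   hairpin-closing pair (default 3, as in standard folding engines).
#' @param RT Boltzmann scale; must be positive (default 1).
#' @return An object of class `energy_model`.
#' @export
toy_energy_model <- function(pair_cg = -3, pair_au = -2, pair_gu = -1,
                             stack_bonus = -1, min_hairpin = 3L, RT = 1) {
  stopifnot(RT > 0, min_hairpin >= 0,
            is.finite(pair_cg), is.finite(pair_au), is.finite(pair_gu),
            is.finite(stack_bonus))
  emat <- matrix(NA_real_, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  emat["C", "G"] <- emat["G", "C"] <- pair_cg
  emat["A", "U"] <- emat["U", "A"] <- pair_au
  emat["G", "U"] <- emat["U", "G"] <- pair_gu
  structure(
    list(emat = emat, stack_bonus = stack_bonus,
         min_hairpin = as.integer(min_hairpin), RT = RT),
    class = "energy_model"
  )
}

#' @export
print.energy_model <- function(x, ...) {
  cat("Nearest-pair energy model (toy units)\n")
  cat(sprintf("  pair energies: CG/GC %+g, AU/UA %+g, GU/UG %+g\n",
              x$emat["C", "G"], x$emat["A", "U"], x$emat["G", "U"]))
  cat(sprintf("  stack bonus %+g, min hairpin %d, RT %g\n",
              x$stack_bonus, x$min_hairpin, x$RT))
  invisible(x)
}

#' Energy of a structure for a sequence
#'
#' Sums the pair terms and stack bonuses of the model.  Errors if any
#' pair of `y` is not an admissible base pair of `x` or violates the
#' minimum hairpin length.
#'
#' @param x RNA sequence.
#' @param y Structure (`rna_structure` or dot-bracket string).
#' @param model An `energy_model`.
#' @return The energy (a single number; 0 for the open chain).
#' @export
structure_energy <- function(x, y, model = toy_energy_model()) {
  y <- as_structure(y)
  b <- seq_chars(x)
  if (length(b) != y$n) stop("sequence and structure have different lengths")
  if (!nrow(y$pairs)) return(0)
  i <- y$pairs[, 1L]; j <- y$pairs[, 2L]
  if (any(j - i <= model$min_hairpin))
    stop("structure violates the minimum hairpin length")
  e <- model$emat[cbind(b[i], b[j])]
  if (anyNA(e))
    stop("structure contains a pair that is not admissible for this sequence")
  stacked <- y$partner[pmin(i + 1L, y$n)] == j - 1L & y$partner[i] == j & i + 1L < j
  sum(e) + model$stack_bonus * sum(stacked)
}

#' Enumerate the complete structural ensemble of a short sequence
#'
#' Recursively generates every pseudoknot-free structure the sequence
#' can form under the admissible pair types and the model's minimum
#' hairpin length, with its energy.  This is the brute-force oracle the
#' dynamic programs are tested against; it always includes the open
#' chain (energy 0).
#'
#' @param x RNA sequence of length at most `cap`.
#' @param model An `energy_model`.
#' @param cap Maximum length accepted (default 16); beyond it the
#'   enumeration is intractable and [partition_function()] should be
#'   used instead.
#' @return A data frame with columns `structure` (dot-bracket) and
#'   `energy`, one row per ensemble member.
#' @export
enumerate_ensemble <- function(x, model = toy_energy_model(), cap = 16L) {
  b <- seq_chars(x)
  n <- length(b)
  if (n > cap)
    stop(sprintf(
      "length %d exceeds the enumeration cap (%d); use partition_function()",
      n, cap))
  h <- model$min_hairpin
  # pair-set enumeration, independent of the DP kernels: each call splits
  # on the status of position i (unpaired, or paired with some k); a
  # structure is a flat vector of pair endpoints c(i1,j1,i2,j2,...)
  gen2 <- function(i, j) {
    if (i > j) return(list(integer(0)))
    out <- gen2(i + 1L, j)
    if (i + h + 1L <= j) {
      for (k in seq.int(i + h + 1L, j)) {
        if (!can_pair(b[i], b[k])) next
        for (s1 in gen2(i + 1L, k - 1L))
          for (s2 in gen2(k + 1L, j))
            out[[length(out) + 1L]] <- c(i, k, s1, s2)
      }
    }
    out
  }
  sets <- gen2(1L, n)
  db <- vapply(sets, function(p) {
    ch <- rep(".", n)
    if (length(p)) {
      ii <- p[seq(1L, length(p), by = 2L)]
      jj <- p[seq(2L, length(p), by = 2L)]
      ch[ii] <- "("; ch[jj] <- ")"
    }
    paste(ch, collapse = "")
  }, character(1))
  energy <- vapply(db, function(s) structure_energy(x, s, model), numeric(1))
  data.frame(structure = db, energy = unname(energy),
             stringsAsFactors = FALSE)
}

can_pair_vec <- function(a, bs) {
  vapply(bs, function(bb) can_pair(a, bb), logical(1))
}
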