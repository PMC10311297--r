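# Brute-force oracles built on enumerate_ensemble(); everything here is
# independent of the C++ dynamic programs it is used to check.

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                collapse = "")

# Boltzmann-weighted ensemble table: structure, energy, probability
oracle_ensemble <- function(x, model = toy_energy_model()) {
  e <- enumerate_ensemble(x, model)
  w <- exp(-e$energy / model$RT)
  e$prob <- w / sum(w)
  e
}

oracle_Q <- function(x, model = toy_energy_model()) {
  e <- enumerate_ensemble(x, model)
  sum(exp(-e$energy / model$RT))
}

oracle_bpp <- function(x, model = toy_energy_model()) {
  e <- oracle_ensemble(x, model)
  n <- nchar(x)
  bpp <- matrix(0, n, n)
  for (k in seq_len(nrow(e))) {
    y <- parse_dotbracket(e$structure[k])
    if (nrow(y$pairs)) {
      for (r in seq_len(nrow(y$pairs))) {
        i <- y$pairs[r, 1]; j <- y$pairs[r, 2]
        bpp[i, j] <- bpp[i, j] + e$prob[k]
        bpp[j, i] <- bpp[i, j]
      }
    }
  }
  bpp
}

oracle_mfe_set <- function(x, model = toy_energy_model()) {
  e <- enumerate_ensemble(x, model)
  sort(e$structure[e$energy < min(e$energy) + 1e-9])
}

# expected structure distance to y_star, by full enumeration
oracle_expected_distance <- function(x, y_star, model = toy_energy_model()) {
  e <- oracle_ensemble(x, model)
  sum(vapply(seq_len(nrow(e)), function(k)
    structure_distance(e$structure[k], y_star) * e$prob[k], numeric(1)))
}

# per-index pairing-status comparison, the independent distance oracle
oracle_distance <- function(a, b) {
  a <- parse_dotbracket(as.character(a)); b <- parse_dotbracket(as.character(b))
  sum(a$partner != b$partner)
}
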