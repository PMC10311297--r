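#' Folding backends
#'
#' The search engine talks to the energy model through a small contract,
#' a `fold_backend` object with four functions:
#'
#' * `ensemble(x)`: ensemble summary (`logQ`, `bpp`, `unpaired`) used by
#'   the defect objective and by defect-weighted position sampling;
#' * `prob(x, y)`: equilibrium probability of a structure;
#' * `criterion(x, y)`: MFE / unique-MFE check
#'   (`list(satisfies_mfe =, satisfies_umfe =)`);
#' * `RT`: the Boltzmann scale of the backend.
#'
#' Any object honouring this contract can drive [design()]; the package
#' ships the exact toy-model backend and an adapter for the ViennaRNA
#' command-line programs.
#'
#' @name fold_backend
NULL

#' Backend for the built-in nearest-pair model
#'
#' @param model An [toy_energy_model()].
#' @return A `fold_backend` object.
#' @export
toy_backend <- function(model = toy_energy_model()) {
  structure(
    list(
      name = "toy",
      RT = model$RT,
      model = model,
      ensemble = function(x) partition_function(x, model),
      prob = function(x, y) prob_of_structure(x, y, model),
      criterion = function(x, y) check_criterion(x, y, model)
    ),
    class = "fold_backend"
  )
}

#' @export
print.fold_backend <- function(x, ...) {
  cat(sprintf("Folding backend '%s' (RT = %g)\n", x$name, x$RT))
  invisible(x)
}

#' Backend adapter for the ViennaRNA command-line programs
#'
#' Wraps `RNAfold`, `RNAeval` and `RNAsubopt` (ViennaRNA 2.x) behind the
#' [fold_backend] contract, so designs can be run and evaluated under
#' the full Turner nearest-neighbour model.  The MFE set is obtained
#' with `RNAsubopt -e 0` (all structures within zero energy of the
#' minimum), equilibrium probabilities from the ensemble free energy of
#' `RNAfold -p`, and base-pair probabilities by parsing the dot-plot
#' file `RNAfold -p` writes.
#'
#' Extra command-line options (e.g. a dangle model) can be passed
#' through unchanged via `options`.
#'
#' @param options Character vector of extra flags passed to every
#'   ViennaRNA call (default none).
#' @param RT Boltzmann scale in kcal/mol (default 0.6163207, i.e. 37C).
#' @return A `fold_backend`, or an error if the executables are absent.
#' @export
vienna_backend <- function(options = character(), RT = 0.6163207) {
  for (exe in c("RNAfold", "RNAeval", "RNAsubopt"))
    if (Sys.which(exe) == "")
      stop(sprintf("ViennaRNA executable '%s' not found on PATH", exe))
  structure(
    list(
      name = "vienna",
      RT = RT,
      options = options,
      ensemble = function(x) vienna_ensemble(x, options, RT),
      prob = function(x, y) vienna_prob(x, y, options, RT),
      criterion = function(x, y) vienna_criterion(x, y, options)
    ),
    class = "fold_backend"
  )
}

#' Select a folding backend by name
#'
#' @param name `"toy"` or `"vienna"`.
#' @param model Energy model used when `name = "toy"`.
#' @return A `fold_backend`.
#' @export
get_backend <- function(name = c("toy", "vienna"), model = toy_energy_model()) {
  name <- match.arg(name)
  switch(name, toy = toy_backend(model), vienna = vienna_backend())
}

run_vienna <- function(exe, args, input) {
  out <- suppressWarnings(system2(exe, args, stdout = TRUE, input = input))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop(sprintf("%s exited with status %d", exe, status))
  out
}

vienna_eval_energy <- function(x, y, options) {
  out <- run_vienna("RNAeval", options, c(x, as.character(as_structure(y))))
  # last line: "structure ( energy )"
  m <- regmatches(out, regexpr("\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", out))
  m <- m[nzchar(m)]
  if (!length(m)) stop("could not parse RNAeval output")
  as.numeric(gsub("[()\\s]", "", m[length(m)], perl = TRUE))
}

# the ensemble free energy appears either on its own labelled line
# (older output) or as the "[ dG ]" partition-function line
parse_ensemble_dG <- function(out) {
  line <- grep("free energy of ensemble", out, value = TRUE)
  if (!length(line))
    line <- grep("\\[\\s*-?[0-9.]+\\s*\\]", out, value = TRUE)
  if (!length(line)) stop("could not parse RNAfold -p output")
  tail_part <- sub(".*\\[", "", line[1L])
  as.numeric(regmatches(tail_part, regexpr("-?[0-9]+\\.?[0-9]*", tail_part)))
}

vienna_ensemble <- function(x, options, RT) {
  n <- nchar(x)
  owd <- getwd()
  td <- tempfile("vrna")
  dir.create(td)
  on.exit({ setwd(owd); unlink(td, recursive = TRUE) })
  setwd(td)
  out <- run_vienna("RNAfold", c("-p", "--noPS", options), x)
  dG <- parse_ensemble_dG(out)
  ps <- list.files(td, pattern = "(dp|dot)\\.ps$", full.names = TRUE)
  if (!length(ps)) stop("RNAfold did not write a dot-plot file")
  bpp <- matrix(0, n, n)
  for (ln in readLines(ps[1L])) {
    if (!grepl("ubox$", ln)) next
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(f) < 4L) next
    i <- suppressWarnings(as.integer(f[1L]))
    j <- suppressWarnings(as.integer(f[2L]))
    p <- suppressWarnings(as.numeric(f[3L]))^2  # file stores sqrt(p)
    if (is.na(i) || is.na(j) || is.na(p)) next
    bpp[i, j] <- p; bpp[j, i] <- p
  }
  q <- pmax(0, 1 - rowSums(bpp))
  structure(
    list(logQ = -dG / RT, Q = exp(-dG / RT), bpp = bpp, unpaired = q,
         n = n, sequence = toupper(x), model = NULL),
    class = "ensemble_summary"
  )
}

vienna_prob <- function(x, y, options, RT) {
  e <- vienna_eval_energy(x, y, options)
  out <- run_vienna("RNAfold", c("-p", "--noPS", "--noDP", options), x)
  dG <- parse_ensemble_dG(out)
  min(1, exp(-(e - dG) / RT))
}

vienna_criterion <- function(x, y, options) {
  y <- as_structure(y)
  out <- run_vienna("RNAsubopt", c("-e", "0", options), x)
  structs <- grep("^[().]+", out, value = TRUE)
  structs <- vapply(strsplit(structs, "\\s+"), `[[`, character(1), 1L)
  structs <- unique(structs[nchar(structs) == y$n])
  hit <- y$dotbracket %in% structs
  list(satisfies_mfe = hit, satisfies_umfe = hit && length(structs) == 1L)
}
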