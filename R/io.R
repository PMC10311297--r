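#' Read a puzzle file of target structures
#'
#' Plain-text format, one dot-bracket structure per line, optionally
#' followed by a whitespace-separated puzzle name.  Blank lines and
#' lines starting with `#` are ignored; unnamed puzzles are numbered
#' `puzzle_001`, `puzzle_002`, ...  Every structure is parsed and
#' validated; a malformed line raises an error naming the line number.
#'
#' @param path Path to the puzzle file.
#' @return A named character vector of dot-bracket strings (a puzzle
#'   set).
#' @export
read_puzzles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  out <- character(0)
  for (ln in keep) {
    fields <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    y <- tryCatch(parse_dotbracket(fields[1L]), error = function(e)
      stop(sprintf("line %d of '%s': %s", ln, path, conditionMessage(e)),
           call. = FALSE))
    nm <- if (length(fields) >= 2L) fields[2L] else
      sprintf("puzzle_%03d", length(out) + 1L)
    if (nm %in% names(out))
      stop(sprintf("duplicate puzzle name '%s' (line %d)", nm, ln))
    out[nm] <- y$dotbracket
  }
  out
}

#' Write a puzzle file
#'
#' @param puzzles Named character vector of dot-bracket structures.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_puzzles <- function(puzzles, path) {
  for (p in puzzles) parse_dotbracket(p)
  writeLines(paste(puzzles, names(puzzles)), path)
  invisible(path)
}

#' Write designed sequences as FASTA
#'
#' Record IDs encode the puzzle name, the criterion the sequence
#' satisfies (`mfe`, `umfe` or `best`) and its objective value, as
#' `name|criterion|obj=VALUE`.  Sequences are wrapped at 60 columns.
#'
#' @param records Data frame with columns `puzzle`, `criterion`,
#'   `objective`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_designs_fasta <- function(records, path) {
  ids <- sprintf("%s|%s|obj=%.6g", records$puzzle, records$criterion,
                 records$objective)
  set <- Biostrings::BStringSet(setNames(records$sequence, ids))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a designs FASTA file
#'
#' Inverse of [write_designs_fasta()]: parses record IDs of the form
#' `name|criterion|obj=VALUE` back into a data frame.  Plain FASTA from
#' other tools is accepted too; the whole ID then becomes the puzzle
#' name with criterion `NA`.
#'
#' @param path Path to a FASTA file.
#' @return Data frame with columns `puzzle`, `criterion`, `objective`,
#'   `sequence`.
#' @export
read_designs_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  seqs <- as.character(set)
  parts <- strsplit(ids, "|", fixed = TRUE)
  data.frame(
    puzzle = vapply(parts, `[[`, character(1), 1L),
    criterion = vapply(parts, function(p)
      if (length(p) >= 2L) p[[2L]] else NA_character_, character(1)),
    objective = vapply(parts, function(p) {
      if (length(p) < 3L) return(NA_real_)
      v <- sub("obj=", "", p[[3L]], fixed = TRUE)
      if (v %in% c("NA", "")) NA_real_ else as.numeric(v)
    }, numeric(1)),
    sequence = unname(seqs),
    stringsAsFactors = FALSE
  )
}

puzzle_metrics <- function(name, y, x, backend, iterations = NA_integer_,
                           stop_reason = NA_character_,
                           n_mfe = NA_integer_, n_umfe = NA_integer_) {
  crit <- backend$criterion(x, y)
  summ <- backend$ensemble(x)
  # a target outside the sequence's ensemble has probability zero
  p <- tryCatch(backend$prob(x, y), error = function(e) 0)
  data.frame(
    puzzle = name,
    length = as_structure(y)$n,
    sequence = x,
    solved_mfe = crit$satisfies_mfe,
    solved_umfe = crit$satisfies_umfe,
    n_mfe_solutions = n_mfe,
    n_umfe_solutions = n_umfe,
    best_probability = p,
    best_ned = ensemble_defect(summ, y) / as_structure(y)$n,
    mean_positional_entropy = mean(positional_entropy(summ)),
    iterations = iterations,
    stop_reason = stop_reason,
    stringsAsFactors = FALSE
  )
}

#' Design a set of puzzles and write a report
#'
#' Runs [design()] on every target of a puzzle set (optionally several
#' independent runs per puzzle), writes per-puzzle FASTA files of the
#' harvested MFE/uMFE solutions and the final frontier, a tab-separated
#' metrics report, a reproducibility manifest, and — when `runs > 1` —
#' an aggregate table with the union and average solved counts over
#' runs.
#'
#' Per-run metrics are computed for the most probable harvested
#' solution if any, else for the best-objective frontier sequence.
#'
#' @param puzzles Named character vector of targets (see
#'   [read_puzzles()]).
#' @param config A [design_config()]; run `r` of puzzle `p` uses seed
#'   `seed + 1000 * (r - 1) + index(p) - 1` so runs are independent but
#'   reproducible.
#' @param backend A [fold_backend].
#' @param out_dir Output directory (created if needed), or `NULL` to
#'   skip writing files.
#' @param runs Independent design runs per puzzle (default 1).
#' @param max_fasta_records Cap on harvested solutions written per
#'   FASTA file (default 1000).
#' @return Invisibly, a list with `metrics` (per puzzle x run data
#'   frame) and `aggregate` (per puzzle union/average summary).
#' @export
run_design <- function(puzzles, config = design_config(),
                       backend = toy_backend(), out_dir = NULL, runs = 1L,
                       max_fasta_records = 1000L) {
  stopifnot(length(puzzles) >= 1, !is.null(names(puzzles)), runs >= 1)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  base_seed <- if (is.null(config$seed)) 0L else as.integer(config$seed)

  metrics <- list()
  solved_by_run <- list()
  for (r in seq_len(runs)) {
    for (pi in seq_along(puzzles)) {
      nm <- names(puzzles)[pi]
      cfg <- config
      cfg$seed <- base_seed + 1000L * (r - 1L) + (pi - 1L)
      res <- design(puzzles[[pi]], cfg, backend)
      best_x <- if (length(res$x_umfe)) {
        res$x_umfe[[1L]]
      } else if (length(res$x_mfe)) {
        res$x_mfe[[1L]]
      } else res$x_best$sequence[1L]
      row <- puzzle_metrics(nm, puzzles[[pi]], best_x, backend,
                            res$iterations_run, res$stop_reason,
                            length(res$x_mfe), length(res$x_umfe))
      row$run <- r
      metrics[[length(metrics) + 1L]] <- row
      solved_by_run[[length(solved_by_run) + 1L]] <-
        list(puzzle = nm, run = r, mfe = res$x_mfe, umfe = res$x_umfe)

      if (!is.null(out_dir)) {
        recs <- data.frame(
          puzzle = nm,
          criterion = c(rep("umfe", length(res$x_umfe)),
                        rep("mfe", length(setdiff(res$x_mfe, res$x_umfe))),
                        rep("best", nrow(res$x_best))),
          objective = NA_real_,
          sequence = c(res$x_umfe, setdiff(res$x_mfe, res$x_umfe),
                       res$x_best$sequence),
          stringsAsFactors = FALSE
        )
        recs$objective[recs$criterion == "best"] <- res$x_best$objective
        recs <- head(recs, max_fasta_records)
        write_designs_fasta(
          recs, file.path(out_dir, sprintf("%s_run%d.fasta", nm, r)))
      }
    }
  }
  metrics <- do.call(rbind, metrics)

  # aggregate over runs: union counts pool solutions, averages are per run
  agg <- do.call(rbind, lapply(names(puzzles), function(nm) {
    rows <- metrics[metrics$puzzle == nm, , drop = FALSE]
    sols <- solved_by_run[vapply(solved_by_run, function(s)
      s$puzzle == nm, logical(1))]
    data.frame(
      puzzle = nm,
      solved_mfe_union = length(unique(unlist(lapply(sols, `[[`, "mfe")))) > 0,
      solved_umfe_union = length(unique(unlist(lapply(sols, `[[`, "umfe")))) > 0,
      solved_mfe_avg = mean(rows$solved_mfe),
      solved_umfe_avg = mean(rows$solved_umfe),
      n_mfe_union = length(unique(unlist(lapply(sols, `[[`, "mfe")))),
      n_umfe_union = length(unique(unlist(lapply(sols, `[[`, "umfe")))),
      mean_probability = mean(rows$best_probability),
      mean_ned = mean(rows$best_ned),
      stringsAsFactors = FALSE
    )
  }))

  if (!is.null(out_dir)) {
    num <- vapply(metrics, is.numeric, logical(1))
    fm <- metrics
    fm[num] <- lapply(fm[num], function(v) signif(v, 6))
    write.table(fm, file.path(out_dir, "metrics.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    fa <- agg
    numa <- vapply(fa, is.numeric, logical(1))
    fa[numa] <- lapply(fa[numa], function(v) signif(v, 6))
    write.table(fa, file.path(out_dir, "aggregate.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest <- c(
      sprintf("package_version: %s",
              as.character(utils::packageVersion("rnadesign"))),
      sprintf("backend: %s", backend$name),
      sprintf("objective: %s", config$objective),
      sprintf("k: %d", config$k),
      sprintf("temp: %g", config$temp),
      sprintf("t_prime: %g", config$t_prime),
      sprintf("max_iters: %d", config$max_iters),
      sprintf("converge_eps: %g", config$converge_eps),
      sprintf("patience: %d", config$patience),
      sprintf("seed: %d", base_seed),
      sprintf("runs: %d", runs),
      sprintf("ablations: TI=%d BS=%d SM=%d MF=%d BP=%d",
              config$use_targeted_init, config$use_boltzmann_sampling,
              config$use_structured_mutation, config$multifrontier,
              config$collect_byproducts)
    )
    writeLines(manifest, file.path(out_dir, "manifest.txt"))
  }
  invisible(list(metrics = metrics, aggregate = agg))
}

#' Evaluate externally produced designs
#'
#' Recomputes every report metric (MFE/uMFE status, target probability,
#' normalized ensemble defect, mean positional entropy) for sequences
#' supplied in a FASTA file, matched to targets by puzzle name.  This
#' allows any design tool's output to be scored under the same metrics
#' without reimplementing the tool.
#'
#' @param puzzles Named character vector of targets.
#' @param designs Path to a FASTA file (see [read_designs_fasta()]) or
#'   a data frame with columns `puzzle` and `sequence`.
#' @param backend A [fold_backend].
#' @return A metrics data frame, one row per design record.
#' @export
evaluate_designs <- function(puzzles, designs, backend = toy_backend()) {
  if (is.character(designs)) designs <- read_designs_fasta(designs)
  unmatched <- setdiff(unique(designs$puzzle), names(puzzles))
  if (length(unmatched))
    stop("designs reference unknown puzzles: ",
         paste(unmatched, collapse = ", "))
  rows <- lapply(seq_len(nrow(designs)), function(r) {
    nm <- designs$puzzle[r]
    if (nchar(designs$sequence[r]) != nchar(puzzles[[nm]]))
      stop(sprintf("design %d for '%s' has the wrong length", r, nm))
    puzzle_metrics(nm, puzzles[[nm]], designs$sequence[r], backend)
  })
  do.call(rbind, rows)
}
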