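test_that("generated targets always satisfy the structure invariants", {
  set.seed(31)
  for (r in 1:200) {
    n <- sample(10:80, 1)
    y <- random_structure(n)
    expect_equal(y$n, n)
    expect_equal(2 * nrow(y$pairs) + length(y$unpaired), n)
    # round-trip through the parser (validates nesting/balance)
    expect_identical(parse_dotbracket(y$dotbracket)$dotbracket, y$dotbracket)
    # hairpin minimum: innermost pairs enclose >= 3 unpaired bases
    if (nrow(y$pairs)) {
      for (r2 in seq_len(nrow(y$pairs))) {
        i <- y$pairs[r2, 1]; j <- y$pairs[r2, 2]
        inner <- seq(i + 1, j - 1)
        if (all(y$partner[inner] == 0)) expect_gte(length(inner), 3)
      }
    }
  }
})

test_that("generator respects forced shapes and degenerate lengths", {
  expect_equal(random_structure(5, helix_len_range = c(3, 3))$dotbracket,
               ".....")
  set.seed(32)
  y <- random_structure(9, helix_len_range = c(3, 3),
                        loop_len_range = c(3, 3))
  expect_equal(y$dotbracket, "(((...)))")
  expect_equal(random_structure(1)$dotbracket, ".")
})

test_that("generator is deterministic under a seed", {
  set.seed(77); a <- replicate(5, random_structure(50)$dotbracket)
  set.seed(77); b <- replicate(5, random_structure(50)$dotbracket)
  expect_identical(a, b)
})

test_that("helix lengths fall inside the requested range", {
  helix_runs <- function(y) {
    # maximal runs of stacked pairs
    runs <- integer(0); cur <- 0L
    for (r in seq_len(nrow(y$pairs))) {
      i <- y$pairs[r, 1]; j <- y$pairs[r, 2]
      if (cur > 0 && i > 1 && j < y$n && y$partner[i - 1] == j + 1)
        cur <- cur + 1L
      else { if (cur > 0) runs <- c(runs, cur); cur <- 1L }
    }
    if (cur > 0) runs <- c(runs, cur)
    runs
  }
  set.seed(34)
  for (r in 1:30) {
    y <- random_structure(60, helix_len_range = c(3, 5))
    runs <- helix_runs(y)
    if (length(runs)) {
      expect_gte(min(runs), 3)
      expect_lte(max(runs), 5)
    }
  }
})

test_that("worked examples parse, validate, and carry companions", {
  ex <- worked_examples()
  expect_true("two_hairpins" %in% names(ex$puzzles))
  expect_equal(ex$puzzles[["two_hairpins"]], "(((...)))..(((...)))")
  for (p in ex$puzzles)
    expect_identical(parse_dotbracket(p)$dotbracket, unname(p))
  expect_true(is_compatible(ex$init_sequence, ex$puzzles[["two_hairpins"]]))
  # the companion is a targeted-initialization draw: A's at loops,
  # complementary C/G at pairs
  y <- parse_dotbracket(ex$puzzles[["two_hairpins"]])
  b <- strsplit(ex$init_sequence, "")[[1]]
  expect_true(all(b[y$unpaired] == "A"))
  expect_true(all(b[y$pairs] %in% c("C", "G")))
  expect_length(mfe_structures(ex$tie_sequence), 2)
})
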