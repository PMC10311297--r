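#' Random pseudoknot-free target structures
#'
#' Seeded generator of valid design targets for testing and
#' benchmarking without external data.  Structures are built
#' recursively: a segment either stays unpaired or opens a helix of
#' `helix_len` stacked pairs enclosing an interior that is a hairpin
#' loop, a continuation (optionally flanked by bulges), or — with
#' probability `branching_prob` — a multiloop with two branches.  Every
#' hairpin encloses at least `min_hairpin` unpaired bases so all
#' generated targets are foldable under both the toy model and
#' thermodynamic engines.
#'
#' @param n Target length (exact).
#' @param helix_len_range Length-2 vector: min/max stacked pairs per
#'   helix (default `c(2, 6)`).
#' @param loop_len_range Length-2 vector: min/max unpaired run length
#'   (default `c(3, 6)`); the hairpin minimum is enforced on top.
#' @param branching_prob Probability that a helix interior branches
#'   into a multiloop (default 0.2).
#' @param min_hairpin Minimum unpaired bases in a hairpin (default 3).
#' @return An `rna_structure` of length exactly `n`.
#' @examples
#' set.seed(7)
#' random_structure(40)
#' @export
random_structure <- function(n, helix_len_range = c(2L, 6L),
                             loop_len_range = c(3L, 6L),
                             branching_prob = 0.2, min_hairpin = 3L) {
  stopifnot(n >= 1, length(helix_len_range) == 2, length(loop_len_range) == 2,
            helix_len_range[1] >= 1, helix_len_range[1] <= helix_len_range[2],
            loop_len_range[1] >= 0, loop_len_range[1] <= loop_len_range[2],
            branching_prob >= 0, branching_prob <= 1, min_hairpin >= 0)
  hlo <- as.integer(helix_len_range[1]); hhi <- as.integer(helix_len_range[2])
  llo <- as.integer(loop_len_range[1]);  lhi <- as.integer(loop_len_range[2])
  hp <- max(as.integer(min_hairpin), llo)
  if (n < 2L * hlo + hp && n < 1L)
    stop("length too small for any structure under this spec")

  rint <- function(lo, hi) if (lo >= hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L

  gen <- function(m) {
    # smallest helix + hairpin that fits
    if (m < 2L * hlo + hp) return(strrep(".", m))
    h <- rint(hlo, min(hhi, (m - hp) %/% 2L))
    interior <- m - 2L * h
    # interior: hairpin loop, branch, or flanked continuation
    inner <-
      if (interior < 2L * hlo + hp + 2L) {
        strrep(".", interior)
      } else if (runif(1) < branching_prob &&
                 interior >= 2L * (2L * hlo + hp) + 3L) {
        spacer <- rint(1L, min(3L, interior - 2L * (2L * hlo + hp)))
        left <- rint(2L * hlo + hp, interior - spacer - (2L * hlo + hp))
        paste0(gen(left), strrep(".", spacer), gen(interior - spacer - left))
      } else {
        lpad <- rint(1L, min(lhi, interior - (2L * hlo + hp) - 1L))
        rpad <- rint(0L, min(lhi, interior - (2L * hlo + hp) - lpad))
        paste0(strrep(".", lpad), gen(interior - lpad - rpad),
               strrep(".", rpad))
      }
    paste0(strrep("(", h), inner, strrep(")", h))
  }

  # optional exterior flanks so helices do not always span the ends
  lflank <- if (n >= 2L * hlo + hp + 2L) rint(0L, min(lhi, 2L)) else 0L
  rflank <- if (n - lflank >= 2L * hlo + hp + 1L) rint(0L, min(lhi, 2L)) else 0L
  db <- paste0(strrep(".", lflank), gen(n - lflank - rflank),
               strrep(".", rflank))
  parse_dotbracket(db)
}

#' Worked-example and oracle fixtures
#'
#' A small bundle of hand-built targets used throughout the
#' documentation and tests: the 20-nt two-hairpin target (with the
#' canonical targeted-initialization sequence that solves it), trivial
#' open-chain and single-hairpin targets, and a toy-model tie fixture —
#' a sequence with two minimum-energy structures, exercising the
#' distinction between the MFE and unique-MFE criteria.
#'
#' @return A list with components
#'   * `puzzles`: named character vector of dot-bracket targets,
#'   * `init_sequence`: a targeted-initialization draw for
#'     `two_hairpins` (A at the 8 unpaired positions, complementary
#'     C/G at the 6 pairs),
#'   * `tie_sequence`: a sequence whose toy-model MFE set has exactly
#'     two members.
#' @export
worked_examples <- function() {
  list(
    puzzles = c(
      two_hairpins = "(((...)))..(((...)))",
      open_chain   = ".....",
      hairpin      = "(...)",
      stacked_stem = "((...))"
    ),
    init_sequence = "CGGAAACCGAAGCGAAACGC",
    # two co-optimal structures (".((....))" and "((...).)." at -5)
    tie_sequence  = "AGGCGCAUC"
  )
}
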