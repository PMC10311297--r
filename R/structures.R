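#' Parse a dot-bracket secondary structure
#'
#' Converts a dot-bracket string over `(`, `)` and `.` into an
#' `rna_structure` object holding the base-pair set and the unpaired
#' positions.  Only pseudoknot-free structures can be written in this
#' notation: matching brackets are resolved by stack discipline, so any
#' parseable string is automatically properly nested.
#'
#' All positions are 1-based.
#'
#' @param text A single dot-bracket string, e.g. `"(((...)))"`.
#' @return An object of class `rna_structure` with components
#'   * `dotbracket`: the input string,
#'   * `n`: structure length,
#'   * `partner`: integer vector; `partner[i]` is the position paired
#'     with `i`, or 0 if `i` is unpaired,
#'   * `pairs`: two-column integer matrix of pairs `(i, j)` with `i < j`,
#'   * `unpaired`: integer vector of unpaired positions.
#' @examples
#' y <- parse_dotbracket("(((...)))..(((...)))")
#' y$pairs
#' @export
parse_dotbracket <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("'text' must be a single nonempty string")
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("(", ")", "."))
  if (length(bad))
    stop(sprintf("illegal character '%s' at position %d", chars[bad[1L]], bad[1L]))
  n <- length(chars)
  partner <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack))
        stop(sprintf("unmatched ')' at position %d", i))
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack))
    stop(sprintf("unmatched '(' at position %d", stack[length(stack)]))
  new_rna_structure(text, partner)
}

new_rna_structure <- function(dotbracket, partner) {
  n <- length(partner)
  i <- which(partner > seq_len(n))
  pairs <- cbind(i = i, j = partner[i])
  structure(
    list(dotbracket = dotbracket, n = n, partner = partner,
         pairs = pairs, unpaired = which(partner == 0L)),
    class = "rna_structure"
  )
}

#' Build an `rna_structure` from a partner vector
#'
#' @param partner Integer vector; `partner[i]` is the partner of position
#'   `i` (0 if unpaired).  Must be involutive and pseudoknot-free.
#' @return An `rna_structure`.
#' @export
structure_from_partner <- function(partner) {
  partner <- as.integer(partner)
  n <- length(partner)
  db <- rep(".", n)
  for (i in seq_len(n)) {
    p <- partner[i]
    if (p != 0L) {
      if (p < 1L || p > n || p == i || partner[p] != i)
        stop("'partner' is not a valid involution")
      db[i] <- if (p > i) "(" else ")"
    }
  }
  # parsing re-derives the pairing; a crossing pair set cannot round-trip
  y <- parse_dotbracket(paste(db, collapse = ""))
  if (!identical(y$partner, partner))
    stop("partner vector encodes a pseudoknotted (crossing) pairing")
  y
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("RNA secondary structure (n = %d, %d pairs, %d unpaired)\n",
              x$n, nrow(x$pairs), length(x$unpaired)))
  cat(x$dotbracket, "\n")
  invisible(x)
}

#' @export
as.character.rna_structure <- function(x, ...) x$dotbracket

as_structure <- function(y) {
  if (inherits(y, "rna_structure")) y else parse_dotbracket(y)
}

#' Structure distance between two secondary structures
#'
#' Counts the positions whose pairing status differs between the two
#' structures: `n - 2 * |shared pairs| - |shared unpaired positions|`.
#' A position contributes 0 when it has the same partner (or is unpaired)
#' in both structures and 1 otherwise, so the value lies in `[0, n]` and
#' is symmetric.
#'
#' @param a,b `rna_structure` objects (or dot-bracket strings) of equal
#'   length.
#' @return A non-negative integer.
#' @examples
#' structure_distance("(...)", ".....")  # 2: both ends differ
#' @export
structure_distance <- function(a, b) {
  a <- as_structure(a); b <- as_structure(b)
  if (a$n != b$n)
    stop("structures have different lengths")
  shared_pairs <- sum(a$partner > seq_len(a$n) &
                      a$partner == b$partner)
  shared_unpaired <- sum(a$partner == 0L & b$partner == 0L)
  as.integer(a$n - 2L * shared_pairs - shared_unpaired)
}

#' Is a sequence compatible with a target structure?
#'
#' A sequence is compatible when every base pair of the structure is one
#' of the six admissible types CG, GC, AU, UA, GU, UG (Watson-Crick plus
#' the G-U wobble).  Compatibility is the constraint that the target
#' belongs to the sequence's structural ensemble.
#'
#' @param x RNA sequence (string over A, C, G, U).
#' @param y Target structure (`rna_structure` or dot-bracket string).
#' @return `TRUE` or `FALSE`.
#' @export
is_compatible <- function(x, y) {
  y <- as_structure(y)
  b <- seq_chars(x)
  if (length(b) != y$n)
    stop("sequence and structure have different lengths")
  if (!nrow(y$pairs)) return(TRUE)
  keys <- paste0(b[y$pairs[, 1L]], b[y$pairs[, 2L]])
  all(keys %in% rownames(PAIR_TYPES))
}

seq_chars <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("'x' must be a single string")
  b <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  b[b == "T"] <- "U"
  bad <- which(!b %in% RNA_BASES)
  if (length(bad))
    stop(sprintf("illegal base '%s' at position %d", b[bad[1L]], bad[1L]))
  b
}

# 0-based integer encoding used by the C++ kernels
seq_codes <- function(x) {
  match(seq_chars(x), RNA_BASES) - 1L
}
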