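# Molecular formula parsing and serialization.

# Atomic numbers for the elements the fixtures use, plus common extensions.
# The element universe of a registry may restrict this further.
.ELEMENTS <- c(H = 1L, C = 6L, N = 7L, O = 8L, F = 9L, P = 15L, S = 16L,
               Cl = 17L, Br = 35L)

.DEFAULT_UNIVERSE <- c("H", "C", "N", "O")

#' Parse a molecular formula into an element composition
#'
#' Parses an expanded Hill-notation formula (no parentheses, e.g.
#' \code{"C3H9NO"} for trimethylamine N-oxide) into a named integer vector of
#' element counts.
#'
#' @param text character scalar, e.g. \code{"C5H5NO"}.
#' @param universe character vector of allowed element symbols; defaults to
#'   \code{c("H","C","N","O")}, the universe of the packaged fixtures.
#' @return named integer vector of counts, one entry per element present.
#' @examples
#' parseFormula("C5H5NO")
#' parseFormula("O")
#' @seealso [formulaString()] for the canonical Hill-order serializer.
#' @export
parseFormula <- function(text, universe = .DEFAULT_UNIVERSE) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty formula", call. = FALSE)
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1L]]
  matched <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1L]]
  if (sum(nchar(matched)) != nchar(text))
    stop("malformed formula: ", text, call. = FALSE)
  counts <- integer(0)
  for (tok in matched) {
    sym <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!sym %in% names(.ELEMENTS))
      stop("unknown element symbol: ", sym, call. = FALSE)
    if (!sym %in% universe)
      stop("element ", sym, " outside the declared universe [",
           paste(universe, collapse = ", "), "]", call. = FALSE)
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  counts[counts > 0L]
}

#' Serialize a composition in canonical Hill order
#'
#' Hill order: C first, then H, then all other elements alphabetically
#' (alphabetical throughout if no carbon is present). Counts of one are
#' omitted. \code{formulaString(parseFormula(x))} is the canonical form of
#' \code{x}.
#'
#' @param composition named integer vector of element counts.
#' @return character scalar.
#' @examples
#' formulaString(c(O = 1L, H = 5L, C = 5L, N = 1L))  # "C5H5NO"
#' @export
formulaString <- function(composition) {
  composition <- composition[composition != 0L]
  if (!length(composition)) return("")
  syms <- names(composition)
  if ("C" %in% syms) {
    ord <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  } else {
    ord <- sort(syms)
  }
  paste0(vapply(ord, function(s) {
    n <- composition[[s]]
    if (n == 1L) s else paste0(s, n)
  }, character(1L)), collapse = "")
}

# Componentwise composition arithmetic over a common element set.
.compCombine <- function(a, b, fb = 1L) {
  syms <- union(names(a), names(b))
  out <- integer(length(syms)); names(out) <- syms
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + fb * b
  out
}

.compAdd <- function(a, b) .compCombine(a, b, 1L)
.compSub <- function(a, b) .compCombine(a, b, -1L)

# Total electron count of a species: sum Z * count - charge.
.electronCount <- function(composition, charge) {
  sum(.ELEMENTS[names(composition)] * composition) - charge
}
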