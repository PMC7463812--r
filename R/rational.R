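# Exact rational arithmetic for stoichiometric coefficients.
#
# Coefficients are kept as reduced integer numerator/denominator pairs so that
# element and charge balance checks are integer-exact, never float-tolerance.
# Only the small surface needed for stoichiometry is implemented: parsing,
# reduction, addition, scaling, and exact zero/equality tests.

.gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

#' Construct a reduced rational number
#'
#' Internal representation of an exact rational as a length-2 integer vector
#' \code{c(num, den)} with \code{den > 0} and \code{gcd(num, den) == 1}.
#'
#' @param num,den integer numerator and (nonzero) denominator.
#' @return integer vector \code{c(num, den)} in lowest terms.
#' @keywords internal
#' @noRd
.rat <- function(num, den = 1L) {
  num <- as.integer(num); den <- as.integer(den)
  if (is.na(num) || is.na(den) || den == 0L)
    stop("invalid rational: ", num, "/", den, call. = FALSE)
  if (den < 0L) { num <- -num; den <- -den }
  g <- .gcd(num, den)
  if (g > 1L) { num <- num %/% g; den <- den %/% g }
  c(num, den)
}

# Parse a coefficient given as a whole number or a "p/q" string.
.ratParse <- function(x) {
  if (is.numeric(x)) {
    if (length(x) != 1L || !is.finite(x) || x != round(x))
      stop("non-integer numeric coefficient ", deparse(x),
           "; write fractional coefficients as \"p/q\" strings", call. = FALSE)
    return(.rat(x))
  }
  if (is.character(x) && length(x) == 1L) {
    x <- trimws(x)
    if (grepl("^[+-]?[0-9]+$", x)) return(.rat(as.integer(x)))
    if (grepl("^[+-]?[0-9]+[[:space:]]*/[[:space:]]*[0-9]+$", x)) {
      parts <- strsplit(x, "/", fixed = TRUE)[[1L]]
      return(.rat(as.integer(trimws(parts[1L])), as.integer(trimws(parts[2L]))))
    }
  }
  stop("cannot parse stoichiometric coefficient: ", deparse(x), call. = FALSE)
}

.ratAdd <- function(a, b) .rat(a[1L] * b[2L] + b[1L] * a[2L], a[2L] * b[2L])
.ratMul <- function(a, b) .rat(a[1L] * b[1L], a[2L] * b[2L])
.ratNeg <- function(a) c(-a[1L], a[2L])
.ratIsZero <- function(a) a[1L] == 0L
.ratNumeric <- function(a) a[1L] / a[2L]

.ratFormat <- function(a) {
  if (a[2L] == 1L) as.character(a[1L]) else paste0(a[1L], "/", a[2L])
}

# Sum of rationals scaled by an integer vector: sum_i coef_i * n_i.
# `coefs` is a list of c(num, den); `n` an integer vector of equal length.
.ratDot <- function(coefs, n) {
  acc <- c(0L, 1L)
  for (i in seq_along(coefs))
    acc <- .ratAdd(acc, .ratMul(coefs[[i]], .rat(as.integer(n[i]))))
  acc
}
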