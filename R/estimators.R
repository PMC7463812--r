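#' @include schemes.R
NULL

#' Group-count vector for vaporization-enthalpy additivity
#'
#' Carbon counts of the hydrocarbyl part R of a monosubstituted compound RX,
#' plus the substituent label X whose additive term b(X) may be unknown
#' (symbolic): only differences between molecules sharing X are then
#' b-free.
#'
#' @param nC number of nonquaternary carbons in R (integer >= 0).
#' @param nQ number of quaternary carbons in R (integer >= 0).
#' @param substituent substituent label X (used to verify that b cancels in
#'   differences).
#' @return list of class \code{"groupCounts"}.
#' @export
groupCounts <- function(nC, nQ = 0L, substituent = "X") {
  stopifnot(length(nC) == 1L, length(nQ) == 1L, nC >= 0, nQ >= 0,
            nC == round(nC), nQ == round(nQ))
  structure(list(nC = as.integer(nC), nQ = as.integer(nQ),
                 substituent = as.character(substituent)),
            class = "groupCounts")
}

#' Group-additivity vaporization enthalpy
#'
#' \deqn{\Delta H_v(RX) = 1.12\,\tilde n_C(R) + 0.3\,n_Q(R) + 0.71 + b(X)}
#' in kcal/mol. When the substituent term \code{b} is unknown the carbon-only
#' part is returned and flagged symbolic; validated outputs in that case are
#' differences between molecules sharing X (see [hvDifference()]).
#'
#' @param groups a [groupCounts()] vector.
#' @param b substituent parameter b(X) in kcal/mol, or \code{NULL} (symbolic).
#' @return list with \code{value} (the numeric part), \code{symbolic}
#'   (\code{TRUE} iff b was unknown) and \code{substituent}.
#' @examples
#' hvEstimate(groupCounts(3))$value   # 4.07 (plus the symbolic b(X))
#' hvEstimate(groupCounts(0), b = 0)  # 0.71
#' @export
hvEstimate <- function(groups, b = NULL) {
  stopifnot(inherits(groups, "groupCounts"))
  base <- 1.12 * groups$nC + 0.3 * groups$nQ + 0.71
  list(value = base + if (is.null(b)) 0 else b, symbolic = is.null(b),
       substituent = groups$substituent)
}

#' Vaporization-enthalpy difference with a common substituent
#'
#' Difference of two group-additivity estimates for molecules sharing the
#' substituent X, so that the unknown b(X) cancels exactly:
#' \code{1.12 (nC_a - nC_b) + 0.3 (nQ_a - nQ_b)}. With R = C5H5 for pyridine
#' N-oxide and R = C3H9 for trimethylamine N-oxide (common X = NO), the
#' estimate is +2.24, i.e. the aromatic oxide is expected to have a
#' vaporization enthalpy about 2.2 kcal/mol higher.
#'
#' @param groupsA,groupsB [groupCounts()] vectors with identical
#'   \code{substituent} labels.
#' @return difference in kcal/mol (b-free).
#' @examples
#' hvDifference(groupCounts(5, substituent = "NO"),
#'              groupCounts(3, substituent = "NO"))  # 2.24
#' @export
hvDifference <- function(groupsA, groupsB) {
  stopifnot(inherits(groupsA, "groupCounts"), inherits(groupsB, "groupCounts"))
  if (!identical(groupsA$substituent, groupsB$substituent))
    stop("substituents differ ('", groupsA$substituent, "' vs '",
         groupsB$substituent, "'); b(X) does not cancel", call. = FALSE)
  1.12 * (groupsA$nC - groupsB$nC) + 0.3 * (groupsA$nQ - groupsB$nQ)
}

#' Harmonic force-constant ratio from stretch frequencies
#'
#' For harmonic oscillators \eqn{\nu = \frac{1}{2\pi}\sqrt{k/m_r}}, so
#' \deqn{k_a/k_b = (\nu_a/\nu_b)^2 \cdot (m_a/m_b).}
#' The default equal-reduced-mass assumption (both masses 1) is the crude
#' comparison appropriate when the two bonds involve the same atom pair;
#' explicit reduced masses are also accepted.
#'
#' @param freqA,freqB stretch frequencies in cm^-1 (> 0).
#' @param massA,massB reduced masses in amu (default equal).
#' @return dimensionless force-constant ratio k_a/k_b.
#' @examples
#' forceConstantRatio(1270, 940)  # ~1.83: "roughly 1.8"
#' @export
forceConstantRatio <- function(freqA, freqB, massA = 1, massB = 1) {
  stopifnot(freqA > 0, freqB > 0, massA > 0, massB > 0)
  (freqA / freqB)^2 * (massA / massB)
}

#' Benson-increment interpolation check
#'
#' Tests whether a mixed-substituent group increment (e.g.
#' [C-(H)2(N)(O)]) lies within the closed interval spanned by its two
#' homo-substituent neighbours ([C-(H)2(N)2], [C-(H)2(O)2]), and reports the
#' arithmetic midpoint of the neighbours for reference.
#'
#' @param valueNO the mixed increment, kcal/mol.
#' @param valueNN,valueOO the flanking increments, kcal/mol.
#' @return list with \code{interpolates} (logical) and \code{midpoint}.
#' @examples
#' bensonInterpolationCheck(-14.98, -12.75, -15.43)
#' @export
bensonInterpolationCheck <- function(valueNO, valueNN, valueOO) {
  stopifnot(is.finite(valueNO), is.finite(valueNN), is.finite(valueOO))
  lo <- min(valueNN, valueOO); hi <- max(valueNN, valueOO)
  list(interpolates = valueNO >= lo && valueNO <= hi,
       midpoint = (valueNN + valueOO) / 2)
}

#' Partition a sublimation enthalpy into vaporization + fusion
#'
#' Enforces the phase-cycle identity \code{dHsub = dHvap + dHfus} by
#' construction.
#'
#' @param dHvap,dHfus component enthalpies, kcal/mol (>= 0).
#' @return list of class \code{"phasePartition"} with \code{dHvap},
#'   \code{dHfus}, \code{dHsub}.
#' @examples
#' phasePartition(13, 6)$dHsub  # 19
#' @export
phasePartition <- function(dHvap, dHfus) {
  stopifnot(dHvap >= 0, dHfus >= 0)
  structure(list(dHvap = dHvap, dHfus = dHfus, dHsub = dHvap + dHfus),
            class = "phasePartition")
}

#' Sublimation-enthalpy revision and its effect on a relative BDE
#'
#' Implements the bookkeeping of revising an assumed sublimation enthalpy:
#' keeping \code{dHvap} from a baseline partition and raising \code{dHfus}
#' gives a new \code{dHsub}; the increase over the previously assumed
#' sublimation enthalpy adds to the species' gas-phase formation enthalpy
#' (\code{deltaDHfGas}), and the relative N-O BDE of that species against a
#' comparison oxide shifts by \code{deltaDHfGas + |coupling reaction
#' enthalpy|} (the coupling reaction being the isodesmic oxygen-transfer
#' equation linking the two oxides).
#'
#' Because the source arithmetic of this argument is itself approximate, the
#' stipulated formation-enthalpy increase may be supplied explicitly via
#' \code{stipulatedDelta} (reproducing the published "ca 6.0 + 2.3 = 8.3"
#' chain); otherwise it is computed mechanically from the partitions. When
#' both are available and differ, the divergence is reported via
#' \code{message()}.
#'
#' @param baseline a [phasePartition()] (e.g. 13 + 6 for the aromatic
#'   oxide's measured sublimation enthalpy).
#' @param revisedDHfus revised fusion enthalpy, kcal/mol (>= 0).
#' @param assumedDHsub the sublimation enthalpy previously assumed for the
#'   target species (default: the baseline partition's total).
#' @param couplingDHr enthalpy of the coupling isodesmic reaction, kcal/mol;
#'   alternatively supply \code{registry}, \code{reaction} and \code{method}
#'   to compute it.
#' @param stipulatedDelta explicitly stipulated formation-enthalpy increase
#'   (kcal/mol), or \code{NULL} to use the mechanical value.
#' @param registry,reaction,method optional route to \code{couplingDHr} via
#'   [reactionEnthalpy()]. Nothing in the registry is modified.
#' @return list with \code{newDHsub}, \code{deltaDHfGas} (the value used),
#'   \code{mechanicalDelta}, \code{bdeShift}.
#' @examples
#' base <- phasePartition(13, 6)
#' reviseSublimation(base, 11, stipulatedDelta = 6.0)$bdeShift  # 8.3
#' @export
reviseSublimation <- function(baseline, revisedDHfus,
                              assumedDHsub = baseline$dHsub,
                              couplingDHr = -2.3, stipulatedDelta = NULL,
                              registry = NULL, reaction = NULL,
                              method = "experimental") {
  stopifnot(inherits(baseline, "phasePartition"), revisedDHfus >= 0)
  if (!is.null(registry) && !is.null(reaction))
    couplingDHr <- reactionEnthalpy(reaction, registry, method)
  newDHsub <- baseline$dHvap + revisedDHfus
  mechanicalDelta <- newDHsub - assumedDHsub
  delta <- if (is.null(stipulatedDelta)) mechanicalDelta else stipulatedDelta
  if (!is.null(stipulatedDelta) &&
      abs(stipulatedDelta - mechanicalDelta) > 1e-9)
    message("stipulated formation-enthalpy increase (", stipulatedDelta,
            ") differs from the mechanical partition arithmetic (",
            round(mechanicalDelta, 2), ")")
  list(newDHsub = newDHsub, deltaDHfGas = delta,
       mechanicalDelta = mechanicalDelta,
       bdeShift = delta + abs(couplingDHr))
}
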