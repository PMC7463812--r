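#' @include reaction.R
NULL

# Composition gate shared by bde()/negTTRS(): oxide must be parent + one O,
# with equal charges.
.checkOxidePair <- function(registry, oxide, parent) {
  co <- .speciesComposition(registry, oxide)
  cp <- .speciesComposition(registry, parent)
  diff <- .compSub(co, cp)
  diff <- diff[diff != 0L]
  if (!(length(diff) == 1L && identical(names(diff), "O") && diff[[1L]] == 1L))
    stop("composition mismatch: '", oxide, "' is not '", parent,
         "' plus one oxygen atom", call. = FALSE)
  if (.speciesField(registry, oxide, "charge") !=
      .speciesField(registry, parent, "charge"))
    stop("charge mismatch between '", oxide, "' and '", parent, "'",
         call. = FALSE)
  invisible(TRUE)
}

#' N-O (X-O) bond dissociation enthalpy
#'
#' Enthalpy of \eqn{XO \rightarrow X + O(^3P)}, the BDE scale. The reaction
#' is element-balanced but not isogyric (0 vs 2 unpaired electrons); the
#' ground-state O-atom formation enthalpy of the chosen method must be on
#' record (59.6 kcal/mol experimentally; for calculated columns the package
#' fixtures carry gaps back-derived from the printed scale).
#'
#' @param registry a [ThermoRegistry-class].
#' @param oxide,parent species ids with \code{composition(oxide) ==
#'   composition(parent) + O} and equal charges.
#' @param method method tag.
#' @param oxygenAtom species id of the triplet O-atom reference.
#' @return BDE in kcal/mol.
#' @examples
#' reg <- exampleRegistry()
#' bde(reg, "tmao", "tma", "experimental")      # 61.1
#' bde(reg, "pno", "pyridine", "experimental")  # 63.4
#' @export
bde <- function(registry, oxide, parent, method = "experimental",
                oxygenAtom = "o_atom_3p") {
  .checkOxidePair(registry, oxide, parent)
  r <- Reaction(paste0("bde_", oxide), stats::setNames(list(1L), oxide),
                stats::setNames(list(1L, 1L), c(parent, oxygenAtom)))
  reactionEnthalpy(r, registry, method)
}

#' Reverse transfer thermodynamic reactivity scale (-TTRS)
#'
#' Enthalpy of \eqn{XO \rightarrow X + \frac{1}{2} O_2}. Differs from
#' [bde()] by the O-atom formation enthalpy of the method (the half-O2
#' reference is zero experimentally).
#'
#' @inheritParams bde
#' @param dioxygen species id of the O2 reference.
#' @return -TTRS value in kcal/mol.
#' @examples
#' reg <- exampleRegistry()
#' negTTRS(reg, "pno", "pyridine", "experimental")  # 3.8
#' negTTRS(reg, "co2", "co", "experimental")        # 67.7
#' @export
negTTRS <- function(registry, oxide, parent, method = "experimental",
                    dioxygen = "o2") {
  .checkOxidePair(registry, oxide, parent)
  r <- Reaction(paste0("ttrs_", oxide), stats::setNames(list(1L), oxide),
                stats::setNames(list(1L, "1/2"), c(parent, dioxygen)))
  reactionEnthalpy(r, registry, method)
}

# Modal value of gaps rounded to 0.1 kcal/mol (smallest wins a tie).
.modalGap <- function(gaps) {
  r <- round(gaps, 1L)
  tab <- table(r)
  as.numeric(names(tab)[which.max(tab)])
}

#' Audit a BDE / -TTRS scale for a constant per-method oxygen gap
#'
#' For each method, \code{bde - neg_ttrs} should be a constant: the O-atom
#' formation enthalpy on that method's scale. The auditor reports the modal
#' gap per method (mode of values rounded to 0.1 kcal/mol) and flags every
#' row deviating from it by more than \code{tolerance}.
#'
#' @param scale data.frame with columns \code{species_id}, \code{method},
#'   \code{bde}, \code{neg_ttrs} (one row per species/method; \code{NA} cells
#'   are skipped).
#' @param tolerance flagging threshold in kcal/mol (default 0.2, i.e. just
#'   above print-rounding wobble).
#' @return list with \code{methods} (data.frame: \code{method}, \code{gap},
#'   \code{n}, \code{n_outliers}) and \code{outliers} (data.frame:
#'   \code{method}, \code{species_id}, \code{gap}, \code{deviation}).
#' @examples
#' sc <- loadScaleTable(system.file("extdata", "scale_table3.csv",
#'                                  package = "ThermoHess"))
#' a <- auditScale(sc)
#' a$methods    # experimental 59.6; B3LYP/6-31G* 61.7; M06 57.1
#' a$outliers   # one anomalous M06 row
#' @export
auditScale <- function(scale, tolerance = 0.2) {
  stopifnot(all(c("species_id", "method", "bde", "neg_ttrs") %in% names(scale)))
  scale <- scale[is.finite(scale$bde) & is.finite(scale$neg_ttrs), , drop = FALSE]
  methodsOut <- data.frame(method = character(0), gap = numeric(0),
                           n = integer(0), n_outliers = integer(0),
                           stringsAsFactors = FALSE)
  outliers <- data.frame(method = character(0), species_id = character(0),
                         gap = numeric(0), deviation = numeric(0),
                         stringsAsFactors = FALSE)
  for (m in unique(scale$method)) {
    rows <- scale[scale$method == m, , drop = FALSE]
    gaps <- rows$bde - rows$neg_ttrs
    gap <- .modalGap(gaps)
    dev <- gaps - gap
    flag <- abs(dev) > tolerance
    methodsOut <- rbind(methodsOut,
                        data.frame(method = m, gap = gap, n = nrow(rows),
                                   n_outliers = sum(flag),
                                   stringsAsFactors = FALSE))
    if (any(flag))
      outliers <- rbind(outliers,
                        data.frame(method = m,
                                   species_id = rows$species_id[flag],
                                   gap = gaps[flag], deviation = dev[flag],
                                   stringsAsFactors = FALSE))
  }
  rownames(methodsOut) <- NULL; rownames(outliers) <- NULL
  list(methods = methodsOut, outliers = outliers)
}

#' Interconvert BDE and -TTRS columns of a scale via audited oxygen gaps
#'
#' Uses per-method gaps (as recovered by [auditScale()]) to fill one column
#' from the other: \code{bde = neg_ttrs + gap}.
#'
#' @param values numeric vector of scale values.
#' @param gap the method's oxygen gap (kcal/mol).
#' @param from \code{"neg_ttrs"} to convert -TTRS to BDE, \code{"bde"} for
#'   the reverse.
#' @return numeric vector.
#' @export
convertScale <- function(values, gap, from = c("neg_ttrs", "bde")) {
  from <- match.arg(from)
  if (from == "neg_ttrs") values + gap else values - gap
}

#' Proton-affinity difference
#'
#' \code{PA(a) - PA(b)} from \code{proton_affinity} records of one method.
#' Antisymmetric in its species arguments.
#'
#' @param registry a [ThermoRegistry-class].
#' @param a,b species ids.
#' @param method method tag.
#' @return difference in kcal/mol.
#' @examples
#' reg <- exampleRegistry()
#' deltaPA(reg, "tmao", "pno", "experimental")    # +14.3
#' deltaPA(reg, "tmao", "pno", "B3LYP/6-31G*")    # +17.8
#' @export
deltaPA <- function(registry, a, b, method = "experimental") {
  lookupProperty(registry, a, "proton_affinity", method)$value -
    lookupProperty(registry, b, "proton_affinity", method)$value
}

#' Relative formation enthalpies of a set of isomers
#'
#' Offsets each species' \code{dHf_gas} from the set minimum (lowest isomer
#' = 0.0), the convention of relative isomer ladders. All species must share
#' one composition and charge.
#'
#' @param registry a [ThermoRegistry-class].
#' @param ids character vector of isomer species ids.
#' @param method method tag.
#' @return named numeric vector of offsets (min = 0), in input order.
#' @examples
#' reg <- exampleRegistry()
#' isomerLadder(reg, c("nitromethane", "methyl_nitrite"), "experimental")
#' # 0.0, +2.0
#' @export
isomerLadder <- function(registry, ids, method = "experimental") {
  stopifnot(length(ids) >= 1L)
  comps <- lapply(ids, function(s) .speciesComposition(registry, s))
  canon <- vapply(comps, formulaString, character(1L))
  if (length(unique(canon)) != 1L)
    stop("species are not isomers: formulas ",
         paste(unique(canon), collapse = " vs "), call. = FALSE)
  ch <- .speciesField(registry, ids, "charge")
  if (length(unique(ch)) != 1L)
    stop("species are not isomers: charges differ", call. = FALSE)
  vals <- vapply(ids, function(s)
    lookupProperty(registry, s, "dHf_gas", method)$value, numeric(1L))
  vals - min(vals)
}
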