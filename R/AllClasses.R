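#' @include rational.R formula.R
NULL

# Quantities a PropertyRecord may carry, with their canonical storage units.
.QUANTITIES <- c(dHf_gas = "kcal/mol", dHf_crystal = "kcal/mol",
                 dHsub = "kcal/mol", dHfus = "kcal/mol", dHvap = "kcal/mol",
                 proton_affinity = "kcal/mol",
                 no_stretch_freq = "cm-1", no_bond_length = "angstrom",
                 dipole_moment = "debye")

.REACTION_CLASSES <- c("isodesmic", "isogyric", "plain")

#' ThermoRegistry: species and property records with method provenance
#'
#' A validated registry of chemical species (identity cards: composition,
#' charge, unpaired electrons) and property records (one measured or computed
#' quantity per species/quantity/method triple). Enthalpies and proton
#' affinities are stored in kcal/mol only; kJ/mol inputs are converted on
#' load. Method tags are free-form registered strings (e.g.
#' \code{"experimental"}, \code{"B3LYP/6-31G*"}) and are never silently
#' aliased.
#'
#' @slot species data.frame with columns \code{id}, \code{name},
#'   \code{formula}, \code{charge}, \code{unpaired_electrons}.
#' @slot properties data.frame with columns \code{species_id},
#'   \code{quantity}, \code{method}, \code{value}, \code{unit},
#'   \code{uncertainty}, \code{source}; \code{unit} is the canonical unit of
#'   the quantity.
#' @slot elements character vector, the allowed element universe.
#'
#' @seealso [loadRegistry()], [registryFromFrames()], [lookupProperty()]
#' @exportClass ThermoRegistry
setClass("ThermoRegistry",
  representation(species = "data.frame", properties = "data.frame",
                 elements = "character"))

setValidity("ThermoRegistry", function(object) {
  sp <- object@species
  pr <- object@properties
  msgs <- character(0)
  needSp <- c("id", "name", "formula", "charge", "unpaired_electrons")
  needPr <- c("species_id", "quantity", "method", "value", "unit",
              "uncertainty", "source")
  if (!all(needSp %in% names(sp)))
    return(paste("species table lacks columns:",
                 paste(setdiff(needSp, names(sp)), collapse = ", ")))
  if (!all(needPr %in% names(pr)))
    return(paste("property table lacks columns:",
                 paste(setdiff(needPr, names(pr)), collapse = ", ")))
  if (anyDuplicated(sp$id))
    msgs <- c(msgs, paste("duplicated species id:",
                          paste(unique(sp$id[duplicated(sp$id)]), collapse = ", ")))
  for (i in seq_len(nrow(sp))) {
    comp <- tryCatch(parseFormula(sp$formula[i], object@elements),
                     error = function(e) conditionMessage(e))
    if (is.character(comp)) { msgs <- c(msgs, comp); next }
    if (sp$unpaired_electrons[i] < 0)
      msgs <- c(msgs, paste0(sp$id[i], ": negative unpaired electron count"))
    ne <- .electronCount(comp, sp$charge[i])
    if ((ne %% 2L) != (sp$unpaired_electrons[i] %% 2L))
      msgs <- c(msgs, paste0(sp$id[i], ": unpaired-electron parity (",
                             sp$unpaired_electrons[i],
                             ") inconsistent with electron count (", ne, ")"))
  }
  if (nrow(pr)) {
    bad <- !pr$quantity %in% names(.QUANTITIES)
    if (any(bad))
      msgs <- c(msgs, paste("unknown quantity:",
                            paste(unique(pr$quantity[bad]), collapse = ", ")))
    orphan <- !pr$species_id %in% sp$id
    if (any(orphan))
      msgs <- c(msgs, paste("property record for unknown species:",
                            paste(unique(pr$species_id[orphan]), collapse = ", ")))
    key <- paste(pr$species_id, pr$quantity, pr$method, sep = "\r")
    if (anyDuplicated(key))
      msgs <- c(msgs, paste("duplicate (species, quantity, method) key:",
                            paste(unique(gsub("\r", "/", key[duplicated(key)])),
                                  collapse = "; ")))
    if (!all(is.finite(pr$value)))
      msgs <- c(msgs, "non-finite property value")
    wrongUnit <- !bad & pr$unit != .QUANTITIES[pr$quantity]
    if (any(wrongUnit))
      msgs <- c(msgs, paste("non-canonical unit stored for:",
                            paste(unique(pr$quantity[wrongUnit]), collapse = ", ")))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Reaction: exact rational stoichiometry
#'
#' A chemical reaction as a pair of species-to-coefficient maps. Coefficients
#' are exact rationals (reduced integer numerator/denominator pairs), so half
#' units such as the \eqn{\frac{1}{2}\,O_2} of an oxygen-transfer scale are
#' represented without floating-point error. No species may appear on both
#' sides.
#'
#' @slot id character scalar.
#' @slot reactants,products named lists of length-2 integer vectors
#'   \code{c(num, den)}, one per participating species.
#' @slot declaredClass one of \code{"isodesmic"}, \code{"isogyric"},
#'   \code{"plain"}. Isodesmicity is a user declaration (bond-type
#'   bookkeeping is not mechanized); element/charge balance, by contrast, is
#'   always checked mechanically.
#'
#' @seealso [Reaction()], [checkBalance()], [reactionEnthalpy()]
#' @exportClass Reaction
setClass("Reaction",
  representation(id = "character", reactants = "list", products = "list",
                 declaredClass = "character"))

setValidity("Reaction", function(object) {
  msgs <- character(0)
  if (length(object@id) != 1L || !nzchar(object@id))
    msgs <- c(msgs, "reaction id must be a nonempty string")
  for (side in list(object@reactants, object@products)) {
    if (!length(side)) { msgs <- c(msgs, "empty reaction side"); next }
    if (is.null(names(side)) || any(!nzchar(names(side))))
      msgs <- c(msgs, "unnamed coefficient")
    for (co in side)
      if (!is.integer(co) || length(co) != 2L || co[2L] <= 0L || co[1L] <= 0L)
        msgs <- c(msgs, "coefficients must be positive reduced rationals")
  }
  both <- intersect(names(object@reactants), names(object@products))
  if (length(both))
    msgs <- c(msgs, paste("species on both sides:",
                          paste(both, collapse = ", ")))
  if (!object@declaredClass %in% .REACTION_CLASSES)
    msgs <- c(msgs, "declaredClass must be isodesmic, isogyric or plain")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' BalanceReport: element, charge and spin accounting for a reaction
#'
#' Produced by [checkBalance()]. Imbalances are signed reactant-minus-product
#' differences computed with exact rational arithmetic (the numeric slots are
#' exact because every intermediate is integer). A reaction is balanced iff
#' all element and charge imbalances vanish; it is isogyric iff the
#' unpaired-electron counts also match across sides. Imbalance is reported,
#' never raised.
#'
#' @slot reactionId character scalar.
#' @slot elementImbalance named numeric, per-element signed deficit
#'   (reactants minus products).
#' @slot chargeImbalance,unpairedImbalance numeric scalars.
#' @slot isBalanced,isIsogyric logical scalars.
#' @exportClass BalanceReport
setClass("BalanceReport",
  representation(reactionId = "character", elementImbalance = "numeric",
                 chargeImbalance = "numeric", unpairedImbalance = "numeric",
                 isBalanced = "logical", isIsogyric = "logical"))

#' SyntheticNetwork: generated thermochemical network with known ground truth
#'
#' A synthetic registry plus exactly balanced reactions whose true reaction
#' enthalpies are known by construction, used as an oracle for the reaction
#' engine and the scale auditor. Per pseudo-method measurement records equal
#' truth + method offset (+ optional Gaussian noise); the ground truth itself
#' is never perturbed.
#'
#' @slot registry a [ThermoRegistry-class] holding the measurement records.
#' @slot reactions list of [Reaction-class] objects.
#' @slot reactionTruth named numeric, ground-truth reaction enthalpy per
#'   reaction id (kcal/mol).
#' @slot speciesTruth data.frame with columns \code{id}, \code{dHf_true}.
#' @slot methodOffsets named numeric, additive offset per pseudo-method.
#' @slot seed integer seed the network was generated from.
#' @seealso [generateNetwork()], [generateOxideFamily()]
#' @exportClass SyntheticNetwork
setClass("SyntheticNetwork",
  representation(registry = "ThermoRegistry", reactions = "list",
                 reactionTruth = "numeric", speciesTruth = "data.frame",
                 methodOffsets = "numeric", seed = "integer"))
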