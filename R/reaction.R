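#' @include registry.R
NULL

#' Construct a Reaction
#'
#' @param id reaction identifier.
#' @param reactants,products named vectors/lists mapping species id to a
#'   positive coefficient; coefficients are whole numbers or \code{"p/q"}
#'   strings (e.g. \code{"1/2"} for half an O2).
#' @param class declared reaction class: \code{"isodesmic"},
#'   \code{"isogyric"} or \code{"plain"} (default). The class is a user
#'   declaration; element/charge balance is checked mechanically by
#'   [checkBalance()] regardless.
#' @return a [Reaction-class] object.
#' @examples
#' # (CH3)3NO + pyridine -> (CH3)3N + pyridine N-oxide
#' r <- Reaction("eq1", c(tmao = 1, pyridine = 1), c(tma = 1, pno = 1),
#'               class = "isodesmic")
#' @export
Reaction <- function(id, reactants, products, class = "plain") {
  toSide <- function(x) {
    if (is.null(names(x)) && is.list(x)) x <- unlist(x)
    out <- lapply(seq_along(x), function(i) .ratParse(x[[i]]))
    names(out) <- names(x)
    out
  }
  methods::new("Reaction", id = as.character(id), reactants = toSide(reactants),
               products = toSide(products), declaredClass = class)
}

setMethod("show", "Reaction", function(object) {
  fmt <- function(side) paste(vapply(names(side), function(s) {
    co <- side[[s]]
    if (co[1L] == 1L && co[2L] == 1L) s else paste(.ratFormat(co), s)
  }, character(1L)), collapse = " + ")
  cat("Reaction ", object@id, " [", object@declaredClass, "]\n  ",
      fmt(object@reactants), " -> ", fmt(object@products), "\n", sep = "")
  invisible(NULL)
})

#' Reverse a reaction
#'
#' @param reaction a [Reaction-class].
#' @param id id for the reversed reaction (default \code{"<id>_rev"}).
#' @return a [Reaction-class] with sides swapped. Its reaction enthalpy is
#'   the negation of the original's.
#' @export
reverseReaction <- function(reaction, id = paste0(reaction@id, "_rev")) {
  methods::new("Reaction", id = id, reactants = reaction@products,
               products = reaction@reactants,
               declaredClass = reaction@declaredClass)
}

# Net signed coefficient map (products positive) as a list of rationals.
.netCoefs <- function(reaction) {
  out <- list()
  for (s in names(reaction@reactants))
    out[[s]] <- .ratNeg(reaction@reactants[[s]])
  for (s in names(reaction@products)) {
    prev <- if (s %in% names(out)) out[[s]] else c(0L, 1L)
    out[[s]] <- .ratAdd(prev, reaction@products[[s]])
  }
  out
}

#' Rational linear combination of two reactions
#'
#' Forms \code{w1*r1 + w2*r2} with exact rational weights, cancelling species
#' that net to zero and placing net-negative coefficients on the reactant
#' side. Reaction enthalpy is linear under this operation.
#'
#' @param r1,r2 [Reaction-class] objects.
#' @param w1,w2 weights (whole numbers or \code{"p/q"} strings).
#' @param id id of the combined reaction.
#' @return a [Reaction-class].
#' @export
combineReactions <- function(r1, r2, w1 = 1, w2 = 1,
                             id = paste0(r1@id, "+", r2@id)) {
  w1 <- .ratParse(w1); w2 <- .ratParse(w2)
  acc <- list()
  addIn <- function(acc, coefs, w) {
    for (s in names(coefs)) {
      prev <- if (s %in% names(acc)) acc[[s]] else c(0L, 1L)
      acc[[s]] <- .ratAdd(prev, .ratMul(w, coefs[[s]]))
    }
    acc
  }
  acc <- addIn(acc, .netCoefs(r1), w1)
  acc <- addIn(acc, .netCoefs(r2), w2)
  reac <- list(); prod <- list()
  for (s in names(acc)) {
    co <- acc[[s]]
    if (.ratIsZero(co)) next
    if (co[1L] > 0L) prod[[s]] <- co else reac[[s]] <- .ratNeg(co)
  }
  if (!length(reac) || !length(prod))
    stop("combination cancels to an empty reaction side", call. = FALSE)
  methods::new("Reaction", id = id, reactants = reac, products = prod,
               declaredClass = "plain")
}

#' Element, charge and spin balance of a reaction
#'
#' Exact rational accounting of per-element, charge and unpaired-electron
#' (spin) balance against a registry's species cards. Imbalance is reported
#' in the returned [BalanceReport-class], never raised; only an unknown
#' species id is an error. The sign convention is reactants minus products.
#'
#' @param reaction a [Reaction-class].
#' @param registry a [ThermoRegistry-class] defining the species.
#' @return a [BalanceReport-class].
#' @examples
#' reg <- exampleRegistry()
#' r <- Reaction("eq2", c(tmao = 1), c(tma = 1, o_atom_3p = 1))
#' rep <- checkBalance(r, reg)
#' rep@isBalanced   # TRUE: element- and charge-balanced
#' rep@isIsogyric   # FALSE: 0 vs 2 unpaired electrons
#' @export
setMethod("checkBalance", signature("Reaction", "ThermoRegistry"),
  function(reaction, registry) {
    ids <- c(names(reaction@reactants), names(reaction@products))
    comps <- lapply(ids, function(s) .speciesComposition(registry, s))
    elems <- unique(unlist(lapply(comps, names)))
    names(comps) <- ids
    signedCoefs <- c(reaction@reactants,
                     lapply(reaction@products, .ratNeg))
    elemImb <- numeric(length(elems)); names(elemImb) <- elems
    balanced <- TRUE
    for (e in elems) {
      counts <- vapply(ids, function(s) {
        co <- comps[[s]]
        if (e %in% names(co)) co[[e]] else 0L
      }, integer(1L))
      tot <- .ratDot(signedCoefs, counts)
      elemImb[[e]] <- .ratNumeric(tot)
      if (!.ratIsZero(tot)) balanced <- FALSE
    }
    charges <- vapply(ids, function(s) .speciesField(registry, s, "charge"),
                      integer(1L))
    chTot <- .ratDot(signedCoefs, charges)
    if (!.ratIsZero(chTot)) balanced <- FALSE
    unp <- vapply(ids,
                  function(s) .speciesField(registry, s, "unpaired_electrons"),
                  integer(1L))
    unpTot <- .ratDot(signedCoefs, unp)
    methods::new("BalanceReport", reactionId = reaction@id,
                 elementImbalance = elemImb,
                 chargeImbalance = .ratNumeric(chTot),
                 unpairedImbalance = .ratNumeric(unpTot),
                 isBalanced = balanced, isIsogyric = .ratIsZero(unpTot))
  })

setMethod("show", "BalanceReport", function(object) {
  cat("BalanceReport for '", object@reactionId, "': ",
      if (object@isBalanced) "balanced" else "NOT balanced", ", ",
      if (object@isIsogyric) "isogyric" else "non-isogyric", "\n", sep = "")
  nz <- object@elementImbalance[object@elementImbalance != 0]
  if (length(nz))
    cat("  element imbalance (reactants - products): ",
        paste(names(nz), sprintf("%+g", nz), collapse = ", "), "\n", sep = "")
  if (object@chargeImbalance != 0)
    cat("  charge imbalance:", sprintf("%+g", object@chargeImbalance), "\n")
  if (object@unpairedImbalance != 0)
    cat("  unpaired-electron imbalance:",
        sprintf("%+g", object@unpairedImbalance), "\n")
  invisible(NULL)
})

#' Hess's-law reaction enthalpy
#'
#' \deqn{\Delta H_r = \sum_{products} \nu_i \Delta H_f(i) -
#'       \sum_{reactants} \nu_j \Delta H_f(j)}
#' using \code{dHf_gas} records of a single method. The reaction must be
#' element- and charge-balanced; by default an unbalanced reaction is a hard
#' error (\code{strict = TRUE}). Non-isogyric but element-balanced reactions
#' (e.g. dissociation of an N-oxide to amine + triplet O) pass the balance
#' gate; isogyricity is reported by [checkBalance()], not enforced here.
#'
#' @param reaction a [Reaction-class].
#' @param registry a [ThermoRegistry-class].
#' @param method method tag whose \code{dHf_gas} records to use; no cross-
#'   method fallback.
#' @param strict if \code{TRUE} (default) element/charge imbalance is an
#'   error; if \code{FALSE} it is downgraded to a warning (for deliberately
#'   schematic bookkeeping).
#' @param ... ignored.
#' @return reaction enthalpy in kcal/mol.
#' @examples
#' reg <- exampleRegistry()
#' eq1 <- Reaction("eq1", c(tmao = 1, pyridine = 1), c(tma = 1, pno = 1),
#'                 class = "isodesmic")
#' reactionEnthalpy(eq1, reg, "experimental")  # -2.3
#' @export
setMethod("reactionEnthalpy", signature("Reaction", "ThermoRegistry"),
  function(reaction, registry, method = "experimental", strict = TRUE, ...) {
    rep <- checkBalance(reaction, registry)
    if (!rep@isBalanced) {
      msg <- paste0("reaction '", reaction@id,
                    "' is not element/charge balanced")
      if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    }
    total <- 0
    for (s in names(reaction@products))
      total <- total + .ratNumeric(reaction@products[[s]]) *
        lookupProperty(registry, s, "dHf_gas", method)$value
    for (s in names(reaction@reactants))
      total <- total - .ratNumeric(reaction@reactants[[s]]) *
        lookupProperty(registry, s, "dHf_gas", method)$value
    total
  })

#' Solve a reaction for one unknown formation enthalpy
#'
#' Given a reaction, a known reaction enthalpy and exactly one participant
#' whose \code{dHf_gas} is absent from the registry (for the chosen method),
#' returns the formation enthalpy that makes [reactionEnthalpy()] equal the
#' known value. This generalizes the assembly of a gas-phase formation
#' enthalpy from combustion plus sublimation data.
#'
#' @param reaction a [Reaction-class].
#' @param registry a [ThermoRegistry-class].
#' @param method method tag.
#' @param knownDHr known reaction enthalpy, kcal/mol.
#' @param unknown species id of the single unknown; it must participate with
#'   nonzero coefficient, and must be the only participant lacking a record.
#' @return formation enthalpy of \code{unknown} in kcal/mol.
#' @examples
#' reg <- exampleRegistry()
#' eq1 <- Reaction("eq1", c(tmao = 1, pyridine = 1), c(tma = 1, pno = 1))
#' # pretend pno were unknown: recover +29.8 from the printed -2.3
#' solveUnknown(eq1, dropProperty(reg, "pno", "dHf_gas", "experimental"),
#'              "experimental", -2.3, "pno")
#' @export
setMethod("solveUnknown", signature("Reaction", "ThermoRegistry"),
  function(reaction, registry, method, knownDHr, unknown) {
    ids <- c(names(reaction@reactants), names(reaction@products))
    if (!unknown %in% ids)
      stop("species '", unknown, "' does not participate in reaction '",
           reaction@id, "'", call. = FALSE)
    has <- vapply(ids, function(s) {
      ok <- tryCatch({ lookupProperty(registry, s, "dHf_gas", method); TRUE },
                     error = function(e) FALSE)
      ok
    }, logical(1L))
    missing <- ids[!has]
    if (!identical(missing, unknown)) {
      if (!length(missing))
        stop("no unknown: every participant has a dHf_gas record for method '",
             method, "'", call. = FALSE)
      stop("multiple participants lack dHf_gas records: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    rep <- checkBalance(reaction, registry)
    if (!rep@isBalanced)
      stop("reaction '", reaction@id, "' is not balanced", call. = FALSE)
    # signed coefficient of the unknown (products positive)
    net <- .netCoefs(reaction)[[unknown]]
    nu <- .ratNumeric(net)
    partial <- 0
    for (s in setdiff(names(reaction@products), unknown))
      partial <- partial + .ratNumeric(reaction@products[[s]]) *
        lookupProperty(registry, s, "dHf_gas", method)$value
    for (s in setdiff(names(reaction@reactants), unknown))
      partial <- partial - .ratNumeric(reaction@reactants[[s]]) *
        lookupProperty(registry, s, "dHf_gas", method)$value
    (knownDHr - partial) / nu
  })

#' Remove one property record from a registry
#'
#' Convenience for remove-then-solve round trips and for constructing
#' degenerate inputs in tests.
#'
#' @param registry a [ThermoRegistry-class].
#' @param species,quantity,method key of the record to drop.
#' @return the registry without that record.
#' @export
dropProperty <- function(registry, species, quantity, method) {
  pr <- registry@properties
  keep <- !(pr$species_id == species & pr$quantity == quantity &
              pr$method == method)
  if (all(keep))
    stop("no such record: ", species, "/", quantity, "/", method, call. = FALSE)
  methods::new("ThermoRegistry", species = registry@species,
               properties = pr[keep, , drop = FALSE],
               elements = registry@elements)
}

#' Load reaction definitions from a YAML or JSON file
#'
#' Each entry is a map with fields \code{id}, \code{reactants},
#' \code{products} (species to coefficient; coefficients are integers or
#' \code{"p/q"} strings) and optional \code{class}.
#'
#' @param path file path.
#' @return named list of [Reaction-class] objects.
#' @examples
#' rx <- loadReactions(system.file("extdata", "reactions.yaml",
#'                                 package = "ThermoHess"))
#' names(rx)
#' @export
loadReactions <- function(path) {
  entries <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  out <- lapply(entries, function(e) {
    if (is.null(e$id) || is.null(e$reactants) || is.null(e$products))
      stop("reaction entry lacks id/reactants/products", call. = FALSE)
    Reaction(e$id, e$reactants, e$products,
             class = if (is.null(e$class)) "plain" else e$class)
  })
  names(out) <- vapply(out, function(r) r@id, character(1L))
  out
}
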