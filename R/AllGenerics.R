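#' @include AllClasses.R
NULL

#' @rdname ThermoRegistry-class
#' @param object,x a \code{ThermoRegistry}.
#' @export
setGeneric("speciesTable", function(x) standardGeneric("speciesTable"))

#' @rdname ThermoRegistry-class
#' @export
setGeneric("propertyTable", function(x) standardGeneric("propertyTable"))

#' @rdname ThermoRegistry-class
#' @export
setGeneric("elementUniverse", function(x) standardGeneric("elementUniverse"))

#' Look up a single property record
#'
#' Exact lookup of one \code{(species, quantity, method)} record. There is
#' deliberately no fallback across methods: a missing record is an error, so
#' that any mixing of provenance (e.g. experimental with a DFT model) is
#' always explicit in calling code.
#'
#' @param x a [ThermoRegistry-class].
#' @param species species id.
#' @param quantity one of the registered quantity kinds (e.g.
#'   \code{"dHf_gas"}, \code{"proton_affinity"}).
#' @param method method tag, e.g. \code{"experimental"} or
#'   \code{"B3LYP/6-31G*"}.
#' @return list with elements \code{value}, \code{uncertainty} (NA when not
#'   reported), \code{unit} and \code{source}.
#' @examples
#' reg <- exampleRegistry()
#' lookupProperty(reg, "tmao", "dHf_gas", "experimental")$value  # -7.2
#' @export
setGeneric("lookupProperty",
           function(x, species, quantity, method) standardGeneric("lookupProperty"))

#' @rdname checkBalance
#' @export
setGeneric("checkBalance",
           function(reaction, registry) standardGeneric("checkBalance"))

#' @rdname reactionEnthalpy
#' @export
setGeneric("reactionEnthalpy",
           function(reaction, registry, method = "experimental", ...)
             standardGeneric("reactionEnthalpy"))

#' @rdname solveUnknown
#' @export
setGeneric("solveUnknown",
           function(reaction, registry, method, knownDHr, unknown)
             standardGeneric("solveUnknown"))
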