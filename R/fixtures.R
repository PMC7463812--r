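#' @include report.R
NULL

#' Path to a packaged fixture file
#'
#' @param name file name under the package's \code{extdata} directory.
#' @return absolute path.
#' @export
fixturePath <- function(name) {
  p <- system.file("extdata", name, package = "ThermoHess")
  if (!nzchar(p)) stop("no packaged fixture named '", name, "'", call. = FALSE)
  p
}

#' The packaged N-oxide thermochemistry registry
#'
#' Species and property records transcribed or reconciled from published
#' gas-phase thermochemistry of amine/lactam N-oxides and reference
#' compounds: experimental formation enthalpies, proton affinities, N-O
#' stretch frequencies, bond lengths and dipole moments, plus per-model
#' (DFT) formation-enthalpy records anchored so that only differences are
#' meaningful (see the sources column and the methods vignette).
#'
#' @param quiet suppress the record-count message (default TRUE here).
#' @return a [ThermoRegistry-class].
#' @examples
#' reg <- exampleRegistry()
#' reg
#' @export
exampleRegistry <- function(quiet = TRUE) {
  loadRegistry(fixturePath("species.csv"), fixturePath("properties.csv"),
               quiet = quiet)
}

#' The packaged reaction schemes
#'
#' Named oxygen-transfer, dissociation, resonance and oxidation reactions
#' over the packaged registry, including one deliberately unbalanced
#' literature variant (\code{re_benzene_printed}) kept to document a
#' coefficient misprint in its source scheme.
#'
#' @return named list of [Reaction-class] objects.
#' @export
exampleReactions <- function() {
  loadReactions(fixturePath("reactions.yaml"))
}
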