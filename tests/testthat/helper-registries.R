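# Small in-code registries for unit tests.

# Minimal oxide pair with tunable enthalpies (X, XO, O references, H2).
tinyOxideRegistry <- function(dhfX = 10, dhfXO = 5, hO = 59.6,
                              method = "experimental") {
  species <- data.frame(
    id = c("x", "xo", "o_atom_3p", "o2", "h2"),
    name = c("parent", "oxide", "O atom", "dioxygen", "dihydrogen"),
    formula = c("C2H7N", "C2H7NO", "O", "O2", "H2"),
    charge = 0L,
    unpaired_electrons = c(0L, 0L, 2L, 2L, 0L),
    stringsAsFactors = FALSE)
  props <- data.frame(
    species_id = c("x", "xo", "o_atom_3p", "o2", "h2"),
    quantity = "dHf_gas", method = method,
    value = c(dhfX, dhfXO, hO, 0, 0),
    unit = "kcal/mol", uncertainty = NA_real_, source = "test",
    stringsAsFactors = FALSE)
  registryFromFrames(species, props)
}

# Four-species chain sharing one composition offset, for scheme tests:
# arene C5H5N -> +H2 -> +H2 -> +H2, all at a common enthalpy `level`.
flatChainRegistry <- function(level = 0, method = "experimental") {
  species <- data.frame(
    id = c("ar", "di", "en", "sa", "h2"),
    name = c("arene", "diene", "ene", "saturated", "dihydrogen"),
    formula = c("C5H5N", "C5H7N", "C5H9N", "C5H11N", "H2"),
    charge = 0L, unpaired_electrons = 0L, stringsAsFactors = FALSE)
  props <- data.frame(
    species_id = c("ar", "di", "en", "sa", "h2"),
    quantity = "dHf_gas", method = method,
    value = c(rep(level, 4L), 0),
    unit = "kcal/mol", uncertainty = NA_real_, source = "test",
    stringsAsFactors = FALSE)
  registryFromFrames(species, props)
}
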