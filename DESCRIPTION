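Package: ThermoHess
Title: Hess's-Law Thermochemical Networks and Derived Enthalpy Scales for
    Amine N-Oxides
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for auditing and deriving gas-phase thermochemistry of
    amine and lactam N-oxides from curated enthalpy-of-formation registries.
    Represents species and measured or computed property records with explicit
    method provenance, reactions with exact rational stoichiometry and
    element/charge/spin balance reports, and computes Hess's-law reaction
    enthalpies, N-O bond dissociation enthalpy and oxygen-transfer (-TTRS)
    scales, proton-affinity differences, isomer ladders, hydrogenation
    sequences, isodesmic resonance energies, Dewar-Breslow aromaticity
    comparisons, oxidation enthalpies, group-additivity vaporization
    estimates, force-constant ratios, and sublimation-partition revisions.
    Includes a synthetic thermochemical-network generator with known ground
    truth for validation, and a consistency auditor that flags scale outliers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'formula.R'
    'rational.R'
    'AllClasses.R'
    'AllGenerics.R'
    'registry.R'
    'reaction.R'
    'scales.R'
    'schemes.R'
    'estimators.R'
    'synthetic.R'
    'report.R'
    'fixtures.R'
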