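# ThermoHess

Hess's-law thermochemical networks and derived enthalpy scales for amine and
lactam N-oxides.

## What it is for

Gas-phase enthalpies of formation of amine N-oxides — trimethylamine N-oxide
(TMAO), pyridine N-oxide (PNO), bridgehead bicyclic and lactam N-oxides —
are scarce, and the quantities chemists actually argue about (N–O bond
dissociation enthalpies, oxygen-transfer scales, resonance and aromaticity
energies, oxidation exothermicities) are all Hess's-law combinations of a
small registry of measured and computed numbers. ThermoHess is for
thermochemists and cheminformaticians who want that inference layer as
tested, audited code rather than spreadsheet arithmetic.

The core objects and operations:

* a validated **species/property registry** (composition, charge, unpaired
  electrons; records keyed by species × quantity × method tag, kcal/mol
  canonical, no silent cross-method fallback);
* **reactions with exact rational stoichiometry**, integer-exact
  element/charge/spin balance reports, Hess's-law reaction enthalpies
  ΔH°r = Σ νᵢ ΔH°f(products) − Σ νⱼ ΔH°f(reactants), and solve-for-one-unknown;
* **derived scales**: BDE (XO → X + O(³P)) and −TTRS (XO → X + ½O₂), with a
  consistency auditor that recovers each method's constant O-atom gap
  (BDE − (−TTRS)) and flags outliers; proton-affinity differences, isomer
  ladders, hydrogenation sequences, isodesmic resonance energies
  (3 C₆H₁₀ → 2 C₆H₁₂ + C₆H₆ and aza/N-oxide analogues), Dewar–Breslow
  aromaticity, oxidation enthalpies (H₂O₂ → H₂O, DMDO → acetone);
* **estimators**: group-additivity vaporization enthalpy
  ΔHv = 1.12 ñC + 0.3 nQ + 0.71 + b(X), harmonic force-constant ratios
  (νa/νb)²(ma/mb), Benson-increment interpolation, and the
  ΔHsub = ΔHv + ΔHfus revision argument;
* a **synthetic network generator** with exactly balanced random reactions
  and known ground truth, used as the oracle for every engine test.

## Worked example

```r
library(ThermoHess)
reg <- exampleRegistry()          # packaged N-oxide registry
rx  <- exampleReactions()         # named reaction schemes

# Oxygen transfer between the two reference N-oxides:
reactionEnthalpy(rx$eq_oat, reg, "experimental")
#> [1] -2.3

# N-O bond dissociation enthalpies (XO -> X + triplet O):
bde(reg, "tmao", "tma")           # 61.1
bde(reg, "pno", "pyridine")       # 63.4

# The oxygen-transfer scale and its audit:
negTTRS(reg, "pno", "pyridine")   # 3.8
auditReport()$methods
#>             method  gap  n n_outliers
#> 1     experimental 59.6  7          0
#> 2     B3LYP/6-31G* 61.7 18          0
#> 3 M06/6-311G+(d,p) 57.1 18          1

# Proton-affinity difference and a resonance energy:
deltaPA(reg, "tmao", "pno")                       # 14.3
resonanceIsodesmic(reg, "benzene")$re             # 35.61

# Solve a reaction for one missing formation enthalpy:
solveUnknown(rx$eq_oat,
             dropProperty(reg, "pno", "dHf_gas", "experimental"),
             "experimental", knownDHr = -2.3, unknown = "pno")
#> [1] 29.8
```

The registry's BDE of 61.1 kcal/mol for TMAO and 63.4 for PNO differ by
exactly the −2.3 kcal/mol oxygen-transfer enthalpy — the internal identity
the audit machinery enforces. The one flagged M06 row is a genuine anomaly
in the source scale table (see the methods vignette).

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/thermohess-report.R tables --format markdown
Rscript inst/scripts/thermohess-report.R audit --method "M06/6-311G+(d,p)"
```

## Package layout

* `R/` — registry, reaction engine, scales, schemes, estimators, synthetic
  generator, reporting.
* `inst/extdata/` — species/property registry, reaction schemes, and the
  fixture tables (dissociation scale, model comparison, hydrogenation
  steps, oxidation enthalpies) as plain CSV/YAML.
* `vignettes/thermohess-methods.Rmd` — the model, fixture-reconciliation
  decisions, generator design, and known source-table inconsistencies.
* `tests/testthat/` — unit, property and acceptance suites.
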