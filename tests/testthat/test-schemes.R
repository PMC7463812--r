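reg <- exampleRegistry()

test_that("hydrogenation sequences reproduce the printed step enthalpies", {
  hb <- hydrogenationSequence(reg, "benzene", "experimental")
  expect_equal(unname(hb$steps), c(5.7, -26.6, -28.3), tolerance = 0.051)
  expect_equal(hb$total, -49.2, tolerance = 0.051)
  expect_equal(hb$total, sum(hb$steps))  # identity, exact
  hp <- hydrogenationSequence(reg, "pyridine", "experimental")
  expect_equal(hp$total, -44.9, tolerance = 0.051)
  # model columns were propagated from the printed steps: exact to 1e-12
  hm <- hydrogenationSequence(reg, "pno", "B3LYP/6-31G*")
  expect_equal(unname(hm$steps), c(0.1, -23.6, -3.5))
  expect_equal(hydrogenationSequence(reg, "benzene", "M06/6-311G+(d,p)")$total,
               -54.3)
  expect_error(hydrogenationSequence(reg, "pno", "experimental"), "no record")
  expect_error(hydrogenationSequence(reg, "nonesuch"), "unknown scheme")
})

test_that("a flat chain with zero H2 reference has all-zero steps", {
  treg <- flatChainRegistry(level = 7.25)
  # redirect the built-in scheme machinery through a hand-built chain
  steps <- vapply(list(c("ar", "di"), c("di", "en"), c("en", "sa")),
                  function(p) reactionEnthalpy(
                    Reaction("s", setNames(list(1L, 1L), c(p[1], "h2")),
                             setNames(list(1L), p[2])), treg),
                  numeric(1))
  expect_equal(steps, c(0, 0, 0))
})

test_that("first-step aromaticity measures benzene and pyridine as printed", {
  expect_equal(aromaticityFirstStep(reg, "benzene", "experimental"), 34.0,
               tolerance = 0.051)
  expect_equal(aromaticityFirstStep(reg, "pyridine", "experimental"), 31.0,
               tolerance = 0.051)
  # dH1 equal to the reference step gives zero by construction
  hb <- hydrogenationSequence(reg, "benzene", "experimental")
  expect_equal(aromaticityFirstStep(reg, "benzene", "experimental",
                                    referenceDH3 = hb$steps[["dH1"]]), 0)
  # the alternative -28.6 reference is configurable
  expect_equal(aromaticityFirstStep(reg, "benzene", "experimental",
                                    referenceDH3 = -28.6),
               34.3, tolerance = 0.051)
})

test_that("saturation enthalpies (3 H2) match the printed comparison table", {
  expect_equal(saturationEnthalpy(reg, "benzene", "cyclohexane"), -49.2,
               tolerance = 0.051)
  expect_equal(saturationEnthalpy(reg, "phenol", "cyclohexanol"), -45.4)
  expect_equal(saturationEnthalpy(reg, "phenoxide", "cyclohexanoxide"), -20.2)
  expect_equal(saturationEnthalpy(reg, "pyridine", "piperidine"), -44.9,
               tolerance = 0.051)
  expect_equal(saturationEnthalpy(reg, "phenol", "cyclohexanol",
                                  "M06/6-311G+(d,p)"), -54.3)
  expect_error(saturationEnthalpy(reg, "benzene", "cyclohexene"),
               "composition mismatch")
  # identical enthalpies give zero
  treg <- flatChainRegistry(3)
  expect_equal(saturationEnthalpy(treg, "ar", "sa"), 0)
})

test_that("isodesmic resonance energies carry the stabilization-positive sign", {
  expect_equal(resonanceIsodesmic(reg, "benzene", "experimental")$re, 35.6,
               tolerance = 0.051)
  expect_equal(resonanceIsodesmic(reg, "pyridine", "experimental")$re, 32.5,
               tolerance = 0.051)
  expect_equal(resonanceIsodesmic(reg, "benzene", "B3LYP/6-31G*")$re, 39.5)
  expect_equal(resonanceIsodesmic(reg, "pyridine", "M06/6-311G+(d,p)")$re, 35.7,
               tolerance = 1e-12)
  expect_equal(resonanceIsodesmic(reg, "pno", "B3LYP/6-31G*")$re, 33.7,
               tolerance = 1e-12)
  # all-zero enthalpies give zero resonance energy
  species <- data.frame(id = c("cyclohexene", "cyclohexane", "benzene"),
                        name = "s", formula = c("C6H10", "C6H12", "C6H6"),
                        charge = 0L, unpaired_electrons = 0L)
  props <- data.frame(species_id = species$id, quantity = "dHf_gas",
                      method = "experimental", value = 0, unit = "kcal/mol",
                      uncertainty = NA_real_, source = "test")
  expect_equal(resonanceIsodesmic(registryFromFrames(species, props),
                                  "benzene")$re, 0)
})

test_that("extra resonance of the conjugated anion is the printed double difference", {
  expect_equal(extraResonance(reg), 25.4)
  expect_equal(extraResonance(reg, pairA = c("phenol", "phenol"),
                              pairB = c("phenoxide", "phenoxide")), 0)
})

test_that("acyclic-analogue aromaticity comparisons match the printed values", {
  expect_equal(dewarBreslow(reg, "benzene", "stilbene"), 36.9)
  expect_equal(dewarBreslow(reg, "pyridine", "benzylideneaniline"), 35.2)
  expect_equal(dewarBreslow(reg, "pno", "diphenylnitrone"), 33.1)
  # equal enthalpies, zero correction: zero
  treg <- flatChainRegistry(5)
  expect_equal(dewarBreslow(treg, "ar", "di"), 0)
  # synthetic pair with a known offset shifts by offset minus correction
  expect_equal(dewarBreslow(reg, "pno", "diphenylnitrone", capCorrection = 2),
               31.1)
  # translation: shifting both members by a constant leaves it unchanged
  expect_equal(dewarBreslow(reg, "pyridine", "benzylideneaniline",
                            "experimental"),
               lookupProperty(reg, "benzylideneaniline", "dHf_gas",
                              "experimental")$value + 10 -
                 (lookupProperty(reg, "pyridine", "dHf_gas",
                                 "experimental")$value + 10))
})

test_that("oxidation enthalpies at nitrogen match the printed footnote chain", {
  expect_equal(oxidationEnthalpy(reg, "pyridine", "pno", "H2O2"), -29.1,
               tolerance = 1e-12)
  expect_equal(oxidationEnthalpy(reg, "pyridine", "pno", "DMDO"), -29.0,
               tolerance = 1e-12)
  expect_equal(oxidationEnthalpy(reg, "tma", "tmao", "H2O2"), -26.8,
               tolerance = 1e-12)
  expect_equal(oxidationEnthalpy(reg, "tma", "tmao", "DMDO"), -26.7,
               tolerance = 1e-12)
  # bias corrections are opt-in, additive, and never applied silently
  expect_equal(oxidationEnthalpy(reg, "pyridine", "pno", "H2O2",
                                 biasCorrection = 13),
               -29.1 + 13, tolerance = 1e-12)
  # degenerate couple: oxidant == reduced enthalpy and oxide == substrate + O
  # at equal enthalpy gives zero
  treg <- tinyOxideRegistry(dhfX = 4, dhfXO = 4)
  species <- rbind(speciesTable(treg),
                   data.frame(id = c("oxd", "red"), name = "t",
                              formula = c("H2O2", "H2O"), charge = 0L,
                              unpaired_electrons = 0L))
  props <- rbind(propertyTable(treg),
                 data.frame(species_id = c("oxd", "red"), quantity = "dHf_gas",
                            method = "experimental", value = -10,
                            unit = "kcal/mol", uncertainty = NA_real_,
                            source = "test"))
  treg2 <- registryFromFrames(species, props)
  r <- Reaction("ox0", c(x = 1, oxd = 1), c(xo = 1, red = 1))
  expect_equal(reactionEnthalpy(r, treg2), 0)
})
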