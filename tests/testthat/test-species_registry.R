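reg <- exampleRegistry()

test_that("formula parsing counts atoms exactly and round-trips", {
  expect_identical(parseFormula("C5H5NO"), c(C = 5L, H = 5L, N = 1L, O = 1L))
  expect_identical(parseFormula("C3H9NO"), c(C = 3L, H = 9L, N = 1L, O = 1L))
  expect_identical(parseFormula("O"), c(O = 1L))
  # round trip through the canonical Hill-order serializer, all fixtures
  for (f in speciesTable(reg)$formula)
    expect_identical(formulaString(parseFormula(f)), f)
  # Hill order: C then H then alphabetical; alphabetical without C
  expect_identical(formulaString(c(O = 1L, H = 5L, C = 5L, N = 1L)), "C5H5NO")
  expect_identical(formulaString(c(O = 1L, H = 2L)), "H2O")
  expect_error(parseFormula("C5X2"), "unknown element")
  expect_error(parseFormula("c5h5"), "malformed")
  expect_error(parseFormula("C5H5S"), "universe")
})

test_that("kJ-to-kcal conversion divides by 4.184 and is exactly linear", {
  expect_equal(round(kjToKcal(80), 1), 19.1)
  expect_equal(round(kjToKcal(124.7), 1), 29.8)
  expect_identical(kjToKcal(0), 0)
  x <- c(-3.7, 12.2, 80); y <- c(5.5, -124.7, 0.001)
  expect_equal(kjToKcal(x + y), kjToKcal(x) + kjToKcal(y))
})

test_that("packaged registry loads with the printed reference values", {
  expect_equal(lookupProperty(reg, "pyridine", "dHf_gas", "experimental")$value,
               33.6)
  expect_equal(lookupProperty(reg, "tmao", "dHf_gas", "experimental")$value,
               -7.2)
  expect_equal(lookupProperty(reg, "o_atom_3p", "dHf_gas", "experimental")$value,
               59.6)
  expect_equal(lookupProperty(reg, "tmao", "dHf_gas", "experimental")$uncertainty,
               1.2)
})

test_that("lookup never falls back across methods", {
  expect_error(lookupProperty(reg, "tmao", "dHf_gas", "HF/6-31G*"),
               "tmao.*dHf_gas.*HF/6-31G\\*")
  expect_error(lookupProperty(reg, "nosuch", "dHf_gas", "experimental"),
               "no record")
})

test_that("every fixture species satisfies the electron-parity invariant", {
  # validity runs on construction; rebuilding from the frames re-checks it
  expect_s4_class(registryFromFrames(speciesTable(reg), propertyTable(reg)),
                  "ThermoRegistry")
  # and a deliberate violation is caught (NO with 0 unpaired electrons)
  bad <- data.frame(id = "no", name = "nitric oxide", formula = "NO",
                    charge = 0L, unpaired_electrons = 0L)
  expect_error(registryFromFrames(bad), "parity")
})

test_that("duplicate (species, quantity, method) keys are rejected", {
  pr <- propertyTable(reg)
  expect_error(registryFromFrames(speciesTable(reg), rbind(pr, pr[pr$species_id == "tmao" &
                 pr$quantity == "dHf_gas" & pr$method == "experimental", ])),
               "duplicate")
})

test_that("empty fixture files give an empty registry with a warning", {
  sp <- withr::local_tempfile(fileext = ".csv")
  prp <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), sp); writeLines(character(0), prp)
  expect_warning(expect_warning(r0 <- loadRegistry(sp, prp, quiet = TRUE),
                                "empty species"), "empty property")
  expect_identical(nrow(speciesTable(r0)), 0L)
})

test_that("kJ/mol inputs are converted on load and the Unicode minus accepted", {
  sp <- withr::local_tempfile(fileext = ".csv")
  prp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,name,formula,charge,unpaired_electrons",
               "pno,pyridine N-oxide,C5H5NO,0,0"), sp)
  writeLines(c("species_id,quantity,method,value,unit,uncertainty,source",
               "pno,dHf_gas,experimental,124.7,kJ/mol,1.8,test",
               "pno,dHsub,experimental,−80.6,kJ/mol,,test"), prp)
  r <- loadRegistry(sp, prp, quiet = TRUE)
  rec <- lookupProperty(r, "pno", "dHf_gas", "experimental")
  expect_equal(rec$value, 124.7 / 4.184)
  expect_identical(rec$unit, "kcal/mol")
  expect_equal(lookupProperty(r, "pno", "dHsub", "experimental")$value,
               -80.6 / 4.184)
})

test_that("registry save/load round trip is lossless in CSV and JSON", {
  for (ext in c(".csv", ".json")) {
    sp <- withr::local_tempfile(fileext = ext)
    prp <- withr::local_tempfile(fileext = ext)
    writeRegistry(reg, sp, prp)
    back <- loadRegistry(sp, prp, quiet = TRUE)
    expect_equal(speciesTable(back), speciesTable(reg))
    expect_equal(propertyTable(back), propertyTable(reg))
  }
})
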