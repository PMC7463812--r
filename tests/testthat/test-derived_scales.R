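reg <- exampleRegistry()
scale3 <- loadScaleTable(fixturePath("scale_table3.csv"))

test_that("experimental BDE and -TTRS reproduce the printed dissociation scale", {
  expect_equal(bde(reg, "tmao", "tma"), 61.1)
  expect_equal(bde(reg, "pno", "pyridine"), 63.4)
  expect_equal(negTTRS(reg, "pno", "pyridine"), 3.8)
  expect_equal(negTTRS(reg, "tmao", "tma"), 1.5)
  expect_equal(negTTRS(reg, "co2", "co"), 67.7)
  # all seven experimental pairs match the fixture scale to print rounding
  pairs <- read.csv(fixturePath("oxide_pairs.csv"), stringsAsFactors = FALSE)
  exp3 <- scale3[scale3$method == "experimental", ]
  for (i in seq_len(nrow(pairs))) {
    row <- exp3[exp3$species_id == pairs$oxide[i], ]
    expect_equal(bde(reg, pairs$oxide[i], pairs$parent[i]), row$bde,
                 tolerance = 0.051)
    expect_equal(negTTRS(reg, pairs$oxide[i], pairs$parent[i]), row$neg_ttrs,
                 tolerance = 0.051)
  }
})

test_that("BDE equals the O-atom enthalpy when oxide and parent coincide in dHf", {
  treg <- tinyOxideRegistry(dhfX = 12.5, dhfXO = 12.5, hO = 59.6)
  expect_equal(bde(treg, "xo", "x"), 59.6)
  expect_equal(negTTRS(treg, "xo", "x"), 0)
})

test_that("oxide/parent composition and charge gates reject mismatches", {
  expect_error(bde(reg, "pno", "tma"), "composition mismatch")
  expect_error(negTTRS(reg, "co2", "pyridine"), "composition mismatch")
  expect_error(bde(reg, "phenol", "phenoxide"), "mismatch")
  # missing O-atom record for a method is an explicit lookup error
  expect_error(bde(reg, "pno", "pyridine", method = "HF/6-31G*"), "no record")
})

test_that("scale audit recovers the constant per-method oxygen gap", {
  a <- auditScale(scale3)
  gaps <- setNames(a$methods$gap, a$methods$method)
  expect_equal(gaps[["experimental"]], 59.6)
  expect_equal(gaps[["B3LYP/6-31G*"]], 61.7)
  expect_equal(gaps[["M06/6-311G+(d,p)"]], 57.1)
  expect_identical(a$methods$n_outliers[a$methods$method == "experimental"], 0L)
  expect_identical(a$methods$n_outliers[a$methods$method == "B3LYP/6-31G*"], 0L)
})

test_that("exactly one anomalous row is flagged in the extended-basis column", {
  a <- auditScale(scale3)
  out <- a$outliers
  expect_identical(nrow(out), 1L)
  expect_identical(out$method, "M06/6-311G+(d,p)")
  expect_identical(out$species_id, "azabicyclo331nonanone_noxide")
  expect_equal(out$gap, 67.1)
})

test_that("gap interconversion round-trips scale columns", {
  b3 <- scale3[scale3$method == "B3LYP/6-31G*", ]
  back <- convertScale(convertScale(b3$bde, 61.7, from = "bde"), 61.7,
                       from = "neg_ttrs")
  expect_equal(back, b3$bde)
})

test_that("proton-affinity differences match the printed comparison", {
  expect_equal(deltaPA(reg, "tmao", "pno", "experimental"), 14.3)
  expect_equal(deltaPA(reg, "tmao", "pno", "B3LYP/6-31G*"), 17.8)
  expect_equal(deltaPA(reg, "tmao", "pno", "M06/6-311G+(d,p)"), 14.7,
               tolerance = 1e-12)
  expect_equal(deltaPA(reg, "pno", "pno"), 0)
  # antisymmetry
  expect_equal(deltaPA(reg, "pno", "tmao"), -deltaPA(reg, "tmao", "pno"))
})

test_that("isomer ladders are zero-based and translation invariant", {
  lad1 <- isomerLadder(reg, c("nitromethane", "methyl_nitrite"))
  expect_equal(unname(lad1), c(0, 2.0))
  lad2 <- isomerLadder(reg, c("dimethylaminomethanol", "tmao"))
  expect_equal(unname(lad2), c(0, 41.4))
  expect_equal(unname(isomerLadder(reg, "benzene")), 0)
  expect_error(isomerLadder(reg, c("benzene", "pyridine")), "not isomers")
  expect_error(isomerLadder(reg, c("phenol", "phenoxide")), "not isomers")
  # adding a constant to all dHf leaves the ladder unchanged: the anchored
  # model columns reproduce the printed relative ladders
  expect_equal(unname(isomerLadder(reg, c("nitromethane", "methyl_nitrite"),
                                   "B3LYP/6-31G*")), c(0, 0.9))
  expect_equal(unname(isomerLadder(reg, c("hydroxypyridine_2", "pyridone_2",
                                          "pno"), "M06/6-311G+(d,p)")),
               c(0.5, 0, 50.1))
  expect_equal(unname(isomerLadder(reg, c("hydroxypyridine_2", "pyridone_2",
                                          "pno"), "experimental")),
               c(0, 0.7, 48.9))
})
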