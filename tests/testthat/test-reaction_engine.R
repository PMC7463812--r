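reg <- exampleRegistry()
rx <- exampleReactions()

test_that("balance reports are exact and isogyricity is tracked", {
  # oxygen transfer between the two N-oxides: balanced and isogyric
  b1 <- checkBalance(rx$eq_oat, reg)
  expect_true(b1@isBalanced)
  expect_true(b1@isIsogyric)
  expect_true(all(b1@elementImbalance == 0))
  # dissociation to triplet O: element-balanced but NOT isogyric (0 vs 2)
  b2 <- checkBalance(rx$bde_tmao, reg)
  expect_true(b2@isBalanced)
  expect_false(b2@isIsogyric)
  expect_identical(b2@unpairedImbalance, -2)
  # the miscounted literature disproportionation: C -6 H -6 deficit
  b3 <- checkBalance(rx$re_benzene_printed, reg)
  expect_false(b3@isBalanced)
  expect_identical(b3@elementImbalance[["C"]], -6)
  expect_identical(b3@elementImbalance[["H"]], -6)
  # half-coefficients are exact: XO -> X + 1/2 O2 balances
  expect_true(checkBalance(rx$ttrs_pno, reg)@isBalanced)
  # charge imbalance is caught
  bad <- Reaction("dep", c(phenol = 1), c(phenoxide = 1))
  expect_false(checkBalance(bad, reg)@isBalanced)
  expect_error(checkBalance(Reaction("u", c(zz = 1), c(pno = 1)), reg),
               "unknown species")
})

test_that("reaction construction enforces exact positive rational coefficients", {
  expect_error(Reaction("r", c(a = 1), c(a = 1)), "both sides")
  expect_error(Reaction("r", c(a = 0.5), c(b = 1)), "p/q")
  expect_error(Reaction("r", c(a = "1/0"), c(b = 1)), "invalid rational")
  r <- Reaction("r", c(a = "2/4"), c(b = "3"))
  expect_identical(r@reactants$a, c(1L, 2L))  # reduced
})

test_that("oxygen-transfer enthalpy matches the published value per method", {
  expect_equal(reactionEnthalpy(rx$eq_oat, reg, "experimental"), -2.3)
  expect_equal(reactionEnthalpy(rx$eq_oat, reg, "B3LYP/6-31G*"), -13.5)
  expect_equal(reactionEnthalpy(rx$eq_oat, reg, "M06/6-311G+(d,p)"), -10.0)
})

test_that("degenerate and unbalanced reactions are handled explicitly", {
  # a reaction and its reverse cancel to nothing: combination refuses
  r <- Reaction("swap", c(tmao = 1, pyridine = 1), c(tma = 1, pno = 1))
  expect_error(combineReactions(r, reverseReaction(r)), "cancels")
  unb <- Reaction("unb", c(benzene = 1), c(cyclohexane = 1))
  expect_error(reactionEnthalpy(unb, reg), "not element/charge balanced")
  expect_warning(v <- reactionEnthalpy(unb, reg, strict = FALSE), "balanced")
  expect_equal(v, -29.4 - 19.8)
  expect_error(reactionEnthalpy(rx$eq_oat, reg, "HF/6-31G*"), "no record")
})

test_that("enthalpy is antisymmetric and linear over reaction combinations", {
  r1 <- rx$eq_oat; r2 <- rx$re_benzene
  h1 <- reactionEnthalpy(r1, reg); h2 <- reactionEnthalpy(r2, reg)
  expect_equal(reactionEnthalpy(reverseReaction(r1), reg), -h1)
  comb <- combineReactions(r1, r2, w1 = 3, w2 = "1/2")
  expect_equal(reactionEnthalpy(comb, reg), 3 * h1 + h2 / 2, tolerance = 1e-12)
  # combination with cancellation: r1 + reverse(2 r1) = -r1
  comb2 <- combineReactions(r1, reverseReaction(r1), w1 = 1, w2 = 2)
  expect_equal(reactionEnthalpy(comb2, reg), -h1)
})

test_that("solve-for-unknown inverts the oxygen-transfer arithmetic", {
  reg2 <- dropProperty(reg, "pno", "dHf_gas", "experimental")
  expect_equal(solveUnknown(rx$eq_oat, reg2, "experimental", -2.3, "pno"), 29.8)
  # remove-then-solve round trip recovers any stored participant exactly
  for (sid in c("tmao", "pyridine", "tma")) {
    stored <- lookupProperty(reg, sid, "dHf_gas", "experimental")$value
    regd <- dropProperty(reg, sid, "dHf_gas", "experimental")
    h <- reactionEnthalpy(rx$eq_oat, reg, "experimental")
    expect_equal(solveUnknown(rx$eq_oat, regd, "experimental", h, sid),
                 stored, tolerance = 1e-12)
  }
})

test_that("solve-for-unknown rejects zero or multiple unknowns", {
  expect_error(solveUnknown(rx$eq_oat, reg, "experimental", -2.3, "pno"),
               "no unknown")
  reg2 <- dropProperty(dropProperty(reg, "pno", "dHf_gas", "experimental"),
                       "tma", "dHf_gas", "experimental")
  expect_error(solveUnknown(rx$eq_oat, reg2, "experimental", -2.3, "pno"),
               "multiple participants")
  expect_error(solveUnknown(rx$eq_oat, reg, "experimental", -2.3, "benzene"),
               "does not participate")
})

test_that("reaction fixtures load from YAML with classes and rational coefficients", {
  expect_named(rx)
  expect_s4_class(rx$eq_oat, "Reaction")
  expect_identical(rx$eq_oat@declaredClass, "isodesmic")
  expect_identical(rx$ttrs_pno@products$o2, c(1L, 2L))
})
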