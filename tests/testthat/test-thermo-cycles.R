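test_that("cycle closure: published legs reproduce the printed ddG values", {
  expect_equal(ddg_binding(127.7, 117.2)$ddG, 10.5, tolerance = 1e-12)
  expect_equal(ddg_binding(132.9, 124.3)$ddG, 8.6, tolerance = 1e-12)
  expect_equal(ddg_binding(5, 5)$ddG, 0)
})

test_that("leg errors combine by quadrature or linearly as requested", {
  b <- free_energy_estimate(127.7, 0.1)
  u <- free_energy_estimate(117.2, 0.2)
  expect_equal(ddg_binding(b, u)$ddG_err, sqrt(0.1^2 + 0.2^2))
  expect_equal(ddg_binding(b, u, error_rule = "linear")$ddG_err, 0.3)
  hot <- free_energy_estimate(117.2, 0.2, T = 310)
  expect_error(ddg_binding(b, hot), "temperature mismatch")
})

test_that("composed cycles close exactly", {
  # ddG(WT->A) - ddG(WT->B) equals the A->B cycle built from the same legs
  a <- ddg_binding(127.7, 117.2)
  b <- ddg_binding(132.9, 124.3)
  composed <- ddg_binding(127.7 - 132.9, 117.2 - 124.3)
  expect_identical(a$ddG - b$ddG, composed$ddG)
})

test_that("ddG converts to pKa units with the definitional scale", {
  expect_equal(ddg_to_dpka(0), 0)
  one_unit <- KB_KCAL * 298.15 * log(10)
  expect_equal(ddg_to_dpka(one_unit), 1.0, tolerance = 1e-12)
  expect_equal(round(ddg_to_dpka(2.0), 1), 1.5)
  expect_equal(ddg_to_dpka(2.0), 2.0 / 1.3643, tolerance = 1e-3)
  # reversing the cycle negates the shift
  cyc <- ddg_binding(126.2, 124.2, cation = "H+")
  rev <- ddg_binding(124.2, 126.2, cation = "H+")
  expect_equal(ddg_to_dpka(cyc), -ddg_to_dpka(rev))
  expect_error(ddg_to_dpka(1, T = 0), "positive")
})

test_that("binding affinities keep Kd * Ka = 1 and reject bad input", {
  ba <- binding_affinity(5.82, "mM", "no Na+")
  expect_equal(ba$Kd * ba$Ka, 1, tolerance = 1e-12)
  expect_error(binding_affinity(0, "mM"), "positive")
  expect_error(binding_affinity(-2, "uM"), "positive")
})

test_that("cooperativity folds reproduce the published ratios and guard units", {
  fold <- cooperativity_fold(binding_affinity(9.28, "mM"),
                             binding_affinity(1.09, "mM"))
  expect_equal(round(fold, 2), 8.51)
  expect_equal(round(cooperativity_fold(binding_affinity(5.82, "mM"),
                                        binding_affinity(5.09, "mM")), 2),
               1.14)
  expect_equal(cooperativity_fold(binding_affinity(3, "mM"),
                                  binding_affinity(3, "mM")), 1.0)
  expect_error(cooperativity_fold(binding_affinity(9.28, "mM"),
                                  binding_affinity(1.09, "uM")),
               "unit mismatch")
})

test_that("the cycle report recomputes every row and flags inconsistencies", {
  rep3 <- reproduce_cycle_table()
  expect_s3_class(rep3, "cycle_report")
  by_row <- function(mut, cat) rep3[rep3$mutation == mut & rep3$cation == cat, ]
  d59 <- by_row("D59C", "Na+")
  expect_equal(d59$ddg_recomputed, 10.5, tolerance = 1e-9)
  expect_true(d59$match)
  d55h <- by_row("D55C", "H+")
  expect_equal(d55h$ddg_recomputed, 2.0, tolerance = 1e-9)
  expect_true(d55h$match)
  expect_equal(round(d55h$dpka, 1), 1.5)
  # T121A: legs give 6.61, printed 6.7 -> flagged, not "corrected"
  t121 <- by_row("T121A", "Na+")
  expect_equal(t121$ddg_recomputed, 6.61, tolerance = 1e-9)
  expect_false(t121$match)
  # D59C proton row: printed roles give -5.0 against printed +5.1 -> flagged
  d59h <- by_row("D59C", "H+")
  expect_equal(d59h$ddg_recomputed, -5.0, tolerance = 1e-9)
  expect_false(d59h$match)
  # both error rules are reported
  expect_equal(d59$err_quadrature, sqrt(0.1^2 + 0.2^2), tolerance = 1e-12)
  expect_equal(d59$err_linear, 0.3, tolerance = 1e-12)
  expect_error(reproduce_cycle_table("no/such/file.tsv"), "does not exist")
})

test_that("the fold report matches every published fold at 2 decimals", {
  rep1 <- reproduce_fold_table()
  expect_s3_class(rep1, "fold_report")
  expect_true(all(rep1$match))
  expect_setequal(round(rep1$fold_recomputed, 2),
                  c(8.51, 1.68, 1.14, 1.11, 1.37))
})
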