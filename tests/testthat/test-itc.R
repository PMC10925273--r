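# canonical truth/design pair used throughout: melibiose-like low-c
# titration at the published Kd of 5.82 mM
melib_params <- function(dH = -2) one_site_params(Ka = 1 / 5.82e-3, dH = dH)
melib_design <- function(n_inj = 25) {
  itc_design(cell_uM = 80, syringe = 100, syringe_unit = "mM", n_inj = n_inj)
}

test_that("zero enthalpy yields an identically zero thermogram", {
  tg <- simulate_thermogram(one_site_params(1e5, dH = 0), melib_design())
  expect_identical(unique(tg$q), 0)
})

test_that("stoichiometric titration limit: early heats equal dH per mole injected", {
  # Ka so large that every injected mole binds until saturation
  d <- itc_design(cell_uM = 10, syringe = 500, syringe_unit = "uM",
                  n_inj = 20)
  p <- one_site_params(Ka = 1e12, dH = -5, n = 1)
  heats <- itc_expected_heats(p, d)
  mol_inj1 <- d$X0_M * d$inj_ul[1] * 1e-6
  expect_equal(heats$q[1], p$dH * mol_inj1 * 4.184e9, tolerance = 0.01)
  # and the heat vanishes once the cell titrand is saturated
  expect_lt(abs(heats$q[20]), abs(heats$q[1]) * 1e-3)
})

test_that("cumulative heat equals dH times bound moles (heat conservation)", {
  p <- melib_params()
  d <- melib_design()
  heats <- itc_expected_heats(p, d)
  V0_L <- d$V0_ul * 1e-6
  expect_equal(heats$Q, p$dH * V0_L * heats$bound * 4.184e9,
               tolerance = 1e-9)
  expect_true(all(diff(heats$bound) > 0)) # binding only accumulates
  # uncorrected increments sum to the final cumulative heat
  expect_equal(sum(diff(c(0, heats$Q))), heats$Q[d$n_inj], tolerance = 1e-9)
})

test_that("noiseless simulate->fit round trip recovers all parameters", {
  for (case in list(list(p = melib_params(), d = melib_design()),
                    list(p = one_site_params(Ka = 1 / 15.06e-6, dH = -8,
                                             n = 0.9),
                         d = itc_design(cell_uM = 50, syringe = 500,
                                        syringe_unit = "uM")))) {
    tg <- simulate_thermogram(case$p, case$d, noise_sd = 0)
    fit <- fit_one_site(tg)
    expect_true(fit$detectable)
    expect_equal(fit$params$Ka, case$p$Ka, tolerance = 5e-4)
    expect_equal(fit$params$dH, case$p$dH, tolerance = 5e-4)
    expect_equal(fit$params$n, case$p$n, tolerance = 5e-4)
  }
})

test_that("dilution-heat subtraction restores a baseline-offset thermogram", {
  # strong binder saturates early, so the last injections carry only the
  # background heat
  p <- one_site_params(Ka = 1e6, dH = -6, n = 1)
  d <- itc_design(cell_uM = 50, syringe = 1000, syringe_unit = "uM",
                  n_inj = 25)
  clean <- simulate_thermogram(p, d, noise_sd = 0)
  shifted <- clean
  shifted$q <- shifted$q + 1.5
  fixed <- subtract_dilution(shifted, m_last = 3)
  expect_true(fixed$dilution_corrected)
  # the saturated tail still evolves a small residual binding heat (<0.5%
  # of the peak), so recovery is exact only to that scale
  expect_lt(max(abs(fixed$q - clean$q)), 0.005 * max(abs(clean$q)))
  fit <- fit_one_site(fixed)
  expect_lt(abs(fit$Kd_M - p$Kd_M) / p$Kd_M, 0.05)
  # degenerate cases
  zero <- simulate_thermogram(one_site_params(1e5, 0), d)
  expect_identical(subtract_dilution(zero, 3)$q, zero$q)
  expect_error(subtract_dilution(clean, 0), "m_last")
  expect_error(subtract_dilution(clean, 25), "m_last")
})

test_that("flat thermograms report no detectable binding instead of a fit", {
  d <- melib_design()
  zero <- simulate_thermogram(one_site_params(1e5, 0), d)
  fit <- fit_one_site(zero)
  expect_false(fit$detectable)
  expect_true(is.na(fit$Kd_M))
  expect_error(kd_as(fit, "mM"), "no detectable binding")
  # pure noise, no signal: the non-binding outcome of a Na+ titration into
  # a binding-dead mutant
  noise_only <- simulate_thermogram(one_site_params(1e5, 0), d,
                                    noise_sd = 0.5, seed = 3)
  expect_false(fit_one_site(noise_only)$detectable)
})

test_that("fitted Ka is invariant under joint dH/noise rescaling", {
  d <- melib_design()
  f1 <- fit_one_site(simulate_thermogram(melib_params(dH = -2), d),
                     fix_n = TRUE)
  f2 <- fit_one_site(simulate_thermogram(melib_params(dH = -20), d),
                     fix_n = TRUE)
  expect_equal(f1$params$Ka, f2$params$Ka, tolerance = 1e-6)
})

test_that("noisy low-c titrations still locate Kd (seeded replicates)", {
  p <- melib_params()
  d <- melib_design()
  scale_q <- max(abs(simulate_thermogram(p, d)$q))
  errs <- vapply(1:20, function(s) {
    tg <- simulate_thermogram(p, d, noise_sd = 0.02 * scale_q, seed = s)
    fit <- fit_one_site(tg, fix_n = TRUE)
    abs(fit$Kd_M - p$Kd_M) / p$Kd_M
  }, numeric(1))
  expect_lt(median(errs), 0.15)
})

test_that("fitted affinities feed the cooperativity pipeline exactly", {
  d <- melib_design()
  fit_wo <- fit_one_site(simulate_thermogram(
    one_site_params(1 / 9.28e-3, -2), d), fix_n = TRUE)
  fit_wi <- fit_one_site(simulate_thermogram(
    one_site_params(1 / 1.09e-3, -2), d), fix_n = TRUE)
  fold <- cooperativity_fold(kd_as(fit_wo, "mM"), kd_as(fit_wi, "mM"))
  expect_identical(fold, kd_as(fit_wo, "mM")$Kd / kd_as(fit_wi, "mM")$Kd)
  expect_equal(fold, 9.28 / 1.09, tolerance = 0.01)
})

test_that("design construction enforces volumes and warns on overfill", {
  expect_error(itc_design(0, 100), "positive")
  expect_error(itc_design(80, -1), "positive")
  expect_warning(itc_design(80, 100, V0_ul = 40, inj_ul = 2, n_inj = 25),
                 "exceeds cell volume")
  expect_error(fit_one_site(simulate_thermogram(melib_params(),
                                                melib_design(n_inj = 4))),
               "at least 5")
})
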