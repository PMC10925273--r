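test_that("exponential averaging handles degenerate and extreme inputs", {
  expect_equal(zwanzig(rep(0, 10), T_TOY), 0)
  expect_equal(zwanzig(3.7, T_TOY), 3.7) # single sample is itself
  # |beta dU| ~ 670: a naive exp() would overflow/underflow
  big <- 400
  expect_equal(zwanzig(rep(big, 5), T_TOY), big)
  expect_equal(zwanzig(rep(-big, 5), T_TOY), -big)
  expect_error(zwanzig(numeric(0), T_TOY), "at least one")
})

test_that("Zwanzig recovers the Gaussian closed form within Monte Carlo error", {
  set.seed(42)
  mu <- 1.0; s2 <- 0.5
  dU <- rnorm(2e4, mu, sqrt(s2))
  truth <- mu - s2 / (2 * KT_TOY)
  est <- zwanzig(dU, T_TOY)
  se <- bootstrap_stderr(function(s) zwanzig(s, T_TOY), dU, B = 200, seed = 1)
  expect_lt(abs(est - truth), 3 * se)
})

test_that("SOS window estimator is exact for constant perturbations", {
  expect_equal(sos_window(rep(0, 8), rep(0, 8), T_TOY, n_bootstrap = 0)$dG, 0)
  c0 <- 2.31
  res <- sos_window(rep(c0, 9), rep(-c0, 7), T_TOY, n_bootstrap = 50)
  expect_equal(res$dG, c0, tolerance = 1e-12)
  expect_equal(res$stderr, 0) # constant samples resample to themselves
  expect_error(sos_window(numeric(0), 1, T_TOY), "non-empty")
  expect_error(sos_window(c(1, Inf), c(0), T_TOY, window_label = "[0,0.05]"),
               "0,0.05")
})

test_that("BAR solves its self-consistency equation on degenerate input", {
  expect_equal(bar_window(rep(0, 5), rep(0, 5), T_TOY, n_bootstrap = 0)$dG,
               0, tolerance = 1e-7)
  expect_equal(bar_window(1.5, -1.5, T_TOY, n_bootstrap = 0)$dG, 1.5,
               tolerance = 1e-7)
  expect_error(bar_window(numeric(0), 1, T_TOY), "non-empty")
})

test_that("SOS and BAR agree on a well-overlapping Gaussian window pair", {
  g <- toy_gaussian_work(0.8, 0.4, T = T_TOY)
  fwd <- sample_fep_run(g, make_lambda_schedule(1), 5000, seed = 31)
  bwd <- sample_fep_run(g, make_lambda_schedule(1, "backward"), 5000,
                        seed = 32)
  f <- fwd$windows[[1]]$samples_dU
  b <- bwd$windows[[1]]$samples_dU
  s <- sos_window(f, b, T_TOY, n_bootstrap = 100, seed = 1)
  r <- bar_window(f, b, T_TOY, n_bootstrap = 100, seed = 2)
  expect_lt(abs(s$dG - r$dG), 3 * sqrt(s$stderr^2 + r$stderr^2))
  truth <- analytic_free_energy(g)
  expect_lt(abs(s$dG - truth), 3 * s$stderr)
})

test_that("window estimates are antisymmetric and translation covariant", {
  set.seed(11)
  f <- rnorm(300, 0.5, 0.4)
  b <- rnorm(280, -0.3, 0.4)
  for (fn in list(function(x, y) sos_window(x, y, T_TOY, n_bootstrap = 0)$dG,
                  function(x, y) bar_window(x, y, T_TOY, n_bootstrap = 0)$dG)) {
    # swapping forward/backward roles negates the estimate exactly
    expect_equal(fn(f, b), -fn(b, f), tolerance = 1e-7)
    # shifting dU by +c and dU' by -c shifts dG by exactly c
    c0 <- 1.234
    expect_equal(fn(f + c0, b - c0), fn(f, b) + c0, tolerance = 1e-7)
  }
})

test_that("bootstrap errors are deterministic and shrink as 1/sqrt(n)", {
  set.seed(8)
  x <- rnorm(4000, 1, sqrt(0.5))
  stat <- function(s) zwanzig(s, T_TOY)
  se1 <- bootstrap_stderr(stat, x[1:500], B = 200, seed = 5)
  se1b <- bootstrap_stderr(stat, x[1:500], B = 200, seed = 5)
  expect_identical(se1, se1b)
  se4 <- bootstrap_stderr(stat, x[1:2000], B = 200, seed = 5)
  expect_gt(se1 / se4, 1.6)
  expect_lt(se1 / se4, 2.4)
  expect_error(bootstrap_stderr(stat, x, B = 1), "at least 2")
})

test_that("block bootstrap widens the error for serially correlated draws", {
  # AR(1) chain with strong autocorrelation: iid resampling understates the
  # error of the mean; 50-block resampling must not
  set.seed(13)
  n <- 4000
  rho <- 0.9
  e <- rnorm(n)
  x <- as.numeric(stats::filter(e, rho, method = "recursive"))
  se_iid <- bootstrap_stderr(mean, x, B = 200, seed = 2, block_length = 1)
  se_blk <- bootstrap_stderr(mean, x, B = 200, seed = 2, block_length = 50)
  truth <- sd(e) / ((1 - rho) * sqrt(n)) # asymptotic SE of the AR(1) mean
  expect_gt(se_blk, 3 * se_iid)
  expect_gt(se_blk / truth, 0.6)
  expect_lt(se_blk / truth, 1.2)
})

test_that("overlap diagnostic spans its [0, 1] range", {
  set.seed(3)
  x <- rnorm(5000)
  expect_equal(overlap_diagnostic(x, -x), 1.0, tolerance = 0.02)
  expect_equal(overlap_diagnostic(rep(0.1, 50), rep(9.9, 50)), 0)
  # neighbouring harmonic windows at 0.05 spacing overlap well
  pair <- run_pair(harmonic_14(), n_windows = 20, n = 2000, seed = 17)
  f <- pair$fwd$windows[[1]]$samples_dU
  b <- pair$bwd$windows[[20]]$samples_dU
  expect_gt(overlap_diagnostic(f, b), 0.5)
})

test_that("accumulation pairs windows by lambda interval and sums them", {
  pair <- run_pair(harmonic_14(), n_windows = 10, n = 1500, seed = 23)
  est <- accumulate_fep(pair$fwd, pair$bwd, n_bootstrap = 50, seed = 1)
  expect_s3_class(est, "free_energy_estimate")
  expect_equal(est$value, sum(est$per_window$dG), tolerance = 1e-9)
  expect_equal(est$stderr, sqrt(sum(est$per_window$stderr^2)),
               tolerance = 1e-12)
  truth <- analytic_free_energy(harmonic_14())
  expect_lt(abs(est$value - truth), 3 * est$stderr)
})

test_that("a null mutation accumulates to zero and reversal negates the total", {
  null_sys <- toy_harmonic(2, 2, T = T_TOY)
  pair <- run_pair(null_sys, n_windows = 4, n = 300, seed = 5)
  est <- accumulate_fep(pair$fwd, pair$bwd, n_bootstrap = 10)
  expect_equal(est$value, 0, tolerance = 1e-12)
  # mirror the pair (lambda -> 1 - lambda): total must negate exactly
  pair2 <- run_pair(harmonic_14(), n_windows = 6, n = 400, seed = 7)
  est_ab <- accumulate_fep(pair2$fwd, pair2$bwd, n_bootstrap = 10, seed = 2)
  est_ba <- accumulate_fep(reverse_run(pair2$bwd), reverse_run(pair2$fwd),
                           n_bootstrap = 10, seed = 2)
  expect_equal(est_ba$value, -est_ab$value, tolerance = 1e-9)
})

test_that("mismatched run pairs fail loudly", {
  pair <- run_pair(harmonic_14(), n_windows = 5, n = 100, seed = 2)
  short <- sample_fep_run(harmonic_14(), make_lambda_schedule(4, "backward"),
                          100, seed = 3)
  expect_error(accumulate_fep(pair$fwd, short, n_bootstrap = 5),
               "different lambda schedules")
  hot <- sample_fep_run(toy_harmonic(1, 4, T = 500),
                        make_lambda_schedule(5, "backward"), 100, seed = 4)
  expect_error(accumulate_fep(pair$fwd, hot, n_bootstrap = 5),
               "temperature mismatch")
  expect_error(accumulate_fep(pair$bwd, pair$fwd, n_bootstrap = 5),
               "forward")
})

test_that("SOS, BAR and averaged Zwanzig agree on the harmonic toy", {
  pair <- run_pair(harmonic_14(), n_windows = 10, n = 2000, seed = 29)
  sos <- accumulate_fep(pair$fwd, pair$bwd, "sos", n_bootstrap = 50, seed = 1)
  bar <- accumulate_fep(pair$fwd, pair$bwd, "bar", n_bootstrap = 50, seed = 1)
  zf <- accumulate_fep(pair$fwd, pair$bwd, "zwanzig_fwd", n_bootstrap = 50,
                       seed = 1)
  zb <- accumulate_fep(pair$fwd, pair$bwd, "zwanzig_bwd", n_bootstrap = 50,
                       seed = 1)
  z_mean <- (zf$value + zb$value) / 2
  z_se <- sqrt(zf$stderr^2 + zb$stderr^2) / 2
  expect_lt(abs(sos$value - bar$value),
            3 * sqrt(sos$stderr^2 + bar$stderr^2))
  expect_lt(abs(sos$value - z_mean), 3 * sqrt(sos$stderr^2 + z_se^2))
})
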