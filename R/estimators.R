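#' Exponential-averaging (Zwanzig) free-energy estimate
#'
#' One-directional perturbation estimate
#' Delta G = -k_B T ln < exp(-beta dU) > over the supplied samples,
#' evaluated through a log-sum-exp formulation so no intermediate
#' overflows occur for |beta dU| up to several hundred.
#'
#' @param samples_dU Energy-difference samples, kcal/mol.
#' @param T Temperature, Kelvin.
#' @return Delta G in kcal/mol.
#' @export
#' @examples
#' zwanzig(c(0, 0, 0), T = 300) # 0
zwanzig <- function(samples_dU, T) {
  assert_samples(samples_dU, "samples_dU")
  kT <- kbt(T)
  -kT * log_mean_exp(-samples_dU / kT)
}

#' Simple-overlap-sampling (SOS) window estimate
#'
#' Two-sided per-window estimator combining half-exponent averages from
#' samples at both window ends:
#' Delta G = -k_B T \[ ln < exp(-beta dU / 2) >_i -
#'                     ln < exp(-beta dU' / 2) >_{i+1} \],
#' where `samples_fwd` holds dU = H_{i+1} - H_i drawn at state i and
#' `samples_bwd` holds dU' = H_i - H_{i+1} drawn at state i+1.  More
#' robust than one-directional exponential averaging when the two window
#' distributions overlap imperfectly.
#'
#' @param samples_fwd Forward energy differences (drawn at the lower end
#'   state), kcal/mol.
#' @param samples_bwd Reverse energy differences (drawn at the upper end
#'   state), kcal/mol.
#' @param T Temperature, Kelvin.
#' @param n_bootstrap Bootstrap resamples for the standard error (>= 2);
#'   set to `0` to skip error estimation.
#' @param seed Seed for the bootstrap.
#' @param block_length Moving-block length for the bootstrap (see
#'   [bootstrap_stderr()]); use the chain correlation scale for
#'   Markov-chain samples.
#' @param window_label Optional label used in error messages.
#' @return List with `dG` and `stderr`, kcal/mol.
#' @seealso [bar_window()], [accumulate_fep()]
#' @export
sos_window <- function(samples_fwd, samples_bwd, T, n_bootstrap = 200L,
                       seed = 1L, block_length = 1L, window_label = NULL) {
  lab <- if (is.null(window_label)) "" else paste0(" in window ", window_label)
  if (!is.numeric(samples_fwd) || !length(samples_fwd) ||
      !is.numeric(samples_bwd) || !length(samples_bwd)) {
    stop("both forward and backward sample lists must be non-empty", lab,
         call. = FALSE)
  }
  if (!all(is.finite(samples_fwd)) || !all(is.finite(samples_bwd))) {
    stop("non-finite energy-difference samples", lab, call. = FALSE)
  }
  kT <- kbt(T)
  est <- function(f, b) {
    -kT * (log_mean_exp(-f / (2 * kT)) - log_mean_exp(-b / (2 * kT)))
  }
  dG <- est(samples_fwd, samples_bwd)
  if (!is.finite(dG)) {
    warning("SOS estimate is non-finite", lab,
            "; reporting stderr = NaN")
    return(list(dG = dG, stderr = NaN))
  }
  se <- if (n_bootstrap >= 2L) {
    bootstrap_stderr(est, samples_fwd, samples_bwd, B = n_bootstrap,
                     seed = seed, block_length = block_length)
  } else {
    NA_real_
  }
  list(dG = dG, stderr = se)
}

#' Bennett acceptance-ratio (BAR) window estimate
#'
#' The minimum-variance two-state estimator, defined as the root of
#' Bennett's self-consistency equation
#' sum_F logistic(-(beta (W_i - dG) + ln(nF/nR))) =
#' sum_R logistic(-(beta (W'_j + dG) + ln(nR/nF))).
#' The root is bracketed by the two directional Zwanzig estimates plus and
#' minus 50 k_B T and solved to `tol`.  Used as an independent oracle for
#' the SOS estimator.
#'
#' @inheritParams sos_window
#' @param tol Root tolerance in kcal/mol.
#' @return List with `dG` and `stderr`, kcal/mol.
#' @export
bar_window <- function(samples_fwd, samples_bwd, T, tol = 1e-8,
                       n_bootstrap = 200L, seed = 1L, block_length = 1L,
                       window_label = NULL) {
  lab <- if (is.null(window_label)) "" else paste0(" in window ", window_label)
  if (!is.numeric(samples_fwd) || !length(samples_fwd) ||
      !is.numeric(samples_bwd) || !length(samples_bwd)) {
    stop("both forward and backward sample lists must be non-empty", lab,
         call. = FALSE)
  }
  if (!all(is.finite(samples_fwd)) || !all(is.finite(samples_bwd))) {
    stop("non-finite energy-difference samples", lab, call. = FALSE)
  }
  kT <- kbt(T)
  beta <- 1 / kT
  solve_bar <- function(f, b) {
    lr <- log(length(f) / length(b))
    g <- function(dG) {
      sum(stats::plogis(-(beta * (f - dG) + lr))) -
        sum(stats::plogis(-(beta * (b + dG) - lr)))
    }
    z_f <- zwanzig(f, T)
    z_b <- -zwanzig(b, T)
    lo <- min(z_f, z_b) - 50 * kT
    hi <- max(z_f, z_b) + 50 * kT
    if (g(lo) * g(hi) > 0) {
      stop(sprintf(
        "BAR self-consistency equation has no sign change in [%.4g, %.4g]%s",
        lo, hi, lab), call. = FALSE)
    }
    stats::uniroot(g, lower = lo, upper = hi, tol = tol)$root
  }
  dG <- solve_bar(samples_fwd, samples_bwd)
  se <- if (n_bootstrap >= 2L) {
    bootstrap_stderr(solve_bar, samples_fwd, samples_bwd, B = n_bootstrap,
                     seed = seed, block_length = block_length)
  } else {
    NA_real_
  }
  list(dG = dG, stderr = se)
}

#' Nonparametric bootstrap standard error of a window estimator
#'
#' Standard deviation of `statistic` over `B` resamples (with replacement)
#' of one or two sample vectors.  With `block_length > 1` a moving-block
#' bootstrap is used: whole contiguous blocks are resampled, so serial
#' correlation within a Markov-chain window (which an ordinary bootstrap
#' would ignore, understating the error) is carried into the resamples.
#' For independent samples the block structure is harmless.  Deterministic
#' for a fixed seed.
#'
#' @param statistic Function of one sample vector, or of two when
#'   `samples_bwd` is supplied.
#' @param samples_fwd Primary sample vector.
#' @param samples_bwd Optional second sample vector, resampled
#'   independently.
#' @param B Number of resamples (>= 2).
#' @param seed Integer seed.
#' @param block_length Moving-block length; 1 (default) is the ordinary
#'   iid bootstrap.
#' @return Bootstrap standard error (same units as the statistic).
#' @export
#' @examples
#' bootstrap_stderr(mean, rnorm(100), B = 50, seed = 1)
bootstrap_stderr <- function(statistic, samples_fwd, samples_bwd = NULL,
                             B = 200L, seed = 1L, block_length = 1L) {
  if (B < 2) stop("'B' must be at least 2", call. = FALSE)
  if (block_length < 1) stop("'block_length' must be >= 1", call. = FALSE)
  assert_samples(samples_fwd, "samples_fwd")
  set.seed(seed)
  resample_idx <- function(n) {
    l <- min(block_length, n)
    if (l == 1L) return(sample.int(n, n, replace = TRUE))
    n_blocks <- ceiling(n / l)
    starts <- sample.int(n - l + 1L, n_blocks, replace = TRUE)
    idx <- rep(starts, each = l) + rep.int(seq_len(l) - 1L, n_blocks)
    idx[seq_len(n)]
  }
  nf <- length(samples_fwd)
  vals <- numeric(B)
  if (is.null(samples_bwd)) {
    for (b in seq_len(B)) {
      vals[b] <- statistic(samples_fwd[resample_idx(nf)])
    }
  } else {
    assert_samples(samples_bwd, "samples_bwd")
    nb <- length(samples_bwd)
    for (b in seq_len(B)) {
      vals[b] <- statistic(samples_fwd[resample_idx(nf)],
                           samples_bwd[resample_idx(nb)])
    }
  }
  stats::sd(vals)
}

#' Phase-space overlap diagnostic for a window pair
#'
#' Histogram intersection of the forward dU distribution and the negated
#' backward dU' distribution on a shared grid; 1 means the two window end
#' states see the same energy-difference distribution (perfect overlap),
#' 0 means disjoint supports, the failure mode under which two-sided
#' window estimators become unreliable.
#'
#' @inheritParams sos_window
#' @param n_bins Number of shared histogram bins.
#' @return Overlap score in \[0, 1\].
#' @export
overlap_diagnostic <- function(samples_fwd, samples_bwd, n_bins = 50L) {
  assert_samples(samples_fwd, "samples_fwd")
  assert_samples(samples_bwd, "samples_bwd")
  neg_b <- -samples_bwd
  rng <- range(c(samples_fwd, neg_b))
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin_freq <- function(x) {
    idx <- findInterval(x, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    tabulate(idx, nbins = n_bins) / length(x)
  }
  sum(pmin(bin_freq(samples_fwd), bin_freq(neg_b)))
}

#' Accumulate window estimates over a forward/backward run pair
#'
#' Pairs every forward window (lambda_i -> lambda_{i+1}) with the backward
#' window covering the same lambda interval in the opposite direction
#' (matched by interval identity, not list position), applies the chosen
#' two-sided estimator per window, and sums the contributions.  The total
#' standard error combines per-window bootstrap errors in quadrature.
#'
#' @param run_fwd,run_bwd Forward and backward [fep_run()] objects over
#'   the same lambda schedule at the same temperature.
#' @param method `"sos"` (default), `"bar"`, `"zwanzig_fwd"`, or
#'   `"zwanzig_bwd"`.
#' @param n_bootstrap Bootstrap resamples per window.
#' @param seed Root seed for the bootstrap (per-window seeds derived by
#'   the sampler's splitting rule).
#' @param block_length Moving-block length for the per-window bootstrap.
#'   The default (50) covers the serial correlation of the package's
#'   random-walk Metropolis chains with margin; it is harmless for
#'   independent samples.
#' @return A `free_energy_estimate`: list with `value`, `stderr`,
#'   `method`, `per_window` (data frame), `T`, `n_bootstrap`.
#' @export
#' @examples
#' sys <- toy_harmonic(1, 4, T = 0.596 / KB_KCAL)
#' f <- sample_fep_run(sys, make_lambda_schedule(5), 400, seed = 1)
#' b <- sample_fep_run(sys, make_lambda_schedule(5, "backward"), 400, seed = 2)
#' accumulate_fep(f, b, n_bootstrap = 20)
accumulate_fep <- function(run_fwd, run_bwd,
                           method = c("sos", "bar", "zwanzig_fwd",
                                      "zwanzig_bwd"),
                           n_bootstrap = 200L, seed = 1L,
                           block_length = 50L) {
  method <- match.arg(method)
  stopifnot(inherits(run_fwd, "fep_run"), inherits(run_bwd, "fep_run"))
  if (run_fwd$direction != "forward" || run_bwd$direction != "backward") {
    stop("'run_fwd' must be a forward run and 'run_bwd' a backward run",
         call. = FALSE)
  }
  if (abs(run_fwd$T - run_bwd$T) > 1e-9) {
    stop(sprintf("temperature mismatch between runs: %g K vs %g K",
                 run_fwd$T, run_bwd$T), call. = FALSE)
  }
  gf <- run_grid(run_fwd)
  gb <- run_grid(run_bwd)
  if (length(gf) != length(gb) || any(abs(gf - rev(gb)) > 1e-9)) {
    stop("runs cover different lambda schedules: forward {",
         paste(format(gf), collapse = ", "), "} vs backward {",
         paste(format(gb), collapse = ", "), "}", call. = FALSE)
  }
  # index backward windows by their lambda interval
  b_from <- vapply(run_bwd$windows, `[[`, numeric(1), "lambda_from")
  b_to <- vapply(run_bwd$windows, `[[`, numeric(1), "lambda_to")
  nw <- length(run_fwd$windows)
  per <- data.frame(lambda_from = numeric(nw), lambda_to = numeric(nw),
                    dG = numeric(nw), stderr = numeric(nw),
                    overlap = numeric(nw))
  for (j in seq_len(nw)) {
    wf <- run_fwd$windows[[j]]
    hit <- which(abs(b_from - wf$lambda_to) < 1e-9 &
                   abs(b_to - wf$lambda_from) < 1e-9)
    if (length(hit) != 1L) {
      stop(sprintf(
        "no unique backward window for interval [%.4f, %.4f] (found %d)",
        wf$lambda_from, wf$lambda_to, length(hit)), call. = FALSE)
    }
    wb <- run_bwd$windows[[hit]]
    lab <- sprintf("[%.3f,%.3f]", wf$lambda_from, wf$lambda_to)
    sw <- child_seed(seed, j, 3L)
    res <- switch(method,
      sos = sos_window(wf$samples_dU, wb$samples_dU, run_fwd$T,
                       n_bootstrap = n_bootstrap, seed = sw,
                       block_length = block_length, window_label = lab),
      bar = bar_window(wf$samples_dU, wb$samples_dU, run_fwd$T,
                       n_bootstrap = n_bootstrap, seed = sw,
                       block_length = block_length, window_label = lab),
      zwanzig_fwd = list(
        dG = zwanzig(wf$samples_dU, run_fwd$T),
        stderr = bootstrap_stderr(function(s) zwanzig(s, run_fwd$T),
                                  wf$samples_dU, B = max(n_bootstrap, 2L),
                                  seed = sw, block_length = block_length)),
      zwanzig_bwd = list(
        dG = -zwanzig(wb$samples_dU, run_fwd$T),
        stderr = bootstrap_stderr(function(s) zwanzig(s, run_fwd$T),
                                  wb$samples_dU, B = max(n_bootstrap, 2L),
                                  seed = sw, block_length = block_length))
    )
    per$lambda_from[j] <- wf$lambda_from
    per$lambda_to[j] <- wf$lambda_to
    per$dG[j] <- res$dG
    per$stderr[j] <- res$stderr
    per$overlap[j] <- overlap_diagnostic(wf$samples_dU, wb$samples_dU)
  }
  structure(
    list(value = sum(per$dG), stderr = sqrt(sum(per$stderr^2)),
         method = method, per_window = per, T = run_fwd$T,
         n_bootstrap = as.integer(n_bootstrap)),
    class = "free_energy_estimate"
  )
}

#' @export
print.free_energy_estimate <- function(x, ...) {
  cat(sprintf("<free_energy_estimate> %s: %.4f +/- %.4f kcal/mol (%d windows, T = %g K)\n",
              x$method, x$value, x$stderr, nrow(x$per_window), x$T))
  invisible(x)
}

#' Construct a free-energy estimate from a value and error
#'
#' Wraps an externally obtained Delta G (for example a published
#' simulation leg) in the container used by the thermodynamic-cycle
#' algebra.
#'
#' @param value Delta G, kcal/mol.
#' @param stderr Standard error, kcal/mol (non-negative).
#' @param method Method tag.
#' @param T Temperature, Kelvin.
#' @return A `free_energy_estimate`.
#' @export
free_energy_estimate <- function(value, stderr = NA_real_,
                                 method = "external", T = T_ITC_DEFAULT) {
  assert_scalar_number(value, "value")
  if (!is.na(stderr)) {
    assert_scalar_number(stderr, "stderr")
    if (stderr < 0) stop("'stderr' must be non-negative", call. = FALSE)
  }
  structure(
    list(value = value, stderr = stderr, method = method,
         per_window = data.frame(lambda_from = 0, lambda_to = 1,
                                 dG = value, stderr = stderr,
                                 overlap = NA_real_),
         T = T, n_bootstrap = 0L),
    class = "free_energy_estimate"
  )
}
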