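#' One-site binding parameters for ITC
#'
#' Parameters of the single class of independent binding sites fitted to
#' an ITC titration: association constant Ka (1/M), molar enthalpy dH
#' (kcal per mol of injectant, negative for exothermic binding), and
#' stoichiometry n (sites per titrand molecule).
#'
#' @param Ka Association constant, 1/M (> 0).
#' @param dH Binding enthalpy, kcal/mol.
#' @param n Stoichiometry (> 0).
#' @return A `one_site_params` object; `Kd_M = 1/Ka` is stored alongside.
#' @export
#' @examples
#' one_site_params(Ka = 1 / 5.82e-3, dH = -2) # Kd = 5.82 mM
one_site_params <- function(Ka, dH, n = 1) {
  assert_scalar_number(Ka, "Ka", positive = TRUE)
  assert_scalar_number(dH, "dH")
  assert_scalar_number(n, "n", positive = TRUE)
  structure(list(Ka = Ka, dH = dH, n = n, Kd_M = 1 / Ka),
            class = "one_site_params")
}

#' @export
print.one_site_params <- function(x, ...) {
  cat(sprintf("<one_site_params> Ka = %.4g /M (Kd = %.4g M), dH = %.4g kcal/mol, n = %.4g\n",
              x$Ka, x$Kd_M, x$dH, x$n))
  invisible(x)
}

#' ITC titration design
#'
#' Cell and syringe composition plus the injection schedule of an
#' isothermal titration calorimetry experiment.  Concentrations are
#' stored internally in molar; the syringe concentration may be given in
#' mM or uM.
#'
#' @param cell_uM Initial cell (titrand) concentration, micromolar.
#' @param syringe Syringe (titrant) concentration, in `syringe_unit`.
#' @param syringe_unit `"mM"` or `"uM"`.
#' @param V0_ul Cell volume, microliters (Nano-ITC standard cell ~300 uL).
#' @param inj_ul Volume per injection, microliters (instrument default
#'   2 uL); recycled to `n_inj` values.
#' @param n_inj Number of injections.
#' @param T Temperature, Kelvin.
#' @return An `itc_design` object.
#' @export
#' @examples
#' itc_design(cell_uM = 80, syringe = 100, syringe_unit = "mM")
itc_design <- function(cell_uM, syringe, syringe_unit = c("mM", "uM"),
                       V0_ul = 300, inj_ul = 2, n_inj = 25,
                       T = T_ITC_DEFAULT) {
  syringe_unit <- match.arg(syringe_unit)
  assert_scalar_number(cell_uM, "cell_uM", positive = TRUE)
  assert_scalar_number(syringe, "syringe", positive = TRUE)
  assert_scalar_number(V0_ul, "V0_ul", positive = TRUE)
  if (any(!is.finite(inj_ul)) || any(inj_ul <= 0)) {
    stop("injection volumes must be positive", call. = FALSE)
  }
  if (n_inj < 1) stop("'n_inj' must be >= 1", call. = FALSE)
  assert_scalar_number(T, "T", positive = TRUE)
  v <- rep_len(as.numeric(inj_ul), n_inj)
  if (sum(v) > V0_ul) {
    warning(sprintf("total injected volume %.1f uL exceeds cell volume %.1f uL",
                    sum(v), V0_ul))
  }
  X0_M <- syringe * switch(syringe_unit, mM = 1e-3, uM = 1e-6)
  structure(
    list(M0_M = cell_uM * 1e-6, X0_M = X0_M, V0_ul = V0_ul,
         inj_ul = v, n_inj = as.integer(n_inj), T = T,
         syringe_unit = syringe_unit),
    class = "itc_design"
  )
}

#' @export
print.itc_design <- function(x, ...) {
  cat(sprintf("<itc_design> cell %.4g uM x %.4g uL; syringe %.4g M; %d x %.3g uL injections @ %g K\n",
              x$M0_M * 1e6, x$V0_ul, x$X0_M, x$n_inj, x$inj_ul[1], x$T))
  invisible(x)
}

#' Expected heats of a one-site titration
#'
#' Closed-form single-site (Wiseman) isotherm with displaced-volume
#' dilution bookkeeping.  After injection j the total cell concentrations
#' follow the perfusion recursion M_j = M_{j-1} (1 - v_j/V0) and
#' X_j = X_{j-1} (1 - v_j/V0) + X0 v_j/V0 (geometric dilution for constant
#' v).  The bound complex is the physical root of the binding quadratic
#' \deqn{[MX] = (nM + X + 1/Ka - sqrt((nM + X + 1/Ka)^2 - 4 n M X)) / 2,}
#' cumulative heat Q_j = dH V0 \[MX\]_j, and the per-injection heat carries
#' the displaced-volume correction
#' q_j = Q_j - Q_{j-1} + (v_j/V0)(Q_j + Q_{j-1})/2.
#'
#' @param params [one_site_params()].
#' @param design [itc_design()].
#' @return Data frame with per-injection `M_t`, `X_t` (molar), `ratio`
#'   (molar ratio titrant/titrand), `bound` (molar complex), `Q`
#'   (cumulative heat, uJ, signed: negative for exothermic), and `q`
#'   (per-injection heat, uJ, signed).
#' @export
itc_expected_heats <- function(params, design) {
  stopifnot(inherits(params, "one_site_params"),
            inherits(design, "itc_design"))
  nj <- design$n_inj
  v <- design$inj_ul
  V0 <- design$V0_ul
  M <- X <- bound <- Q <- q <- numeric(nj)
  m_prev <- design$M0_M
  x_prev <- 0
  Q_prev <- 0
  for (j in seq_len(nj)) {
    d <- 1 - v[j] / V0
    m <- m_prev * d
    x <- x_prev * d + design$X0_M * v[j] / V0
    s <- params$n * m + x + 1 / params$Ka
    disc <- s^2 - 4 * params$n * m * x
    if (disc < 0) stop("internal error: negative binding discriminant")
    b <- (s - sqrt(disc)) / 2
    Qj <- params$dH * (V0 * 1e-6) * b * UJ_PER_KCAL
    q[j] <- Qj - Q_prev + (v[j] / V0) * (Qj + Q_prev) / 2
    M[j] <- m; X[j] <- x; bound[j] <- b; Q[j] <- Qj
    m_prev <- m; x_prev <- x; Q_prev <- Qj
  }
  data.frame(injection = seq_len(nj), M_t = M, X_t = X, ratio = X / M,
             bound = bound, Q = Q, q = q)
}

#' Simulate a one-site ITC thermogram
#'
#' Evaluates the one-site isotherm for the design, adds seeded Gaussian
#' noise, and reports heats in the instrument orientation in which
#' exothermic binding appears as a positive peak (signed enthalpy is kept
#' internal to the model).
#'
#' @inheritParams itc_expected_heats
#' @param noise_sd Gaussian noise standard deviation, uJ.
#' @param seed Integer seed for the noise.
#' @return An `itc_thermogram`: per-injection heats `q` (uJ, exothermic
#'   positive), `ratio` (molar ratio), the design, and flags.
#' @export
#' @examples
#' p <- one_site_params(Ka = 1 / 5.82e-3, dH = -2)
#' d <- itc_design(80, 100, "mM")
#' simulate_thermogram(p, d, noise_sd = 0.1, seed = 1)
simulate_thermogram <- function(params, design, noise_sd = 0, seed = 1L) {
  if (noise_sd < 0) stop("'noise_sd' must be non-negative", call. = FALSE)
  exp_h <- itc_expected_heats(params, design)
  q_instr <- -exp_h$q # exothermic (dH < 0) -> positive peaks
  if (noise_sd > 0) {
    set.seed(seed)
    q_instr <- q_instr + stats::rnorm(design$n_inj, sd = noise_sd)
  }
  structure(
    list(q = q_instr, ratio = exp_h$ratio, design = design,
         dilution_corrected = FALSE, sign = "exothermic_positive",
         noise_sd = noise_sd),
    class = "itc_thermogram"
  )
}

#' @export
print.itc_thermogram <- function(x, ...) {
  cat(sprintf("<itc_thermogram> %d injections, heats %.3g .. %.3g uJ (%s)%s\n",
              length(x$q), min(x$q), max(x$q), x$sign,
              if (x$dilution_corrected) " [dilution-corrected]" else ""))
  invisible(x)
}

#' Subtract the heat of dilution from a thermogram
#'
#' Estimates the per-injection background heat as the mean of the final
#' `m_last` injections, where binding is saturated and no further binding
#' heat is evolved, and subtracts it from every injection.
#'
#' @param thermogram An `itc_thermogram`.
#' @param m_last Number of trailing injections to average (>= 1 and less
#'   than the injection count).
#' @return The corrected `itc_thermogram` with `dilution_corrected = TRUE`.
#' @export
subtract_dilution <- function(thermogram, m_last = 3L) {
  stopifnot(inherits(thermogram, "itc_thermogram"))
  nq <- length(thermogram$q)
  if (m_last < 1 || m_last >= nq) {
    stop(sprintf("'m_last' must be in [1, %d), got %s", nq, m_last),
         call. = FALSE)
  }
  offset <- mean(utils::tail(thermogram$q, m_last))
  thermogram$q <- thermogram$q - offset
  thermogram$dilution_corrected <- TRUE
  thermogram$dilution_offset <- offset
  thermogram
}

# signed model heats (uJ) as a function of free parameters, given a design
itc_model_q <- function(logKa, dH, n, design) {
  itc_expected_heats(one_site_params(exp(logKa), dH, n), design)$q
}

#' Fit the one-site independent-binding model to a thermogram
#'
#' Weighted least squares over per-injection heats using
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]) on (ln Ka, dH, n), with
#' automatic initialisation (n = 1, dH scaled from the total evolved
#' heat, Ka from the titrant concentration at half amplitude).  The
#' association constant is reported with Kd = 1/Ka.  A thermogram whose
#' largest excursion stays below three times the injection-to-injection
#' noise estimate is reported as "no detectable binding" (the outcome for
#' a non-binding titration) rather than fitted.
#'
#' @param thermogram An `itc_thermogram` (instrument orientation,
#'   exothermic positive; run [subtract_dilution()] first if the baseline
#'   is offset).
#' @param design The [itc_design()]; defaults to the one stored in the
#'   thermogram.
#' @param init Optional [one_site_params()] starting values.
#' @param fix_n Fix the stoichiometry at its starting value instead of
#'   fitting it; standard practice for low-c titrations where n is not
#'   identifiable.
#' @param weights Optional per-injection weights (default uniform).
#' @param maxiter,tol Convergence controls: iteration cap and relative
#'   tolerance on parameters/objective.
#' @return An `itc_fit`: `detectable` flag, fitted [one_site_params()],
#'   `Kd_M`, per-parameter standard errors, residual standard deviation,
#'   and convergence diagnostics.  Non-convergence raises an error
#'   carrying the last iterate.
#' @export
#' @examples
#' p <- one_site_params(Ka = 1 / 5.82e-3, dH = -2)
#' d <- itc_design(80, 100, "mM")
#' fit_one_site(simulate_thermogram(p, d), fix_n = TRUE)
fit_one_site <- function(thermogram, design = thermogram$design,
                         init = NULL, fix_n = FALSE, weights = NULL,
                         maxiter = 500L, tol = 1e-8) {
  stopifnot(inherits(thermogram, "itc_thermogram"),
            inherits(design, "itc_design"))
  q_obs <- -thermogram$q # back to signed (exothermic negative)
  nq <- length(q_obs)
  if (nq < 5L) stop("need at least 5 usable injections, got ", nq,
                    call. = FALSE)
  if (nq != design$n_inj) {
    stop("thermogram length does not match the design's injection count",
         call. = FALSE)
  }
  # flat-thermogram guard: noise from first differences (sd of q_j - q_{j-1}
  # is sqrt(2) times the per-injection noise for a flat signal)
  noise_est <- stats::sd(diff(q_obs)) / sqrt(2)
  if (max(abs(q_obs)) < 3 * noise_est + 1e-9) {
    return(structure(
      list(detectable = FALSE, params = NULL, Kd_M = NA_real_,
           stderr = NULL, sigma = noise_est, design = design,
           message = "no detectable binding"),
      class = "itc_fit"
    ))
  }
  exp0 <- itc_expected_heats(one_site_params(1, -1, 1), design) # geometry only
  if (is.null(init)) {
    n0 <- 1
    # total signed heat over total injected titrant, assuming near-complete
    # binding; a deliberate overestimate of the bound fraction that nlsLM
    # refines
    inj_mol <- design$X0_M * sum(design$inj_ul) * 1e-6
    bound_guess <- min(n0 * exp0$M_t[nq] * design$V0_ul * 1e-6, inj_mol)
    dH0 <- sum(q_obs) / (UJ_PER_KCAL * bound_guess)
    if (!is.finite(dH0) || dH0 == 0) dH0 <- -1
    # Kd from the titrant concentration where the heat falls to half of its
    # initial amplitude
    half <- which(abs(q_obs) <= abs(q_obs[1]) / 2)
    Kd0 <- if (length(half)) exp0$X_t[half[1]] else exp0$X_t[ceiling(nq / 2)]
    Kd0 <- max(Kd0, 1e-12)
    init <- one_site_params(1 / Kd0, dH0, n0)
  }
  stopifnot(inherits(init, "one_site_params"))
  w <- if (is.null(weights)) rep(1, nq) else weights
  ctrl <- minpack.lm::nls.lm.control(maxiter = as.integer(maxiter),
                                     ftol = tol, ptol = tol)
  dat <- list(q_obs = q_obs)
  fit <- if (fix_n) {
    n_fixed <- init$n
    minpack.lm::nlsLM(
      q_obs ~ itc_model_q(logKa, dH, n_fixed, design), data = dat,
      start = list(logKa = log(init$Ka), dH = init$dH),
      weights = w, control = ctrl)
  } else {
    minpack.lm::nlsLM(
      q_obs ~ itc_model_q(logKa, dH, n, design), data = dat,
      start = list(logKa = log(init$Ka), dH = init$dH, n = init$n),
      lower = c(-Inf, -Inf, 1e-6),
      weights = w, control = ctrl)
  }
  conv <- fit$convInfo
  if (!is.null(conv) && !conv$isConv && conv$finIter >= maxiter) {
    stop(sprintf(
      "one-site fit did not converge in %d iterations (last iterate: %s)",
      maxiter,
      paste(names(stats::coef(fit)), format(stats::coef(fit)),
            collapse = ", ")), call. = FALSE)
  }
  cf <- stats::coef(fit)
  se_raw <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                     error = function(e) rep(NA_real_, length(cf)))
  Ka_hat <- exp(cf[["logKa"]])
  n_hat <- if (fix_n) init$n else cf[["n"]]
  stderr <- c(Ka = unname(Ka_hat * se_raw[["logKa"]]), # delta method
              dH = unname(se_raw[["dH"]]),
              n = if (fix_n) NA_real_ else unname(se_raw[["n"]]))
  structure(
    list(detectable = TRUE,
         params = one_site_params(Ka_hat, cf[["dH"]], n_hat),
         Kd_M = 1 / Ka_hat, stderr = stderr,
         sigma = summary(fit)$sigma, fix_n = fix_n,
         iterations = conv$finIter %||% NA_integer_,
         converged = conv$isConv %||% TRUE,
         design = design, fit = fit),
    class = "itc_fit"
  )
}

#' @export
print.itc_fit <- function(x, ...) {
  if (!x$detectable) {
    cat("<itc_fit> no detectable binding\n")
    return(invisible(x))
  }
  p <- x$params
  cat(sprintf("<itc_fit> Kd = %.4g M (Ka = %.4g /M), dH = %.4g kcal/mol, n = %.4g%s\n",
              x$Kd_M, p$Ka, p$dH, p$n,
              if (isTRUE(x$fix_n)) " (fixed)" else ""))
  cat(sprintf("  residual sd %.3g uJ, %s in %s iterations\n", x$sigma,
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' Fitted Kd in a tagged concentration unit
#'
#' @param fit An `itc_fit` with detectable binding.
#' @param unit `"mM"`, `"uM"`, or `"M"`.
#' @return A [binding_affinity()] in the requested unit.
#' @export
kd_as <- function(fit, unit = c("mM", "uM", "M")) {
  unit <- match.arg(unit)
  stopifnot(inherits(fit, "itc_fit"))
  if (!fit$detectable) stop("no detectable binding; Kd is undefined",
                            call. = FALSE)
  binding_affinity(fit$Kd_M / switch(unit, mM = 1e-3, uM = 1e-6, M = 1),
                   unit)
}
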