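#' Metropolis sampling of a toy system at fixed lambda
#'
#' Draws equilibrium coordinate samples from the Boltzmann distribution of
#' the lambda-interpolated Hamiltonian by random-walk Metropolis.  Used
#' internally by [sample_fep_run()]; exported for sampler diagnostics
#' (e.g. checking that the coordinate variance of a harmonic state matches
#' k_B T / k(lambda)).
#'
#' The proposal is Gaussian with standard deviation `proposal_sd`; by
#' default it is scaled to 2.4 times the local thermal width (harmonic:
#' sqrt(k_B T / k(lambda)); double well: 0.7 A), which keeps acceptance
#' near the efficient range for 1-D random-walk chains.
#'
#' @param system A coordinate-based `toy_system` (harmonic or double well).
#' @param lambda Coupling value in \[0, 1\].
#' @param n_samples Number of post-burn-in samples to keep.
#' @param burn_in Number of initial steps to discard; default 10% of
#'   `n_samples`.
#' @param seed Integer seed (chain is bit-reproducible given the seed).
#' @param proposal_sd Random-walk proposal standard deviation, Angstrom.
#' @return List with `x` (samples), `acceptance_rate`, `lambda`.
#' @export
sample_lambda_state <- function(system, lambda, n_samples,
                                burn_in = ceiling(0.1 * n_samples),
                                seed = 1L, proposal_sd = NULL) {
  stopifnot(inherits(system, "toy_system"))
  if (system$kind == "shifted_gaussian_work") {
    stop("shifted_gaussian_work has no coordinate to sample", call. = FALSE)
  }
  if (n_samples < 1) stop("'n_samples' must be >= 1")
  kT <- kbt(system$T)
  if (is.null(proposal_sd)) {
    proposal_sd <- if (system$kind == "harmonic") {
      k_lam <- (1 - lambda) * system$k0 + lambda * system$k1
      2.4 * sqrt(kT / k_lam)
    } else {
      0.7
    }
  }
  x0 <- if (system$kind == "harmonic") {
    k_lam <- (1 - lambda) * system$k0 + lambda * system$k1
    ((1 - lambda) * system$k0 * system$c0 +
       lambda * system$k1 * system$c1) / k_lam
  } else {
    -1
  }
  set.seed(seed)
  n_tot <- burn_in + n_samples
  prop <- stats::rnorm(n_tot, sd = proposal_sd)
  logu <- log(stats::runif(n_tot))
  x <- numeric(n_tot)
  cur_x <- x0
  cur_e <- interpolate_hamiltonian(system, lambda, cur_x)
  n_acc <- 0L
  beta <- 1 / kT
  for (i in seq_len(n_tot)) {
    cand <- cur_x + prop[i]
    cand_e <- interpolate_hamiltonian(system, lambda, cand)
    if (logu[i] < -beta * (cand_e - cur_e)) {
      cur_x <- cand
      cur_e <- cand_e
      n_acc <- n_acc + 1L
    }
    x[i] <- cur_x
  }
  list(x = x[(burn_in + 1L):n_tot], acceptance_rate = n_acc / n_tot,
       lambda = lambda)
}

#' Generate a stratified FEP run from a toy system
#'
#' For every window of the schedule, draws equilibrium samples at the
#' window's starting lambda and records the energy difference to the
#' window's other end point, dU = H(x; lambda_to) - H(x; lambda_from).
#' Coordinate systems are sampled by Metropolis Monte Carlo with Boltzmann
#' acceptance at the system temperature; the `shifted_gaussian_work` kind
#' is drawn directly from its stated Gaussian work distributions (forward
#' windows from N(mu, sigma2), backward windows from the Crooks-consistent
#' reverse distribution N(-mu + sigma2/k_B T, sigma2)).
#'
#' Reproducibility: window j of a run uses the deterministic child seed
#' `(seed * 1009 + 101 * dir + j) mod (2^31 - 1)` with dir = 1 (forward)
#' or 2 (backward), so windows are independent and the whole run is
#' bit-reproducible for a fixed root seed.  A window whose Metropolis
#' acceptance rate falls below 1% triggers a warning naming the window.
#'
#' @param system A `toy_system`.
#' @param schedule A [make_lambda_schedule()] object.
#' @param n_samples_per_window Post-burn-in samples per window (>= 1).
#' @param burn_in Steps discarded per window; default 10% of
#'   `n_samples_per_window`.
#' @param seed Root integer seed.
#' @return An [fep_run()] carrying one [fep_window()] per schedule window.
#' @export
#' @examples
#' sys <- toy_harmonic(1, 4, T = 0.596 / KB_KCAL)
#' run <- sample_fep_run(sys, make_lambda_schedule(5), 200, seed = 1)
sample_fep_run <- function(system, schedule = make_lambda_schedule(),
                           n_samples_per_window = 1000L,
                           burn_in = ceiling(0.1 * n_samples_per_window),
                           seed = 1L) {
  stopifnot(inherits(system, "toy_system"))
  validate_schedule(schedule)
  if (n_samples_per_window < 1) {
    stop("'n_samples_per_window' must be >= 1", call. = FALSE)
  }
  dir_index <- if (schedule$direction == "forward") 1L else 2L
  v <- schedule$values
  windows <- vector("list", schedule$n_windows)
  for (j in seq_len(schedule$n_windows)) {
    l_from <- v[j]
    l_to <- v[j + 1L]
    sj <- child_seed(seed, j, dir_index)
    if (system$kind == "shifted_gaussian_work") {
      set.seed(sj)
      kT <- kbt(system$T)
      dU <- if (schedule$direction == "forward") {
        stats::rnorm(n_samples_per_window, mean = system$mu,
                     sd = sqrt(system$sigma2))
      } else {
        stats::rnorm(n_samples_per_window,
                     mean = -system$mu + system$sigma2 / kT,
                     sd = sqrt(system$sigma2))
      }
    } else {
      chain <- sample_lambda_state(system, l_from, n_samples_per_window,
                                   burn_in = burn_in, seed = sj)
      if (chain$acceptance_rate < 0.01) {
        warning(sprintf(
          "window %d (lambda %.3f -> %.3f): Metropolis acceptance %.2f%% < 1%%",
          j, l_from, l_to, 100 * chain$acceptance_rate))
      }
      dU <- interpolate_hamiltonian(system, l_to, chain$x) -
        interpolate_hamiltonian(system, l_from, chain$x)
    }
    windows[[j]] <- fep_window(l_from, l_to, dU, T = system$T, seed = sj)
  }
  fep_run(windows, direction = schedule$direction, system = system)
}
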