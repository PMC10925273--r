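#' Analytically solvable alchemical toy systems
#'
#' A toy alchemical system is a pair of one-dimensional end-state
#' Hamiltonians H0 (initial state, lambda = 0) and H1 (final state,
#' lambda = 1) with a known closed-form (or quadrature-exact) free-energy
#' difference.  They stand in for the two protein variants of an alchemical
#' mutation: sampling the lambda-interpolated Hamiltonian in stratified
#' windows produces per-window energy-difference samples on which the
#' free-energy estimators can be validated against the exact answer.
#'
#' Three kinds are provided:
#' \describe{
#'   \item{harmonic}{H_i(x) = k_i/2 (x - c_i)^2.  The configurational
#'     integral of a 1-D harmonic well does not depend on its center, so
#'     Delta G = (k_B T / 2) ln(k1/k0) for any centers.}
#'   \item{shifted_gaussian_work}{No explicit coordinate; the forward
#'     energy difference for one perturbation step is Gaussian with mean
#'     `mu` and variance `sigma2`, for which
#'     Delta G = mu - sigma2 / (2 k_B T) per step.  Backward samples follow
#'     the Crooks-consistent reverse distribution.}
#'   \item{double_well}{H_i(x) = b_i (x^2 - 1)^2 + s_i x, a quartic double
#'     well with barrier height b_i and linear tilt s_i.  Delta G is
#'     evaluated by adaptive quadrature of the two configurational
#'     integrals (relative tolerance 1e-10).}
#' }
#'
#' Kinetic-energy terms are omitted throughout: for mass-preserving
#' mutations the momentum integrals are identical at both end states and
#' cancel exactly in every energy difference and in Delta G.
#'
#' @param k0,k1 End-state spring constants, kcal/mol/A^2; must be positive.
#' @param c0,c1 End-state well centers, Angstrom.
#' @param mu Mean forward per-step energy difference, kcal/mol.
#' @param sigma2 Variance of the forward per-step energy difference,
#'   kcal^2/mol^2; must be non-negative.
#' @param b0,b1 Double-well barrier heights, kcal/mol; must be positive.
#' @param s0,s1 Linear tilts (well offsets), kcal/mol/A.
#' @param T Temperature, Kelvin.
#' @return An object of class `toy_system` with a `kind` field and the
#'   end-state parameters.
#' @seealso [interpolate_hamiltonian()], [analytic_free_energy()],
#'   [sample_fep_run()]
#' @export
#' @examples
#' sys <- toy_harmonic(k0 = 1, k1 = 4, T = 0.596 / KB_KCAL)
#' analytic_free_energy(sys) # 0.5 * 0.596 * log(4)
toy_harmonic <- function(k0, k1, c0 = 0, c1 = 0, T = T_SAMPLER_DEFAULT) {
  assert_scalar_number(k0, "k0", positive = TRUE)
  assert_scalar_number(k1, "k1", positive = TRUE)
  assert_scalar_number(c0, "c0")
  assert_scalar_number(c1, "c1")
  assert_scalar_number(T, "T", positive = TRUE)
  structure(
    list(kind = "harmonic", k0 = k0, k1 = k1, c0 = c0, c1 = c1, T = T),
    class = "toy_system"
  )
}

#' @rdname toy_harmonic
#' @export
toy_gaussian_work <- function(mu, sigma2, T = T_SAMPLER_DEFAULT) {
  assert_scalar_number(mu, "mu")
  assert_scalar_number(sigma2, "sigma2")
  if (sigma2 < 0) stop("'sigma2' must be non-negative, got ", sigma2)
  assert_scalar_number(T, "T", positive = TRUE)
  structure(
    list(kind = "shifted_gaussian_work", mu = mu, sigma2 = sigma2, T = T),
    class = "toy_system"
  )
}

#' @rdname toy_harmonic
#' @export
toy_double_well <- function(b0, b1, s0 = 0, s1 = 0, T = T_SAMPLER_DEFAULT) {
  assert_scalar_number(b0, "b0", positive = TRUE)
  assert_scalar_number(b1, "b1", positive = TRUE)
  assert_scalar_number(s0, "s0")
  assert_scalar_number(s1, "s1")
  assert_scalar_number(T, "T", positive = TRUE)
  structure(
    list(kind = "double_well", b0 = b0, b1 = b1, s0 = s0, s1 = s1, T = T),
    class = "toy_system"
  )
}

#' @export
print.toy_system <- function(x, ...) {
  pars <- x[setdiff(names(x), "kind")]
  cat("<toy_system:", x$kind, ">",
      paste(names(pars), unlist(pars), sep = "=", collapse = "  "), "\n")
  invisible(x)
}

# end-state potential energies; vectorized over x
endpoint_energy <- function(system, x, state = c("0", "1")) {
  state <- match.arg(state)
  switch(system$kind,
    harmonic = if (state == "0") {
      0.5 * system$k0 * (x - system$c0)^2
    } else {
      0.5 * system$k1 * (x - system$c1)^2
    },
    double_well = if (state == "0") {
      system$b0 * (x^2 - 1)^2 + system$s0 * x
    } else {
      system$b1 * (x^2 - 1)^2 + system$s1 * x
    },
    stop("system kind '", system$kind,
         "' has no coordinate Hamiltonian", call. = FALSE)
  )
}

#' Lambda-interpolated Hamiltonian of a toy system
#'
#' Linear alchemical mixing of the two end-state Hamiltonians,
#' H(x; lambda) = (1 - lambda) H0(x) + lambda H1(x), with lambda = 0 the
#' initial variant and lambda = 1 the final variant.
#'
#' @param system A [toy_harmonic()] or [toy_double_well()] system (the
#'   shifted-Gaussian work model has no explicit coordinate).
#' @param lambda Coupling parameter in \[0, 1\].
#' @param x Coordinate (Angstrom); may be a vector.
#' @return Potential energy in kcal/mol, same length as `x`.
#' @export
#' @examples
#' interpolate_hamiltonian(toy_harmonic(1, 3), lambda = 0.5, x = 1) # 1.0
interpolate_hamiltonian <- function(system, lambda, x) {
  stopifnot(inherits(system, "toy_system"))
  assert_scalar_number(lambda, "lambda")
  if (lambda < 0 || lambda > 1) {
    stop("'lambda' must lie in [0, 1], got ", lambda, call. = FALSE)
  }
  if (lambda == 0) return(endpoint_energy(system, x, "0"))
  if (lambda == 1) return(endpoint_energy(system, x, "1"))
  (1 - lambda) * endpoint_energy(system, x, "0") +
    lambda * endpoint_energy(system, x, "1")
}

# log configurational integral log Z = log int exp(-beta H(x)) dx for one
# end state of a double well, with the minimum factored out for stability
log_config_integral <- function(system, state, rel.tol = 1e-10) {
  beta <- 1 / kbt(system$T)
  h <- function(x) endpoint_energy(system, x, state)
  hmin <- min(h(seq(-3, 3, length.out = 2001)))
  val <- stats::integrate(function(x) exp(-beta * (h(x) - hmin)),
                          lower = -Inf, upper = Inf,
                          rel.tol = rel.tol, abs.tol = 0)$value
  log(val) - beta * hmin
}

#' Exact free-energy difference of a toy system
#'
#' The closed-form (harmonic, shifted-Gaussian work) or quadrature-exact
#' (double well) Delta G between the lambda = 0 and lambda = 1 end states.
#' This is the oracle the sampling-based estimators are validated against;
#' it depends only on the end states, never on the lambda schedule.
#'
#' For `shifted_gaussian_work` the value is per perturbation step; a run
#' over W windows accumulates W times this value (pass `n_steps` to get the
#' schedule total).
#'
#' @param system A `toy_system`.
#' @param n_steps Number of perturbation steps (windows); only meaningful
#'   for `shifted_gaussian_work`, ignored otherwise.
#' @return Delta G in kcal/mol.
#' @export
#' @examples
#' analytic_free_energy(toy_harmonic(1, 4, T = 0.596 / KB_KCAL)) # 0.4131
analytic_free_energy <- function(system, n_steps = 1L) {
  stopifnot(inherits(system, "toy_system"))
  kT <- kbt(system$T)
  switch(system$kind,
    harmonic = 0.5 * kT * log(system$k1 / system$k0),
    shifted_gaussian_work = n_steps * (system$mu - system$sigma2 / (2 * kT)),
    double_well = -kT * (log_config_integral(system, "1") -
                           log_config_integral(system, "0")),
    stop("no closed-form free energy for system kind '", system$kind, "'",
         call. = FALSE)
  )
}
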