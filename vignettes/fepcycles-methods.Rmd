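---
title: "Methods: window-based free-energy estimation, thermodynamic cycles, and one-site ITC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window-based free-energy estimation, thermodynamic cycles, and one-site ITC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fepcycles)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the numerical choices behind the contracts,
and what the synthetic benchmarks do and do not demonstrate.

## 1. The alchemical model and its conventions

An alchemical mutation replaces one Hamiltonian by another along a coupling
parameter: H(x; λ) = (1 − λ)·H₀(x) + λ·H₁(x).  Throughout the package
**λ = 0 is the initial state and λ = 1 the final state**.  Mixing
conventions differ across the literature (some write the coefficient λ on
the initial state); the physical ΔG is unaffected up to the sign of the
direction label, so the package fixes one convention and states it here
once.  The free-energy difference is accumulated over a stratified schedule
of λ windows; the default schedule has 20 windows at 0.05 spacing with a
forward (0 → 1) and a backward (1 → 0) run, mirroring common practice for
protein mutation FEP.

Kinetic-energy terms are omitted from the toy Hamiltonians.  For
mass-preserving mutations the momentum integrals are identical at both end
states, so they cancel exactly in every ΔU and in ΔG; nothing is lost by
working with configurational energies only.

## 2. Toy systems as estimator oracles

Converged FEP on a membrane protein needs microsecond-scale MD; no desk
benchmark can reproduce those legs.  What *can* be validated exactly is the
estimation machinery, and that is what the toy systems are for:

* **harmonic** — H_i(x) = k_i/2 (x − c_i)²; ΔG = (k_BT/2) ln(k1/k0) for
  any centers, since the 1-D Gaussian configurational integral is
  center-independent.
* **shifted_gaussian_work** — the per-step energy difference is
  N(μ, σ²), for which ΔG = μ − σ²/(2k_BT); the backward direction draws
  from the Crooks-consistent reverse distribution N(−μ + σ²/k_BT, σ²), so
  two-sided estimators see a thermodynamically consistent pair.  The value
  is *per perturbation step*; a W-window schedule accumulates W times it.
* **double_well** — a quartic double well b_i(x² − 1)² + s_i·x with ΔG by
  adaptive quadrature (`stats::integrate`, relative tolerance 1e-10, the
  well minimum factored out of the exponent first).

The benchmark conditions used by the tests and the acceptance script are
the study's stated protocol transplanted to the toys: 20 windows at 0.05
spacing, 5,000 equilibrium samples per window per direction, k_BT = 0.596
kcal/mol (the harmonic case), and n = 10⁵ for the single-window Gaussian
checks.  These sizes keep the whole suite in the minutes range on one CPU
while leaving Monte Carlo errors small enough for 3-SE comparisons against
the closed forms.

What the toys emulate: stratified window sampling, forward/backward
asymmetry, controllable overlap quality (window spacing and spring-constant
contrast set how far neighbouring ΔU distributions separate), and sampling
noise with realistic serial correlation.  What they do not emulate: rugged
high-dimensional landscapes, slow conformational degrees of freedom coupled
to the alchemical coordinate, soft-core endpoint singularities, and
finite-size/periodicity artefacts.  A green benchmark therefore certifies
the estimators and their error model, not the convergence of any particular
protein simulation.

## 3. Sampling

Coordinate systems are sampled by random-walk Metropolis with Boltzmann
acceptance at the system temperature.  Defaults: proposal standard
deviation 2.4× the local thermal width (√(k_BT/k(λ)) for the harmonic
mixture; 0.7 Å for double wells), which puts 1-D acceptance in the
efficient range; burn-in 10% of the requested samples; no thinning.  Each
window draws its own chain at the window's starting λ and records
ΔU = H(x; λ_next) − H(x; λ_start).  The `shifted_gaussian_work` kind is
drawn directly from its stated Gaussians (no Markov chain).

Reproducibility: window j of direction d (1 = forward, 2 = backward) under
root seed s uses the child seed (1009·s + 101·d + j) mod (2³¹ − 1), so
windows are mutually independent, runs are bit-reproducible, and the two
directions never share a stream.  A window whose acceptance rate falls
below 1% triggers a warning naming the window.  Default temperature is
303.15 K (the MD-protocol temperature); the calorimetry and pKa modules
default to 298.15 K (25 °C) — see §5.

## 4. Estimators and their error model

* **Zwanzig**: ΔG = −k_BT ln⟨e^{−βΔU}⟩, the one-directional baseline.
* **SOS**: ΔG = −k_BT[ln⟨e^{−βΔU/2}⟩_i − ln⟨e^{−βΔU′/2}⟩_{i+1}], the
  two-sided half-exponent estimator used for the headline numbers.
* **BAR**: the root of Bennett's self-consistency equation, solved with
  Brent's method on the bracket [min, max of the two directional Zwanzig
  estimates] ± 50 k_BT to 1e-8 kcal/mol.  BAR serves as the independent
  cross-check on SOS, never the other way round.

All exponential averages go through a log-sum-exp formulation; this is part
of the contract (no intermediate overflow for |βΔU| up to several hundred),
not an optimization.  Windows are paired by λ-interval identity, not list
position, so ragged forward/backward inputs fail loudly.  Degenerate
windows that drive an estimate non-finite report ±Inf with a NaN error and
a warning rather than aborting a whole accumulation.

**Errors.**  Per-window standard errors come from a nonparametric bootstrap
(B = 200 by default); window errors combine in quadrature across the
schedule.  One design decision deserves emphasis: the accumulation step
uses a *moving-block* bootstrap with a fixed block length of 50.  Metropolis
chains are serially correlated, and an iid bootstrap on correlated samples
understates the standard error of a window mean roughly by the square root
of the integrated autocorrelation time — enough to make "within 3 SE"
comparisons fail for perfectly healthy runs.  Resampling contiguous blocks
of 50 (several times the ~4-sample correlation scale of these 1-D chains)
restores calibration without estimating autocorrelation times, and is
harmless for independent samples, where it reduces to a slightly noisier
iid bootstrap.  The block length is a documented constant, not a fitted
quantity; `bootstrap_stderr()` keeps block length 1 as its primitive
default.

The overlap diagnostic is the histogram intersection (50 shared bins) of
the forward ΔU distribution and the negated backward distribution: 1 for
identical distributions, 0 for disjoint supports.  Neighbouring windows of
the default harmonic benchmark score ≈ 0.9; values below ~0.5 flag window
spacings too coarse for reliable two-sided estimation.

## 5. Thermodynamic cycles, pKa shifts, folds

`ddg_binding()` closes the cycle ΔΔG = ΔG_bound − ΔG_unbound; positive
values mean the mutation weakens cation binding.  Leg errors combine in
quadrature by default with a linear-addition option (`error_rule`), because
the published per-cycle errors are consistent with different rules in
different rows; the reproduction report prints both.  `ddg_to_dpka()`
divides by RT ln 10 (1.3643 kcal/mol at 298.15 K).  The conversion
temperature is not stated with the published values; 298.15 K is chosen as
the default because it matches the 25 °C calorimetry and reproduces both
published roundings, and it is overridable.  Affinities are unit-tagged
(`binding_affinity`), and `cooperativity_fold()` refuses to mix mM with μM
— unit slips, not arithmetic, are the realistic failure mode here.

`reproduce_cycle_table()` recomputes every published cycle from its legs
and flags any row whose recomputation differs from the printed value by
more than 0.05 kcal/mol (rounding precision).  Two rows flag by design:
the Thr121→Ala legs recompute to 6.61 against a printed 6.7, and the
Asp59→Cys proton row recomputes to −5.0 under the printed bound/unbound
labels against a printed +5.1.  The fixture stores the printed labels
verbatim plus a corrected `role` column (the column concerns protonation
of Asp55; the printed labels name Asp59), and known text-versus-table
discrepancies travel in a `note` column.  The report flags; it never
"corrects".

## 6. One-site ITC

`simulate_thermogram()`/`fit_one_site()` implement the single-site
(Wiseman) isotherm.  Displaced-volume ("perfusion") bookkeeping is used
for the overfilled-cell geometry: after injection j of volume v,
M_j = M_{j−1}(1 − v/V₀) and X_j = X_{j−1}(1 − v/V₀) + X₀·v/V₀; the bound
complex is the physical root of the binding quadratic; and the
per-injection heat carries the standard correction
q_j = Q_j − Q_{j−1} + (v/V₀)(Q_j + Q_{j−1})/2.  This convention is
isolated in `itc_expected_heats()` so an alternative dilution model would
be a one-function change.  Defaults mirror the instrument protocol:
2 μL injections, 300 μL cell, 25 °C.  Thermograms are stored in the
instrument orientation (exothermic = positive peak); the signed enthalpy
is internal to the model and restored at the fit boundary.

Dilution heat is estimated as the mean of the last 3 injections
(configurable) and subtracted — the "last few injections" rule.  Fitting
is weighted least squares (uniform weights by default) via
Levenberg–Marquardt (`minpack.lm::nlsLM`) on (ln Ka, ΔH, n), relative
tolerance 1e-8, at most 500 iterations; ln Ka keeps the association
constant positive without constraints.  Auto-initialisation: n = 1, ΔH
scaled from the total evolved heat assuming near-complete binding, Kd from
the titrant concentration at half amplitude.  A thermogram whose largest
excursion stays below 3× the injection-to-injection noise estimate returns
a first-class "no detectable binding" result — the honest outcome for a
cation titration into a binding-dead mutant — rather than an exception or
a runaway fit.

Low-c titrations (c = n·M₀/Kd ≪ 1, the regime of mM-range sugar binding
to ~tens of μM protein) do not determine the stoichiometry; `fix_n = TRUE`
fixes it at its starting value, the standard practice for such data, and
is used in the package's noisy-recovery study (100 seeded replicates at
2% noise; the tests require the median Kd error below 15%).  Ionic-strength
effects (e.g. choline chloride supplementation in cation titrations) are
not modeled; condition strings are metadata only.

## 7. I/O and the command line

The TSV window dialect is deliberately minimal: `#T <kelvin>`, optional
`#RUN <direction>` section markers (so one stream can carry a
forward/backward pair), `#WINDOW <λi> <λj>` headers, and
`<step>\t<dU>` rows written at `%.17g` so round trips are bit-exact.
NAMD-style `fepout` files are read-only: window bounds from
`#NEW FEP WINDOW:` lines, ΔE from the 7th whitespace-separated field of
`FepEnergy:` records, temperature from the 9th when present; all other
fields are opaque.  Malformed lines are collected and reported with line
numbers; zero windows or a non-monotone λ sequence is a format error.
Energies are normalized to kcal/mol at the I/O boundary.

`fep_cli()` exposes the pipeline as subcommands (`simulate-toy`,
`estimate`, `cycle`, `pka-shift`, `itc-simulate`, `itc-fit`, `reproduce`)
with exit codes 0/2/1 for success/usage/computation errors, logging to
stderr and results to stdout or `--out`.  Identical argv + seed give
byte-identical outputs.

## 8. Known limitations

* The toy sampler is 1-D; it validates estimators, not sampling strategies
  for rugged landscapes (no replica exchange, no soft-core potentials).
* No MBAR/WHAM multi-state estimator; accumulation is strictly pairwise
  per window.
* The per-window error estimator behind the published "±" values is not
  stated in the source material; the block bootstrap here is a declared
  substitute, not a reconstruction, so error bars are methodologically
  comparable but not identical.
* The ITC module fits heats, not raw power traces; peak integration and
  baseline drift are upstream of its inputs, and only the one-site model
  is provided.
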