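# shared fixtures: thermal energy chosen so kT = 0.596 kcal/mol
KT_TOY <- 0.596
T_TOY <- KT_TOY / fepcycles::KB_KCAL

harmonic_14 <- function() toy_harmonic(k0 = 1, k1 = 4, T = T_TOY)

# forward/backward run pair for a system, distinct seeds per direction
run_pair <- function(system, n_windows = 10, n = 1000, seed = 1) {
  list(
    fwd = sample_fep_run(system, make_lambda_schedule(n_windows, "forward"),
                         n, seed = seed),
    bwd = sample_fep_run(system, make_lambda_schedule(n_windows, "backward"),
                         n, seed = seed + 1000)
  )
}

# relabel a run as its alchemical mirror image (lambda -> 1 - lambda), so a
# backward run of A->B becomes the forward run of B->A and vice versa
reverse_run <- function(run) {
  wins <- lapply(run$windows, function(w) {
    fep_window(1 - w$lambda_from, 1 - w$lambda_to, w$samples_dU,
               T = w$T, seed = w$seed)
  })
  fep_run(wins,
          direction = if (run$direction == "forward") "backward" else "forward")
}
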