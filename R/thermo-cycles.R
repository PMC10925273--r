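#' Mutation-induced change in cation-binding free energy
#'
#' Closes the alchemical thermodynamic cycle: the experimentally
#' inaccessible change in cation-binding affinity caused by a mutation is
#' obtained from the two alchemical mutation legs,
#' ddG_binding = dG(mutation, cation-bound) - dG(mutation, cation-unbound).
#' A more positive ddG indicates a larger reduction in cation-binding
#' affinity after the mutation.  For protonation cycles the "bound" and
#' "unbound" states are the protonated and deprotonated residue.
#'
#' @param leg_bound,leg_unbound The two mutation legs, as
#'   [free_energy_estimate()] objects or bare numbers (kcal/mol; bare
#'   numbers get `NA` errors and the default temperature).
#' @param cation `"Na+"` or `"H+"` (any label is accepted).
#' @param label Cycle label, e.g. `"WT->D59C / Na+"`.
#' @param error_rule How leg errors combine: `"quadrature"` (default) or
#'   `"linear"`.
#' @return A `mutation_cycle`: list with `label`, `cation`, `leg_bound`,
#'   `leg_unbound`, `ddG`, `ddG_err`, `error_rule`, `T`.
#' @export
#' @examples
#' ddg_binding(127.7, 117.2, cation = "Na+")$ddG # 10.5
ddg_binding <- function(leg_bound, leg_unbound, cation = "Na+",
                        label = NULL,
                        error_rule = c("quadrature", "linear")) {
  error_rule <- match.arg(error_rule)
  if (is.numeric(leg_bound)) leg_bound <- free_energy_estimate(leg_bound)
  if (is.numeric(leg_unbound)) leg_unbound <- free_energy_estimate(leg_unbound)
  stopifnot(inherits(leg_bound, "free_energy_estimate"),
            inherits(leg_unbound, "free_energy_estimate"))
  if (abs(leg_bound$T - leg_unbound$T) > 1e-9) {
    stop(sprintf("temperature mismatch between legs: %g K vs %g K",
                 leg_bound$T, leg_unbound$T), call. = FALSE)
  }
  ddG <- leg_bound$value - leg_unbound$value
  eb <- leg_bound$stderr
  eu <- leg_unbound$stderr
  ddG_err <- if (is.na(eb) || is.na(eu)) {
    NA_real_
  } else if (error_rule == "quadrature") {
    sqrt(eb^2 + eu^2)
  } else {
    eb + eu
  }
  structure(
    list(label = label %||% paste0("cycle / ", cation), cation = cation,
         leg_bound = leg_bound, leg_unbound = leg_unbound,
         ddG = ddG, ddG_err = ddG_err, error_rule = error_rule,
         T = leg_bound$T),
    class = "mutation_cycle"
  )
}

#' @export
print.mutation_cycle <- function(x, ...) {
  err <- if (is.na(x$ddG_err)) "" else sprintf(" +/- %.1f", x$ddG_err)
  cat(sprintf("<mutation_cycle> %s: ddG = %.1f%s kcal/mol (%s errors)\n",
              x$label, x$ddG, err, x$error_rule))
  invisible(x)
}

#' Convert a binding free-energy change to a pKa shift
#'
#' A change of R T ln(10) kcal/mol in proton-binding free energy
#' corresponds to one pKa unit, so
#' dpKa = ddG / (R T ln 10) with R = 1.987204259e-3 kcal/(mol K).
#' Positive ddG means weaker proton binding and is reported as a positive
#' number of pKa units of decrease.
#'
#' @param ddG Binding free-energy change, kcal/mol (may be a
#'   `mutation_cycle`, in which case its `ddG` field is used).
#' @param T Temperature, Kelvin; default 298.15 K (25 degrees C).
#' @return pKa shift in units (unitless).
#' @export
#' @examples
#' ddg_to_dpka(2.0)            # ~1.5 units
#' ddg_to_dpka(KB_KCAL * 298.15 * log(10)) # exactly 1
ddg_to_dpka <- function(ddG, T = T_ITC_DEFAULT) {
  if (inherits(ddG, "mutation_cycle")) ddG <- ddG$ddG
  assert_scalar_number(ddG, "ddG")
  assert_scalar_number(T, "T", positive = TRUE)
  ddG / (KB_KCAL * T * log(10))
}

#' Tagged binding affinity (Kd with its reciprocal Ka)
#'
#' Stores a dissociation constant with an explicit concentration unit so
#' that downstream ratios cannot silently mix scales; Ka = 1/Kd is kept in
#' reciprocal units of the same tag.
#'
#' @param Kd Dissociation constant (> 0) in the tagged unit.
#' @param unit `"mM"`, `"uM"`, or `"M"`.
#' @param condition Free-text condition label (e.g. "+Na+, pH 7.5").
#' @return A `binding_affinity` object.
#' @export
#' @examples
#' binding_affinity(5.82, "mM", "no Na+")
binding_affinity <- function(Kd, unit = c("mM", "uM", "M"), condition = "") {
  unit <- match.arg(unit)
  assert_scalar_number(Kd, "Kd")
  if (Kd <= 0) stop("'Kd' must be positive, got ", Kd, call. = FALSE)
  structure(
    list(Kd = Kd, Ka = 1 / Kd, unit = unit, condition = condition),
    class = "binding_affinity"
  )
}

#' @export
print.binding_affinity <- function(x, ...) {
  cat(sprintf("<binding_affinity> Kd = %g %s (Ka = %g /%s)%s\n",
              x$Kd, x$unit, x$Ka, x$unit,
              if (nzchar(x$condition)) paste0(" [", x$condition, "]") else ""))
  invisible(x)
}

#' Cooperativity fold between two binding conditions
#'
#' Ratio of dissociation constants without versus with the co-substrate,
#' fold = Kd(without) / Kd(with); a fold above 1 quantifies positive
#' thermodynamic coupling (the co-substrate improves binding).  Both
#' affinities must carry the same concentration unit.
#'
#' @param kd_without,kd_with [binding_affinity()] objects measured in the
#'   absence and presence of the co-substrate (or at the two conditions
#'   being compared).
#' @return The fold change (unitless, unrounded; reports round to 2
#'   decimals).
#' @export
#' @examples
#' cooperativity_fold(binding_affinity(9.28, "mM"),
#'                    binding_affinity(1.09, "mM")) # ~8.51
cooperativity_fold <- function(kd_without, kd_with) {
  stopifnot(inherits(kd_without, "binding_affinity"),
            inherits(kd_with, "binding_affinity"))
  if (kd_without$unit != kd_with$unit) {
    stop(sprintf("unit mismatch: %s vs %s (convert explicitly first)",
                 kd_without$unit, kd_with$unit), call. = FALSE)
  }
  kd_without$Kd / kd_with$Kd
}
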