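#' Physical constants and unit helpers
#'
#' `KB_KCAL` is Boltzmann's constant expressed per mole,
#' 1.987204259e-3 kcal/(mol K) (identical to the molar gas constant R in
#' these units).  `T_SAMPLER_DEFAULT` (303.15 K) is the default temperature
#' of the toy sampler; `T_ITC_DEFAULT` (298.15 K, 25 degrees C) is the
#' default for calorimetry and pKa conversions.
#'
#' @format Numeric scalars.
#' @name constants
NULL

#' @rdname constants
#' @export
KB_KCAL <- 1.987204259e-3

#' @rdname constants
#' @export
T_SAMPLER_DEFAULT <- 303.15

#' @rdname constants
#' @export
T_ITC_DEFAULT <- 298.15

# microjoules per kcal; used at the calorimetry unit boundary
UJ_PER_KCAL <- 4.184e9

#' Thermal energy k_B T in kcal/mol
#'
#' @param T Absolute temperature in Kelvin.
#' @return k_B T in kcal/mol.
#' @export
#' @examples
#' kbt(303.15)
kbt <- function(T) {
  stopifnot(is.numeric(T), length(T) == 1L, is.finite(T))
  if (T <= 0) stop("temperature must be positive (Kelvin), got ", T)
  KB_KCAL * T
}
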