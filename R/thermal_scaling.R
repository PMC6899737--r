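#' Physical constants for Boltzmann-Arrhenius temperature scaling
#'
#' Bundles the constants shared by every stage of the analysis: the Boltzmann
#' constant in eV/K, the reference temperature `T0` used for all biological
#' rates (10 degrees C, the midpoint of the experimental range), and the
#' separate reference temperature `T0_star` at which the assimilation
#' efficiency intercept is defined.  The two references genuinely differ, so
#' every function takes the constants object rather than hard-coding either.
#'
#' @param boltzmann_eV_K Boltzmann constant, eV/K.
#' @param T0_K Reference temperature for rate scaling, Kelvin.
#' @param T0_star_K Reference temperature for assimilation efficiency, Kelvin.
#' @return An object of class `fr_constants`.
#' @examples
#' const <- fr_constants()
#' const$T0_K  # 283.15 K = 10 C
#' @export
fr_constants <- function(boltzmann_eV_K = 8.618e-5,
                         T0_K = 283.15,
                         T0_star_K = 293.15) {
  stopifnot(boltzmann_eV_K > 0, T0_K > 0, T0_star_K > 0)
  structure(list(boltzmann_eV_K = boltzmann_eV_K,
                 T0_K = T0_K,
                 T0_star_K = T0_star_K),
            class = "fr_constants")
}

#' @export
print.fr_constants <- function(x, ...) {
  cat("Thermal-scaling constants:\n")
  cat(sprintf("  k   = %.4g eV/K\n", x$boltzmann_eV_K))
  cat(sprintf("  T0  = %.2f K (%.2f C)\n", x$T0_K, kelvin_to_celsius(x$T0_K)))
  cat(sprintf("  T0* = %.2f K (%.2f C, assimilation reference)\n",
              x$T0_star_K, kelvin_to_celsius(x$T0_star_K)))
  invisible(x)
}

#' Temperature unit conversion
#'
#' All I/O in this package carries temperature in degrees Celsius; internals
#' work in Kelvin.  These helpers convert at the boundary.
#'
#' @param T_C,T_K Temperature in degrees Celsius / Kelvin.
#' @return Numeric vector of converted temperatures.
#' @export
celsius_to_kelvin <- function(T_C) T_C + 273.15

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(T_K) T_K - 273.15

#' Boltzmann-Arrhenius temperature factor
#'
#' The multiplier `exp(E * (T - T0) / (k * T * T0))` by which a biological
#' rate measured at the reference temperature `T0` is scaled to temperature
#' `T`, given activation energy `E` in electron volts.  At `T = T0` the
#' factor is exactly 1 for any `E`; for `E > 0` it increases monotonically
#' with `T`.
#'
#' @param E Activation energy, eV (may be zero or negative).
#' @param T_K Absolute temperature, Kelvin.
#' @param T0_K Reference temperature, Kelvin.
#' @param k Boltzmann constant, eV/K.
#' @return Dimensionless multiplier (vectorized over `E` and `T_K`).
#' @examples
#' arrhenius_factor(0.704, celsius_to_kelvin(18))  # rate ~2.2x faster at 18 C
#' @export
arrhenius_factor <- function(E, T_K, T0_K = fr_constants()$T0_K,
                             k = fr_constants()$boltzmann_eV_K) {
  if (any(!is.finite(T_K)) || any(T_K <= 0))
    stop("absolute temperature must be positive and finite")
  if (any(T0_K <= 0)) stop("reference temperature must be positive")
  exp(E * (T_K - T0_K) / (k * T_K * T0_K))
}

#' Assimilation-efficiency parameters
#'
#' Defaults follow the meta-analytic temperature scaling of assimilation
#' efficiency for carnivorous invertebrates: a logistic-transformed Arrhenius
#' function with intercept `omega0 = exp(2.266)` (odds scale, defined at
#' `T0_star` = 293.15 K) and activation energy 0.164 eV.
#'
#' @param omega0 Intercept on the odds scale at `T0_star` (> 0).
#' @param E_omega_eV Activation energy of assimilation efficiency, eV.
#' @param T0_star_K Reference temperature, Kelvin.
#' @return An object of class `assimilation_params`.
#' @export
assimilation_params <- function(omega0 = exp(2.266),
                                E_omega_eV = 0.164,
                                T0_star_K = 293.15) {
  stopifnot(omega0 > 0, T0_star_K > 0)
  structure(list(omega0 = omega0, E_omega_eV = E_omega_eV,
                 T0_star_K = T0_star_K),
            class = "assimilation_params")
}

#' Temperature-dependent assimilation efficiency
#'
#' Fraction of ingested energy not lost to excretion, modelled as
#' `omega(T) = w A / (1 + w A)` with `w = omega0` and `A` the Arrhenius
#' factor at `T` relative to `T0_star`.  Always in (0, 1); strictly
#' increasing in temperature when `E_omega > 0`.
#'
#' @param T_K Absolute temperature, Kelvin (vectorized).
#' @param params An [assimilation_params()] object.
#' @param k Boltzmann constant, eV/K.
#' @return Assimilation efficiency in (0, 1).
#' @examples
#' assimilation_efficiency(celsius_to_kelvin(20))  # ~0.906 at the reference
#' @export
assimilation_efficiency <- function(T_K, params = assimilation_params(),
                                    k = fr_constants()$boltzmann_eV_K) {
  A <- arrhenius_factor(params$E_omega_eV, T_K, params$T0_star_K, k)
  wA <- params$omega0 * A
  wA / (1 + wA)
}
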