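## BPP relaxation-vs-correlation-time curves and Stokes-Einstein(-Debye)
## size / mobility / hydration conversions.

#' Hydrodynamic context
#'
#' Temperature, solvent viscosity and Larmor frequency bundle used by the
#' size and relaxation conversions.
#'
#' @param T Temperature, K (> 0).
#' @param eta Dynamic viscosity, Pa s; defaults to pure water at `T` via
#'   [water_viscosity()].
#' @param nu0 Nuclear Larmor frequency, Hz (e.g. 200e6 for 31P at 11.7 T).
#' @return An object of class `hydro_context` with fields `T`, `eta`,
#'   `nu0`, `omega0` (= 2 pi nu0, rad/s).
#' @export
hydro_context <- function(T, eta = water_viscosity(T), nu0 = 200e6) {
  check_scalar(T, "T", positive = TRUE)
  check_scalar(eta, "eta", positive = TRUE)
  check_scalar(nu0, "nu0", positive = TRUE)
  structure(list(T = T, eta = eta, nu0 = nu0, omega0 = 2 * pi * nu0),
            class = "hydro_context")
}

#' Viscosity of pure water
#'
#' Vogel-type correlation
#' \eqn{\eta(T) = 2.414 \times 10^{-5} \cdot 10^{247.8/(T - 140)}} Pa s,
#' accurate to better than 2% against standard water tables over
#' 278-368 K; strictly decreasing in temperature.
#'
#' @param T Temperature, K; must lie in (273, 373).
#' @return Dynamic viscosity, Pa s (vectorized).
#' @export
water_viscosity <- function(T) {
  if (any(!is.finite(T)) || any(T <= 273) || any(T >= 373))
    stop_input("water_viscosity: temperature must lie in (273, 373) K")
  2.414e-5 * 10^(247.8 / (T - 140))
}

#' Hydrodynamic diameter from translational diffusion (Stokes-Einstein)
#'
#' \eqn{d = k_B T / (3 \pi \eta D)}.
#'
#' @param D Translational diffusion coefficient, m^2/s (> 0).
#' @param ctx A [hydro_context()].
#' @return Hydrodynamic diameter, m.
#' @seealso [diffusion_from_diameter()] for the inverse.
#' @export
stokes_einstein_diameter <- function(D, ctx) {
  stopifnot(inherits(ctx, "hydro_context"))
  if (any(D <= 0)) stop_input("D must be > 0")
  K_BOLTZMANN * ctx$T / (3 * pi * ctx$eta * D)
}

#' @rdname stokes_einstein_diameter
#' @param d Hydrodynamic diameter, m (> 0).
#' @export
diffusion_from_diameter <- function(d, ctx) {
  stopifnot(inherits(ctx, "hydro_context"))
  if (any(d <= 0)) stop_input("d must be > 0")
  K_BOLTZMANN * ctx$T / (3 * pi * ctx$eta * d)
}

#' Hydrodynamic diameter from rotational correlation time
#' (Stokes-Einstein-Debye)
#'
#' Inverts \eqn{\tau_c = \pi \eta d^3 / (6 k_B T)} for the diameter of a
#' sphere tumbling with correlation time `tau`.
#'
#' @param tau Rotational correlation time, s (> 0).
#' @param ctx A [hydro_context()].
#' @return Diameter, m.
#' @seealso [sed_tau_from_diameter()] for the inverse.
#' @export
sed_diameter_from_tau <- function(tau, ctx) {
  stopifnot(inherits(ctx, "hydro_context"))
  if (any(tau <= 0)) stop_input("tau must be > 0")
  (6 * K_BOLTZMANN * ctx$T * tau / (pi * ctx$eta))^(1 / 3)
}

#' @rdname sed_diameter_from_tau
#' @param d Diameter, m (> 0).
#' @export
sed_tau_from_diameter <- function(d, ctx) {
  stopifnot(inherits(ctx, "hydro_context"))
  if (any(d <= 0)) stop_input("d must be > 0")
  pi * ctx$eta * d^3 / (6 * K_BOLTZMANN * ctx$T)
}

#' Correlation time matching the inverse Larmor frequency
#'
#' \eqn{\tau_c = 1/\omega_0 = 1/(2 \pi \nu_0)}: the tumbling time at which
#' the longitudinal relaxation rate peaks (about 800 ps at a 200 MHz
#' Larmor frequency).
#'
#' @param nu0 Larmor frequency, Hz (> 0).
#' @return Correlation time, s.
#' @export
inverse_larmor_tau <- function(nu0) {
  if (any(nu0 <= 0)) stop_input("nu0 must be > 0")
  1 / (2 * pi * nu0)
}

#' Random-field BPP relaxation rates
#'
#' Relaxation by an isotropically fluctuating local field with spectral
#' density \eqn{J(\omega) = 2\tau/(1 + \omega^2\tau^2)}:
#' \deqn{R_1 = c \, 2\tau/(1 + \omega_0^2 \tau^2), \qquad
#'       R_2 = c \, (\tau + \tau/(1 + \omega_0^2 \tau^2)),}
#' where `c` is the mean-square local-field coupling (rad^2/s^2), a free
#' overall scale. `R2 >= R1` everywhere, the two coincide in the
#' extreme-narrowing limit, and R1 peaks at \eqn{\tau = 1/\omega_0}.
#'
#' @param tau Correlation time(s), s (> 0); vectorized.
#' @param ctx A [hydro_context()] (supplies \eqn{\omega_0}).
#' @param coupling Mean-square local-field strength, rad^2/s^2 (> 0).
#' @return A data frame with columns `tau_s`, `R1`, `R2`.
#' @export
bpp_random_field_rates <- function(tau, ctx, coupling = 1) {
  stopifnot(inherits(ctx, "hydro_context"))
  if (any(tau <= 0)) stop_input("tau must be > 0")
  check_scalar(coupling, "coupling", positive = TRUE)
  w0 <- ctx$omega0
  jw <- tau / (1 + (w0 * tau)^2)
  data.frame(tau_s = tau,
             R1 = coupling * 2 * jw,
             R2 = coupling * (tau + jw))
}

#' Hydration waters lost between two hydrodynamic states
#'
#' Converts a shrinkage of the hydrodynamic diameter into a hydration-shell
#' volume change \eqn{\Delta V = (\pi/6)(d_1^3 - d_2^3)} and the nearest
#' whole number of water molecules of radius `r_w` it accounts for.
#'
#' @param d1,d2 Hydrodynamic diameters before and after, m; `d1 >= d2 > 0`.
#' @param r_w Water radius, m (default 1.4 Angstrom).
#' @return List with `count` (integer waters lost) and `dV` (m^3).
#' @export
hydration_water_loss <- function(d1, d2, r_w = 1.4e-10) {
  check_scalar(d1, "d1", positive = TRUE)
  check_scalar(d2, "d2", positive = TRUE)
  check_scalar(r_w, "r_w", positive = TRUE)
  if (d1 < d2)
    stop_input("hydration_water_loss: d1 < d2 would be a negative ",
               "dehydration (diameter grew)")
  dV <- (pi / 6) * (d1^3 - d2^3)
  v_w <- (4 / 3) * pi * r_w^3
  list(count = as.integer(round(dV / v_w)), dV = dV)
}

#' Convert between linewidth and transverse relaxation rate
#'
#' Lorentzian lifetime broadening with the \eqn{R_2 = \pi \cdot FWHM}
#' convention.
#'
#' @param value Linewidth (Hz) or rate (1/s), >= 0.
#' @param direction `"fwhm_to_r2"` or `"r2_to_fwhm"`.
#' @return The converted value.
#' @export
fwhm_r2_convert <- function(value, direction = c("fwhm_to_r2", "r2_to_fwhm")) {
  direction <- match.arg(direction)
  if (any(value < 0)) stop_input("value must be >= 0")
  if (direction == "fwhm_to_r2") pi * value else value / pi
}
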