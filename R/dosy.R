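## Stejskal-Tanner pulsed-field-gradient attenuation, log-linear diffusion
## fitting, and gradient-schedule design.

#' DOSY dataset
#'
#' Gradient schedule, attenuated intensities and pulse timings for a
#' pulsed-field-gradient diffusion measurement.
#'
#' @param gradients Gradient strengths, T/m, strictly increasing (the first
#'   may be 0).
#' @param intensities Signal amplitudes (> 0), same length as `gradients`.
#' @param gamma Gyromagnetic ratio, rad/(s T); default the 31P value.
#' @param delta_small Gradient pulse width delta, s.
#' @param delta_big Diffusion delay Delta, s; must exceed `delta_small / 3`.
#' @param temperature Temperature, K (metadata).
#' @return An object of class `dosy_dataset`.
#' @export
dosy_dataset <- function(gradients, intensities, gamma = GAMMA_31P,
                         delta_small, delta_big, temperature = NA_real_) {
  if (length(gradients) != length(intensities))
    stop_input("gradients and intensities must have the same length")
  if (any(gradients < 0) || any(diff(gradients) <= 0))
    stop_input("gradients must be non-negative and strictly increasing")
  if (any(!is.finite(intensities)) || any(intensities <= 0))
    stop_input("intensities must all be positive")
  check_scalar(gamma, "gamma", positive = TRUE)
  check_scalar(delta_small, "delta_small", positive = TRUE)
  check_scalar(delta_big, "delta_big", positive = TRUE)
  if (delta_big <= delta_small / 3)
    stop_input("delta_big must exceed delta_small / 3")
  structure(list(gradients = gradients, intensities = intensities,
                 gamma = gamma, delta_small = delta_small,
                 delta_big = delta_big, temperature = temperature),
            class = "dosy_dataset")
}

#' @export
print.dosy_dataset <- function(x, ...) {
  cat(sprintf(
    "DOSY dataset: %d gradients in [%.3g, %.3g] T/m, delta = %g s, Delta = %g s, T = %g K\n",
    length(x$gradients), min(x$gradients), max(x$gradients),
    x$delta_small, x$delta_big, x$temperature))
  invisible(x)
}

#' Stejskal-Tanner attenuation
#'
#' \eqn{\psi(g, D) = \exp(-D g^2 \gamma^2 \delta^2 (\Delta - \delta/3))}.
#'
#' @param g Gradient strength, T/m (vectorized).
#' @param D Diffusion coefficient, m^2/s.
#' @param gamma Gyromagnetic ratio, rad/(s T).
#' @param delta_small Gradient pulse width, s.
#' @param delta_big Diffusion delay, s (> `delta_small / 3`).
#' @return Attenuation fraction in (0, 1].
#' @export
st_attenuation <- function(g, D, gamma = GAMMA_31P, delta_small, delta_big) {
  if (any(g < 0) || D < 0 || gamma < 0)
    stop_input("g, D and gamma must be non-negative")
  if (delta_big <= delta_small / 3)
    stop_input("delta_big must exceed delta_small / 3")
  exp(-D * g^2 * gamma^2 * delta_small^2 * (delta_big - delta_small / 3))
}

#' Fit a diffusion coefficient to PFG attenuation data
#'
#' Ordinary least squares of `ln(psi)` against `g^2` (intensities are
#' normalized to the first point internally);
#' `D = -slope / (gamma^2 delta^2 (Delta - delta/3))`. The coefficient of
#' determination of the line is returned as a single-component diagnostic:
#' below `r2_threshold` a warning flags a multi-component or
#' convection-affected decay.
#'
#' @param ds A [dosy_dataset()] with at least 3 points.
#' @param r2_threshold Linearity threshold for the single-component claim.
#' @return List with `D` (m^2/s), `r2_linearity`, `slope`, and `single_component`.
#' @export
fit_diffusion <- function(ds, r2_threshold = 0.99) {
  stopifnot(inherits(ds, "dosy_dataset"))
  if (length(ds$gradients) < 3L)
    stop_input("fit_diffusion: need at least 3 gradient points")
  psi <- ds$intensities / ds$intensities[1]
  x <- ds$gradients^2
  y <- log(psi)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  b <- ds$gamma^2 * ds$delta_small^2 * (ds$delta_big - ds$delta_small / 3)
  single <- r2 >= r2_threshold
  if (!single)
    warning(sprintf(paste0("fit_diffusion: log-attenuation linearity r^2 = ",
                           "%.4f < %.2f; multi-component or convection ",
                           "suspected"), r2, r2_threshold), call. = FALSE)
  list(D = -slope / b, r2_linearity = r2, slope = slope,
       single_component = single)
}

#' Design a linearly spaced gradient schedule
#'
#' Returns `n` linearly spaced gradient strengths from `g_max / n` up to the
#' `g_max` at which the Stejskal-Tanner attenuation of a species with
#' diffusion coefficient `D_expected` is 0.049, so the final point falls
#' below 5% of the first.
#'
#' @param D_expected Expected diffusion coefficient, m^2/s (> 0).
#' @param n Number of gradients (>= 4).
#' @inheritParams st_attenuation
#' @return Strictly increasing numeric vector of length `n`, T/m.
#' @export
design_gradients <- function(D_expected, n = 16, gamma = GAMMA_31P,
                             delta_small, delta_big) {
  check_scalar(D_expected, "D_expected", positive = TRUE)
  if (!is.numeric(n) || n < 4) stop_input("n must be >= 4")
  b <- gamma^2 * delta_small^2 * (delta_big - delta_small / 3)
  if (b <= 0) stop_input("invalid pulse timings")
  g_max <- sqrt(-log(0.049) / (D_expected * b))
  seq(g_max / n, g_max, length.out = n)
}
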