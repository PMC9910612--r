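## Thermodynamic and kinetic parameterization of the two-state
## monomer <-> assembly (A <-> B) exchange, and the fast-exchange
## relaxation relations used to interpret observed R2.

#' Thermodynamic-kinetic exchange parameters
#'
#' Container for the four parameters that govern the temperature dependence
#' of the monomer-assembly exchange: the enthalpy `dH` and entropy `dS` of
#' assembly (defining the free energy \eqn{\Delta G(T) = \Delta H - T \Delta S}
#' and hence the dark-pool population), and the Arrhenius prefactor `k0` and
#' activation energy `Ea` of the forward rate. `dH` and `dS` are treated as
#' temperature independent.
#'
#' @param dH Enthalpy of assembly, J/mol.
#' @param dS Entropy of assembly, J/(mol K).
#' @param k0 Arrhenius prefactor of the forward rate, 1/s. Must be positive.
#' @param Ea Activation energy of the forward rate, J/mol. Must be
#'   non-negative.
#' @return An object of class `thermo_params`.
#' @examples
#' tp <- thermo_params(dH = 25e3, dS = 30, k0 = 2e4, Ea = 10e3)
#' dark_population(tp, 293)
#' @export
thermo_params <- function(dH, dS, k0, Ea) {
  check_scalar(dH, "dH")
  check_scalar(dS, "dS")
  check_scalar(k0, "k0", positive = TRUE)
  check_scalar(Ea, "Ea", nonneg = TRUE)
  structure(list(dH = dH, dS = dS, k0 = k0, Ea = Ea, R_gas = R_GAS),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat("Two-state exchange parameters\n")
  cat(sprintf("  dH = %g kJ/mol, dS = %g J/(mol K)\n", x$dH / 1e3, x$dS))
  cat(sprintf("  k0 = %g 1/s, Ea = %g kJ/mol\n", x$k0, x$Ea / 1e3))
  invisible(x)
}

check_temperature <- function(T) {
  if (!is.numeric(T) || any(!is.finite(T)) || any(T <= 0))
    stop_input("temperature must be > 0 K")
  T
}

#' Free energy of assembly
#'
#' \eqn{\Delta G(T) = \Delta H - T \Delta S}, linear in temperature.
#'
#' @param params A [thermo_params()] object.
#' @param T Temperature, K (vectorized).
#' @return Free energy of assembly, J/mol.
#' @export
gibbs_free_energy <- function(params, T) {
  stopifnot(inherits(params, "thermo_params"))
  check_temperature(T)
  params$dH - T * params$dS
}

#' Dark-pool equilibrium fraction
#'
#' Two-state Boltzmann population of the assembled (dark) pool,
#' \eqn{p_B = e^{-\Delta G/RT} / (1 + e^{-\Delta G/RT})}. Evaluated through
#' `plogis` so that large \eqn{|\Delta G/RT|} saturates at 0 or 1 rather
#' than overflowing.
#'
#' @inheritParams gibbs_free_energy
#' @return Fraction in (0, 1) (vectorized over `T`).
#' @export
dark_population <- function(params, T) {
  dG <- gibbs_free_energy(params, T)
  stats::plogis(-dG / (R_GAS * T))
}

#' Forward exchange rate (Arrhenius)
#'
#' \eqn{k_f(T) = k_0 \exp(-E_a / RT)}. The exponent is negative: a thermally
#' activated forward rate bounded above by the prefactor, increasing with
#' temperature. With the fitted parameters of the phosphate-assembly model
#' (k0 = 20,000 1/s, Ea = 10 kJ/mol) this spans roughly 350 to 660 1/s over
#' 298-353 K.
#'
#' @inheritParams gibbs_free_energy
#' @return Forward rate A -> B, 1/s (vectorized over `T`).
#' @export
forward_rate <- function(params, T) {
  stopifnot(inherits(params, "thermo_params"))
  check_temperature(T)
  params$k0 * exp(-params$Ea / (R_GAS * T))
}

#' Backward exchange rate from detailed balance
#'
#' In steady state \eqn{k_b = k_f (1 - p_B) / p_B}, so that
#' \eqn{k_f (1 - p_B) = k_b p_B}.
#'
#' @param kf Forward rate, 1/s (non-negative).
#' @param pB Dark-pool fraction, strictly inside (0, 1).
#' @return Backward rate B -> A, 1/s.
#' @export
backward_rate <- function(kf, pB) {
  if (any(!is.finite(pB)) || any(pB <= 0) || any(pB >= 1)) {
    if (any(pB == 0))
      stop_input("backward_rate: dark-pool fraction pB is zero; ",
                 "the backward rate is undefined for an empty pool")
    stop_input("backward_rate: pB must lie strictly inside (0, 1)")
  }
  if (any(kf < 0)) stop_input("backward_rate: kf must be >= 0")
  kf * (1 - pB) / pB
}

#' Exchange state at a temperature
#'
#' Evaluates population and rates of the two-state exchange at temperature
#' `T`: `pB`, `kf`, and the detailed-balance `kb`.
#'
#' @inheritParams gibbs_free_energy
#' @return A list with elements `T`, `pB`, `kf`, `kb`.
#' @export
exchange_state <- function(params, T) {
  pB <- dark_population(params, T)
  kf <- forward_rate(params, T)
  list(T = T, pB = pB, kf = kf, kb = backward_rate(kf, pB))
}

#' Observed transverse rate in the fast-exchange limit
#'
#' For exchange much faster than the relaxation contrast it averages, the
#' observed rate is the population-weighted mean
#' \eqn{R_2 = R_2^A + p_B (R_2^B - R_2^A)}; with a dilute dark pool this is
#' the familiar \eqn{R_2 \approx R_2^A + p_B \Delta R_2}.
#'
#' @param R2A,R2B Transverse relaxation rates of the visible (A) and dark
#'   (B) pools, 1/s.
#' @param pB Dark-pool fraction in \[0, 1\].
#' @return Observed R2, 1/s.
#' @export
fast_exchange_r2 <- function(R2A, R2B, pB) {
  if (any(R2A < 0) || any(R2B < 0)) stop_input("relaxation rates must be >= 0")
  if (any(pB < 0) || any(pB > 1)) stop_input("pB must lie in [0, 1]")
  if (any(R2B < R2A))
    warning("fast_exchange_r2: R2B < R2A gives a negative relaxation ",
            "contrast (outside the dark-assembly regime)", call. = FALSE)
  R2A + pB * (R2B - R2A)
}

#' Dark-pool R2 implied by an observed fast-exchange rate
#'
#' Inverts [fast_exchange_r2()]: given the observed rate, the visible-pool
#' rate and the dark fraction, returns the dark-pool \eqn{R_2^B} such that
#' the fast-exchange expression reproduces the observation.
#'
#' @param R2obs Observed transverse rate, 1/s; must exceed `R2A`.
#' @param R2A Visible-pool transverse rate, 1/s.
#' @param pB Dark-pool fraction, strictly inside (0, 1).
#' @return Dark-pool R2, 1/s.
#' @export
invert_dark_r2 <- function(R2obs, R2A, pB) {
  if (any(pB <= 0) || any(pB >= 1))
    stop_input("invert_dark_r2: pB must lie strictly inside (0, 1)")
  if (any(R2obs <= R2A))
    stop_input("invert_dark_r2: R2obs <= R2A; no positive relaxation ",
               "contrast (Delta R2) solves the fast-exchange relation")
  R2A + (R2obs - R2A) / pB
}

#' Fast-exchange regime ratio
#'
#' The ratio \eqn{k_f / (p_B \Delta R_2)} that must be large for the
#' fast-exchange averaging to hold. [is_fast_regime()] applies the
#' one-order-of-magnitude convention (ratio >= 10).
#'
#' @param kf Forward rate, 1/s.
#' @param pB Dark-pool fraction.
#' @param dR2 Relaxation contrast \eqn{R_2^B - R_2^A}, 1/s.
#' @return Dimensionless ratio.
#' @export
exchange_regime_ratio <- function(kf, pB, dR2) {
  if (any(pB * dR2 <= 0))
    stop_input("exchange_regime_ratio: pB * dR2 must be > 0")
  kf / (pB * dR2)
}

#' @rdname exchange_regime_ratio
#' @export
is_fast_regime <- function(kf, pB, dR2) {
  exchange_regime_ratio(kf, pB, dR2) >= 10
}
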