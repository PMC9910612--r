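## Physical constants used throughout; fixed values, not user-configurable.

#' Physical constants
#'
#' Constants used by the package: the molar gas constant `R_GAS`
#' (8.314 J/(mol K)), the Boltzmann constant `K_BOLTZMANN`
#' (1.380649e-23 J/K), and the \eqn{^{31}}P gyromagnetic ratio
#' `GAMMA_31P` (1.08394e8 rad/(s T), overridable where it is an argument).
#'
#' @name constants
#' @keywords internal
NULL

R_GAS <- 8.314
K_BOLTZMANN <- 1.380649e-23
GAMMA_31P <- 1.08394e8

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_input(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0)
    stop_input(sprintf("'%s' must be > 0 (got %g)", name, x))
  if (nonneg && x < 0)
    stop_input(sprintf("'%s' must be >= 0 (got %g)", name, x))
  invisible(x)
}
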