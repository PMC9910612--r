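## Two-pool Bloch-McConnell simulator: continuous-wave saturation,
## Z-spectra, dip-width measurement, and observed relaxation rates under
## exchange. Pool A is the visible species (monomers), pool B the
## spectroscopically dark assemblies. Internally angular units (rad/s);
## every interface is in Hz.

#' Two-pool spin system
#'
#' Relaxation, offsets, population and exchange rates defining one
#' Bloch-McConnell condition. Equilibrium longitudinal magnetizations are
#' `(1 - pB, pB)` in normalized units. If `kb` is omitted it is filled in
#' from detailed balance, `kb = kf (1 - pB) / pB`.
#'
#' @param R1A,R2A,R1B,R2B Longitudinal/transverse relaxation rates of the
#'   visible (A) and dark (B) pools, 1/s. All must be >= 0.
#' @param pB Dark-pool fraction in \[0, 1\].
#' @param kf,kb Forward (A -> B) and backward (B -> A) exchange rates, 1/s.
#'   Must satisfy detailed balance `kf (1 - pB) = kb pB` to 1e-9 relative.
#' @param offsetA,offsetB Chemical-shift offsets of each pool from the
#'   carrier, Hz. Both default to 0 (the shared-shift case: the dark species
#'   resonate at, or so broadly around, the monomer shift that a single
#'   symmetric dip results).
#' @return An object of class `spin_system`.
#' @examples
#' sys <- spin_system(R1A = 0.3, R2A = 0.3, R1B = 0.3, R2B = 450,
#'                    pB = 0.0013, kf = 350)
#' observed_rates(sys)
#' @export
spin_system <- function(R1A, R2A, R1B, R2B, pB, kf, kb = NULL,
                        offsetA = 0, offsetB = 0) {
  for (nm in c("R1A", "R2A", "R1B", "R2B"))
    check_scalar(get(nm), nm, nonneg = TRUE)
  check_scalar(pB, "pB")
  if (pB < 0 || pB > 1) stop_input("pB must lie in [0, 1]")
  check_scalar(kf, "kf", nonneg = TRUE)
  check_scalar(offsetA, "offsetA")
  check_scalar(offsetB, "offsetB")
  if (is.null(kb)) {
    kb <- if (kf == 0) 0 else backward_rate(kf, pB)
  }
  check_scalar(kb, "kb", nonneg = TRUE)
  flux_in <- kf * (1 - pB)
  flux_out <- kb * pB
  scale <- max(abs(flux_in), abs(flux_out))
  if (scale > 0 && abs(flux_in - flux_out) > 1e-9 * scale)
    stop_input("spin_system: kf, kb and pB violate detailed balance ",
               sprintf("(kf (1-pB) = %g but kb pB = %g)", flux_in, flux_out))
  structure(list(R1A = R1A, R2A = R2A, R1B = R1B, R2B = R2B,
                 offsetA = offsetA, offsetB = offsetB,
                 pB = pB, kf = kf, kb = kb),
            class = "spin_system")
}

#' @export
print.spin_system <- function(x, ...) {
  cat("Two-pool spin system\n")
  cat(sprintf("  pool A: R1 = %g, R2 = %g 1/s, offset = %g Hz\n",
              x$R1A, x$R2A, x$offsetA))
  cat(sprintf("  pool B: R1 = %g, R2 = %g 1/s, offset = %g Hz\n",
              x$R1B, x$R2B, x$offsetB))
  cat(sprintf("  pB = %g, kf = %g 1/s, kb = %g 1/s\n", x$pB, x$kf, x$kb))
  invisible(x)
}

#' Spin system implied by the exchange model at a temperature
#'
#' Convenience constructor tying the thermodynamic module to the simulator:
#' populations and rates come from [exchange_state()], the visible-pool
#' R2 is set equal to its R1 (fast-motion small molecule) and the dark-pool
#' R1 defaults to the visible-pool R1 (the fit is insensitive to it over
#' 0.1x-10x).
#'
#' @param params A [thermo_params()] object.
#' @param T Temperature, K.
#' @param R1A Visible-pool longitudinal rate at `T`, 1/s.
#' @param R2B Dark-pool transverse rate at `T`, 1/s.
#' @param R2A Visible-pool transverse rate; default `R1A`.
#' @param R1B Dark-pool longitudinal rate; default `R1A`.
#' @param offsetA,offsetB Offsets from carrier, Hz.
#' @return A [spin_system()].
#' @export
spin_system_at <- function(params, T, R1A, R2B, R2A = R1A, R1B = R1A,
                           offsetA = 0, offsetB = 0) {
  st <- exchange_state(params, T)
  spin_system(R1A = R1A, R2A = R2A, R1B = R1B, R2B = R2B,
              pB = st$pB, kf = st$kf, kb = st$kb,
              offsetA = offsetA, offsetB = offsetB)
}

#' Continuous-wave saturation scheme
#'
#' @param nutation RF nutation frequency \eqn{\nu_1 = \gamma B_1 / 2\pi}, Hz
#'   (>= 0).
#' @param duration Saturation time, s (> 0).
#' @param offsets Saturation frequency offsets, Hz, strictly increasing.
#' @return An object of class `saturation_scheme`.
#' @export
saturation_scheme <- function(nutation, duration,
                              offsets = seq(-4000, 4000, by = 200)) {
  check_scalar(nutation, "nutation", nonneg = TRUE)
  check_scalar(duration, "duration", positive = TRUE)
  if (!is.numeric(offsets) || length(offsets) < 2L || any(diff(offsets) <= 0))
    stop_input("offsets must be a strictly increasing numeric vector")
  structure(list(nutation = nutation, duration = duration, offsets = offsets),
            class = "saturation_scheme")
}

#' Z-spectrum container
#'
#' A saturation-offset grid with the normalized detected longitudinal
#' magnetization of the visible pool, plus acquisition metadata.
#'
#' @param offsets Saturation offsets, Hz, strictly increasing.
#' @param z Normalized intensities (same length as `offsets`).
#' @param temperature Sample temperature, K (may be `NA`).
#' @param nutation RF nutation frequency, Hz.
#' @param duration Saturation duration, s.
#' @return An object of class `zspectrum` (a data frame with columns
#'   `offset_hz`, `z` and metadata attributes).
#' @export
zspectrum <- function(offsets, z, temperature = NA_real_, nutation = NA_real_,
                      duration = NA_real_) {
  if (length(offsets) != length(z))
    stop_input("offsets and z must have the same length")
  if (any(diff(offsets) <= 0))
    stop_input("offsets must be strictly increasing")
  if (any(!is.finite(z))) stop_input("z values must all be finite")
  structure(data.frame(offset_hz = offsets, z = z),
            temperature_K = temperature, nutation_hz = nutation,
            duration_s = duration,
            class = c("zspectrum", "data.frame"))
}

#' @export
print.zspectrum <- function(x, ...) {
  cat(sprintf(
    "Z-spectrum: %d offsets in [%g, %g] Hz, nutation %g Hz, %g s, T = %g K\n",
    nrow(x), min(x$offset_hz), max(x$offset_hz),
    attr(x, "nutation_hz"), attr(x, "duration_s"), attr(x, "temperature_K")))
  cat(sprintf("  min z = %.4g at %g Hz\n",
              min(x$z), x$offset_hz[which.min(x$z)]))
  invisible(x)
}

#' Bloch-McConnell evolution operator
#'
#' Constant-coefficient generator of the augmented 7-state system
#' `(MxA, MyA, MzA, MxB, MyB, MzB, 1)` under continuous-wave irradiation:
#' rotating-frame precession at `2 pi (offset_pool - sat_offset)`, RF
#' coupling `omega1 = 2 pi nutation` between the y and z components,
#' relaxation on the diagonal, first-order exchange coupling between
#' corresponding components of the two pools, and `R1 Meq` recovery through
#' the constant-augmentation column.
#'
#' @param sys A [spin_system()].
#' @param sat_offset Saturation frequency offset from the carrier, Hz.
#' @param nutation RF nutation frequency, Hz.
#' @return A 7 x 7 numeric matrix `L` such that `dM/dt = L M`.
#' @export
bm_generator <- function(sys, sat_offset, nutation) {
  stopifnot(inherits(sys, "spin_system"))
  w1 <- 2 * pi * nutation
  dA <- 2 * pi * (sys$offsetA - sat_offset)
  dB <- 2 * pi * (sys$offsetB - sat_offset)
  meqA <- 1 - sys$pB
  meqB <- sys$pB
  L <- matrix(0, 7, 7)
  ## pool A block (x, y, z) = rows/cols 1:3
  L[1, 1] <- -sys$R2A; L[1, 2] <- dA
  L[2, 1] <- -dA;      L[2, 2] <- -sys$R2A; L[2, 3] <- w1
  L[3, 2] <- -w1;      L[3, 3] <- -sys$R1A; L[3, 7] <- sys$R1A * meqA
  ## pool B block = rows/cols 4:6
  L[4, 4] <- -sys$R2B; L[4, 5] <- dB
  L[5, 4] <- -dB;      L[5, 5] <- -sys$R2B; L[5, 6] <- w1
  L[6, 5] <- -w1;      L[6, 6] <- -sys$R1B; L[6, 7] <- sys$R1B * meqB
  ## exchange couples corresponding components
  for (i in 1:3) {
    j <- i + 3L
    L[i, i] <- L[i, i] - sys$kf
    L[i, j] <- L[i, j] + sys$kb
    L[j, j] <- L[j, j] - sys$kb
    L[j, i] <- L[j, i] + sys$kf
  }
  L
}

#' Equilibrium state vector of a spin system
#'
#' @param sys A [spin_system()].
#' @return Numeric length-7 state `(0, 0, 1 - pB, 0, 0, pB, 1)`.
#' @export
bm_equilibrium <- function(sys) {
  c(0, 0, 1 - sys$pB, 0, 0, sys$pB, 1)
}

## Exact action of exp(L t) on M0: compiled scaling-and-squaring Pade
## (order 13), with Ward-balanced Pade via Matrix::expm as the pure-R
## fallback should the compiled routine ever refuse (singular denominator).
expm_action <- function(L, t, M0) {
  out <- tryCatch(.Call(C_expm_action, L, as.numeric(t), as.numeric(M0)),
                  error = function(err) NULL)
  if (!is.null(out)) return(out)
  as.vector(as.matrix(Matrix::expm(Matrix::Matrix(L * t))) %*% M0)
}

#' Propagate magnetization under constant irradiation
#'
#' Exact solution of the linear constant-coefficient Bloch-McConnell system
#' through the exponential of the augmented generator (evaluated spectrally
#' when the generator is diagonalizable, by Pade approximation otherwise);
#' no time stepping is involved.
#'
#' @inheritParams bm_generator
#' @param t Evolution time, s (>= 0).
#' @param M0 Initial 7-state vector; defaults to thermal equilibrium.
#' @return The state after time `t`.
#' @export
bm_propagate <- function(sys, sat_offset, nutation, t, M0 = bm_equilibrium(sys)) {
  check_scalar(t, "t", nonneg = TRUE)
  if (length(M0) != 7L) stop_input("M0 must be a length-7 state vector")
  if (t == 0) return(M0)
  L <- bm_generator(sys, sat_offset, nutation)
  expm_action(L, t, M0)
}

#' Steady-state saturation of an isolated pool (closed form)
#'
#' No-exchange oracle: the steady-state longitudinal magnetization of a
#' single pool under continuous-wave irradiation,
#' \eqn{z = R_1 (R_2^2 + \Delta^2) / (R_1 (R_2^2 + \Delta^2) + \omega_1^2 R_2)}
#' with \eqn{\Delta = 2\pi\,\mathrm{delta}}, \eqn{\omega_1 = 2\pi\,\nu_1}.
#'
#' @param R1,R2 Relaxation rates, 1/s (> 0).
#' @param nutation RF nutation frequency, Hz.
#' @param delta Offset of the irradiation from the pool resonance, Hz.
#' @return Normalized steady-state z in (0, 1\] (vectorized over `delta`).
#' @export
steady_state_z_single_pool <- function(R1, R2, nutation, delta) {
  check_scalar(R1, "R1", positive = TRUE)
  check_scalar(R2, "R2", positive = TRUE)
  w1 <- 2 * pi * nutation
  d <- 2 * pi * delta
  R1 * (R2^2 + d^2) / (R1 * (R2^2 + d^2) + w1^2 * R2)
}

#' Simulate a CEST/DEST Z-spectrum
#'
#' For each saturation offset, evolves the system from thermal equilibrium
#' for the saturation duration and records the visible-pool longitudinal
#' magnetization normalized to its equilibrium value (the dark pool is
#' spectroscopically silent and contributes nothing to the readout).
#'
#' @param sys A [spin_system()].
#' @param scheme A [saturation_scheme()].
#' @param temperature Temperature metadata to attach, K.
#' @return A [zspectrum()].
#' @export
simulate_z_spectrum <- function(sys, scheme, temperature = NA_real_) {
  stopifnot(inherits(scheme, "saturation_scheme"))
  meqA <- 1 - sys$pB
  if (meqA <= 0) stop_input("visible pool is empty (pB = 1)")
  one_z <- function(off)
    .Call(C_cw_zvalues,
          as.numeric(c(sys$R1A, sys$R2A, sys$R1B, sys$R2B,
                       sys$offsetA, sys$offsetB, sys$pB, sys$kf, sys$kb)),
          as.numeric(off), as.numeric(scheme$nutation),
          as.numeric(scheme$duration))
  off <- scheme$offsets
  symmetric <- sys$offsetA == 0 && sys$offsetB == 0 &&
    isTRUE(all.equal(rev(off), -off, tolerance = 1e-12))
  if (symmetric) {
    ## z(+offset) = z(-offset) exactly for a shared on-carrier shift:
    ## compute one half of the grid and mirror
    pos <- off[off >= 0]
    zp <- one_z(pos)
    z <- c(rev(zp[pos > 0]), zp)
  } else {
    z <- one_z(off)
  }
  zspectrum(scheme$offsets, z, temperature = temperature,
            nutation = scheme$nutation, duration = scheme$duration)
}

#' Full width at half depth of a Z-spectrum dip
#'
#' The baseline is the mean of the two extreme-offset z values; the width is
#' measured at the level halfway between the baseline and the minimum, with
#' the two crossings located by linear interpolation between grid points.
#'
#' @param zs A [zspectrum()] with a single minimum interior to the scan.
#' @return Width, Hz.
#' @export
dip_width <- function(zs) {
  stopifnot(inherits(zs, "zspectrum"))
  off <- zs$offset_hz
  z <- zs$z
  n <- length(z)
  imin <- which.min(z)
  if (imin == 1L || imin == n)
    stop_input("dip_width: dip not resolved within scan window ",
               "(minimum at a boundary offset)")
  baseline <- mean(c(z[1], z[n]))
  level <- (baseline + z[imin]) / 2
  cross <- function(i0, i1) {
    ## linear interpolation of the offset where z crosses `level`
    off[i0] + (level - z[i0]) * (off[i1] - off[i0]) / (z[i1] - z[i0])
  }
  il <- imin
  while (il > 1L && z[il] < level) il <- il - 1L
  if (z[il] < level)
    stop_input("dip_width: dip not resolved within scan window ",
               "(no left half-depth crossing)")
  ir <- imin
  while (ir < n && z[ir] < level) ir <- ir + 1L
  if (z[ir] < level)
    stop_input("dip_width: dip not resolved within scan window ",
               "(no right half-depth crossing)")
  cross(ir - 1L, ir) - cross(il, il + 1L)
}

## Slow-decaying transverse rate of the 2x2 exchange operator
## [[-R2A-kf, kb], [kf, -R2B-kb]], in a cancellation-free form:
## the eigenvalue product is R2A*R2B + R2A*kb + kf*R2B (expanded, all
## positive) and the sum is R2A + kf + R2B + kb.
slow_transverse_rate <- function(R2A, R2B, kf, kb) {
  s <- R2A + kf + R2B + kb
  disc <- sqrt(((R2B + kb - R2A - kf) / 2)^2 + kf * kb)
  fast <- s / 2 + disc
  (R2A * R2B + R2A * kb + kf * R2B) / fast
}

## Inverse of slow_transverse_rate in R2B: the dark-pool rate that makes the
## slow transverse eigenvalue equal R2obs, given kf, kb. Requires
## R2obs < R2A + kf.
invert_slow_transverse <- function(R2obs, R2A, kf, kb) {
  w <- R2A + kf - R2obs
  if (any(w <= 0))
    stop_input("invert_slow_transverse: R2obs >= R2A + kf has no solution")
  (R2obs * (R2A + kf + kb - R2obs) - R2A * kb) / w
}

#' Observed relaxation rates under exchange
#'
#' Eigen-analysis of the 2 x 2 transverse and longitudinal exchange
#' operators for the shared-shift case (`offsetA == offsetB`). The observed
#' rate is the decay rate of the eigenmode carrying the largest
#' visible-pool amplitude when started from the equilibrium-weighted
#' vector `(1 - pB, pB)`. In the limit `kf -> Inf` the transverse rate
#' tends to the population-weighted mean `(1 - pB) R2A + pB R2B`.
#'
#' @param sys A [spin_system()] with `offsetA == offsetB`.
#' @return Named numeric vector `c(R1obs = ..., R2obs = ...)`, 1/s.
#' @export
observed_rates <- function(sys) {
  stopifnot(inherits(sys, "spin_system"))
  if (sys$offsetA != sys$offsetB)
    stop_input("observed_rates: defined for the shared-shift case only ",
               "(offsetA == offsetB)")
  m0 <- c(1 - sys$pB, sys$pB)
  one_rate <- function(RA, RB) {
    A <- matrix(c(-RA - sys$kf, sys$kf, sys$kb, -RB - sys$kb), 2, 2)
    e <- eigen(A)
    co <- solve(e$vectors, m0)
    amp <- abs(co * e$vectors[1, ])   # visible-pool amplitude per mode
    -Re(e$values[which.max(amp)])
  }
  c(R1obs = one_rate(sys$R1A, sys$R1B), R2obs = one_rate(sys$R2A, sys$R2B))
}
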