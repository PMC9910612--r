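sys_paper <- function(T = 298) {
  truth <- paper_truth()
  spin_system_at(truth$thermo, T, R1A = r1a_at(truth, T),
                 R2B = r2b_at(truth, T))
}

no_exchange_sys <- function(r1 = 0.3, r2 = r1) {
  spin_system(R1A = r1, R2A = r2, R1B = r1, R2B = r2, pB = 0, kf = 0, kb = 0)
}

test_that("generator has the expected block and coupling structure", {
  sys <- no_exchange_sys(0.5, 1.2)
  L <- bm_generator(sys, 100, 0)
  # nutation 0, no exchange: Mz rows decouple from the transverse block
  expect_equal(L[3, c(1, 2, 4, 5)], rep(0, 4))
  expect_equal(L[c(1, 2), 3], c(0, 0))
  # no exchange: all A<->B coupling entries vanish
  expect_equal(L[1:3, 4:6], matrix(0, 3, 3))
  expect_equal(L[4:6, 1:3], matrix(0, 3, 3))
  # pure exchange conserves magnetization: column sums of the 6x6
  # magnetization block vanish when relaxation and rf are off
  sysx <- spin_system(R1A = 0, R2A = 0, R1B = 0, R2B = 0,
                      pB = 0.2, kf = 100, offsetA = 0, offsetB = 0)
  Lx <- bm_generator(sysx, 0, 0)
  expect_equal(colSums(Lx[1:6, 1:6]), rep(0, 6))
})

test_that("propagation is exact: identity at t = 0 and closed-form recovery", {
  sys <- sys_paper()
  M0 <- c(0.1, -0.2, 0.5, 0.01, 0, 0.001, 1)
  expect_identical(bm_propagate(sys, 100, 50, 0, M0), M0)
  # nutation 0, no exchange: mono-exponential longitudinal recovery
  sys0 <- no_exchange_sys(0.7)
  M <- bm_equilibrium(sys0)
  M[3] <- 0.2
  for (t in c(0.3, 1, 4)) {
    out <- bm_propagate(sys0, 500, 0, t, M)
    expect_rel_equal(out[3], 1 + (0.2 - 1) * exp(-0.7 * t), 1e-9)
  }
})

test_that("matrix-exponential propagation matches the fixed-step integrator", {
  set.seed(7)
  for (i in 1:5) {
    sys <- random_spin_system()
    sat <- runif(1, -2000, 2000)
    nut <- runif(1, 0, 150)
    t <- 0.05
    exact <- bm_propagate(sys, sat, nut, t)
    L <- bm_generator(sys, sat, nut)
    ref <- rk4_propagate(L, t, bm_equilibrium(sys), dt = 2e-6)
    expect_rel_equal(exact[1:6] + 1, ref[1:6] + 1, 1e-6)
  }
})

test_that("single-pool steady state matches its closed form", {
  expect_equal(steady_state_z_single_pool(0.5, 0.5, 0, 123), 1)
  expect_rel_equal(steady_state_z_single_pool(0.5, 0.5, 150, 0), 2.8e-7, 0.01)
  # half-depth offset ~ nutation when R1 = R2 << omega1: FWHM ~ 2 nu1
  z_at_nu <- steady_state_z_single_pool(0.5, 0.5, 150, 150)
  expect_equal(z_at_nu, 0.5, tolerance = 1e-4)
})

test_that("simulated Z-spectrum agrees with the closed-form steady state", {
  sys <- no_exchange_sys(0.5)
  sch <- saturation_scheme(150, 60, seq(-1200, 1200, by = 40))
  zs <- simulate_z_spectrum(sys, sch)
  expect_equal(zs$z, steady_state_z_single_pool(0.5, 0.5, 150, sch$offsets),
               tolerance = 1e-4)
})

test_that("Z-spectrum is symmetric for a shared on-carrier shift", {
  sys <- sys_paper()
  # deliberately non-symmetric grid so every offset is simulated directly
  off <- sort(c(seq(-800, 800, by = 80), 123))
  zs <- simulate_z_spectrum(sys, saturation_scheme(150, 5, off))
  pos <- seq(80, 800, by = 80)
  zl <- zs$z[match(-pos, zs$offset_hz)]
  zr <- zs$z[match(pos, zs$offset_hz)]
  expect_equal(zl, zr, tolerance = 1e-10)
})

test_that("exchange broadens the dip beyond the no-exchange width", {
  sys <- sys_paper(298)
  sch <- saturation_scheme(150, 5)
  w_ex <- dip_width(simulate_z_spectrum(sys, sch))
  w_off <- dip_width(simulate_z_spectrum(
    no_exchange_sys(sys$R1A, sys$R2A), sch))
  expect_gt(w_ex, w_off)
})

test_that("dip width: geometric construction, boundary error, grid stability", {
  # triangle dip of known half-height width
  off <- seq(-500, 500, by = 10)
  z <- pmax(1 - pmax(0, 1 - abs(off) / 200), 0.0)
  z <- 1 - pmax(0, 1 - abs(off) / 200) * 0.8  # depth 0.8, FWHM 200
  zs <- zspectrum(off, z)
  expect_equal(dip_width(zs), 200)
  # minimum at a boundary offset is rejected
  zedge <- zspectrum(off, seq(0.2, 1, length.out = length(off)))
  expect_error(dip_width(zedge), "not resolved")
  # refinement invariance on the no-exchange case
  sys <- no_exchange_sys(0.5)
  w <- vapply(c(10, 5), function(step) {
    sch <- saturation_scheme(150, 60, c(-4000, seq(-700, 700, by = step), 4000))
    dip_width(simulate_z_spectrum(sys, sch))
  }, numeric(1))
  expect_lt(abs(diff(w)) / w[1], 0.01)
})

test_that("dip width is non-decreasing in pB and in R2B at the study scale", {
  truth <- paper_truth()
  sch <- saturation_scheme(150, 5)
  base <- exchange_state(truth$thermo, 313)
  w_pb <- vapply(c(0.001, 0.003, 0.006), function(pb) {
    sys <- spin_system(R1A = 0.3, R2A = 0.3, R1B = 0.3, R2B = 600,
                       pB = pb, kf = base$kf)
    dip_width(simulate_z_spectrum(sys, sch))
  }, numeric(1))
  expect_true(all(diff(w_pb) >= 0))
  w_r2b <- vapply(c(450, 700, 1000), function(r2b) {
    sys <- spin_system(R1A = 0.3, R2A = 0.3, R1B = 0.3, R2B = r2b,
                       pB = base$pB, kf = base$kf)
    dip_width(simulate_z_spectrum(sys, sch))
  }, numeric(1))
  expect_true(all(diff(w_r2b) >= 0))
})

test_that("exchange without relaxation or rf conserves total Mz", {
  sys <- spin_system(R1A = 0, R2A = 0, R1B = 0, R2B = 0,
                     pB = 0.25, kf = 300)
  M0 <- c(0, 0, 0.9, 0, 0, 0.1, 1)  # off-equilibrium split
  for (t in c(0.001, 0.01, 0.1)) {
    M <- bm_propagate(sys, 0, 0, t, M0)
    expect_rel_equal(M[3] + M[6], 1.0, 1e-9)
  }
})

test_that("Z-spectrum values stay within physical bounds", {
  set.seed(11)
  for (i in 1:8) {
    sys <- random_spin_system()
    zs <- simulate_z_spectrum(sys, saturation_scheme(
      runif(1, 10, 150), 5, seq(-4000, 4000, by = 500)))
    expect_true(all(zs$z >= -0.01 & zs$z <= 1.02))
  }
})

test_that("observed rates: limits and eigen-analysis", {
  sys0 <- no_exchange_sys(0.4, 2.5)
  expect_equal(observed_rates(sys0), c(R1obs = 0.4, R2obs = 2.5))
  # fast-exchange limit is the population-weighted mean
  sysf <- spin_system(R1A = 0.3, R2A = 0.3, R1B = 0.3, R2B = 450,
                      pB = 0.0013, kf = 1e6)
  expect_rel_equal(observed_rates(sysf)[["R2obs"]],
                   (1 - 0.0013) * 0.3 + 0.0013 * 450, 1e-3)
  # across the study range the eigenvalue rate is within 5% of the
  # fast-exchange expression whenever the regime ratio exceeds 10
  truth <- paper_truth()
  for (T in seq(293, 353, by = 10)) {
    sys <- sys_paper(T)
    ratio <- exchange_regime_ratio(sys$kf, sys$pB, sys$R2B - sys$R2A)
    expect_gt(ratio, 10)
    r <- observed_rates(sys)[["R2obs"]]
    expect_rel_equal(r, fast_exchange_r2(sys$R2A, sys$R2B, sys$pB), 0.05)
  }
  expect_error(observed_rates(spin_system(
    R1A = 0.3, R2A = 0.3, R1B = 0.3, R2B = 450, pB = 0.1, kf = 10,
    offsetA = 0, offsetB = 500)), "shared-shift")
})
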