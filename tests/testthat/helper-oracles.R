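# Independent oracles and fixture builders used across the suite.

# Fixed-step 4th-order Runge-Kutta integration of dM/dt = L M for a
# constant operator L: the brute-force counterpart of the matrix-exponential
# propagator.
rk4_propagate <- function(L, t, M0, dt = 1e-5) {
  n <- max(1L, ceiling(t / dt))
  h <- t / n
  M <- M0
  for (i in seq_len(n)) {
    k1 <- L %*% M
    k2 <- L %*% (M + h / 2 * k1)
    k3 <- L %*% (M + h / 2 * k2)
    k4 <- L %*% (M + h * k3)
    M <- M + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  as.vector(M)
}

# Random but physically valid two-pool system; rate scales kept moderate so
# the RK4 oracle stays accurate at its step size.
random_spin_system <- function() {
  pB <- runif(1, 1e-4, 0.3)
  kf <- runif(1, 0, 2000)
  spin_system(R1A = runif(1, 0.05, 2), R2A = runif(1, 0.05, 5),
              R1B = runif(1, 0.05, 2), R2B = runif(1, 10, 2000),
              pB = pB, kf = kf,
              offsetA = runif(1, -200, 200), offsetB = runif(1, -200, 200))
}

paper_truth <- function() default_truth()

expect_rel_equal <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol * abs(expected)),
              label = sprintf("%s within %g relative of %s",
                              paste(signif(object, 6), collapse = ","), tol,
                              paste(signif(expected, 6), collapse = ",")))
}
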