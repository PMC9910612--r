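tp_paper <- thermo_params(dH = 25e3, dS = 30, k0 = 2e4, Ea = 10e3)

test_that("free energy of assembly is dH - T dS and validates inputs", {
  expect_equal(gibbs_free_energy(tp_paper, 293), 25000 - 293 * 30)
  expect_equal(gibbs_free_energy(tp_paper, 293), 16210)
  expect_equal(gibbs_free_energy(thermo_params(0, 0, 1, 0), 310), 0)
  expect_equal(gibbs_free_energy(tp_paper, 25000 / 30), 0)
  # linear in T
  Ts <- seq(280, 360, by = 20)
  expect_equal(diff(gibbs_free_energy(tp_paper, Ts)),
               rep(-30 * 20, length(Ts) - 1))
  expect_error(gibbs_free_energy(tp_paper, -1), "temperature")
  expect_error(thermo_params(25e3, 30, -1, 10e3), "k0")
  expect_error(thermo_params(25e3, 30, 2e4, -5), "Ea")
})

test_that("dark-pool fraction reproduces the fitted populations", {
  expect_equal(signif(dark_population(tp_paper, 293), 2), 0.0013)
  expect_equal(signif(dark_population(tp_paper, 353), 2), 0.0073)
  # Delta G = 0 gives the symmetric two-state population
  expect_equal(dark_population(tp_paper, 25000 / 30), 0.5)
})

test_that("dark-pool fraction is overflow-safe and monotone", {
  # enormous |dG/RT| saturates cleanly at the asymptotes
  big <- thermo_params(dH = 5e6, dS = 0, k0 = 1, Ea = 0)
  expect_equal(dark_population(big, 280), 0)
  neg <- thermo_params(dH = -5e6, dS = 0, k0 = 1, Ea = 0)
  expect_equal(dark_population(neg, 280), 1)
  # strictly increasing in T for dH > 0 over [250, 400] K
  Ts <- seq(250, 400, by = 2.5)
  expect_true(all(diff(dark_population(tp_paper, Ts)) > 0))
  # algebraic equivalence with the logistic form 1/(1 + exp(+dG/RT))
  dG <- gibbs_free_energy(tp_paper, Ts)
  expect_equal(dark_population(tp_paper, Ts),
               1 / (1 + exp(dG / (8.314 * Ts))), tolerance = 1e-12)
})

test_that("Arrhenius forward rate matches the fitted 350-660 1/s span", {
  expect_equal(signif(forward_rate(tp_paper, 298), 2), 350)
  expect_equal(signif(forward_rate(tp_paper, 353), 2), 660)
  expect_rel_equal(forward_rate(tp_paper, 298), 354, 0.01)
  expect_rel_equal(forward_rate(tp_paper, 353), 663, 0.01)
  # zero barrier gives the prefactor at any T; rate is bounded by k0
  tp0 <- thermo_params(dH = 25e3, dS = 30, k0 = 2e4, Ea = 0)
  expect_equal(forward_rate(tp0, c(280, 320, 360)), rep(2e4, 3))
  Ts <- seq(260, 400, by = 5)
  kf <- forward_rate(tp_paper, Ts)
  expect_true(all(kf > 0 & kf <= 2e4))
  expect_true(all(diff(kf) > 0))
})

test_that("backward rate enforces detailed balance", {
  expect_rel_equal(backward_rate(354, 0.00153), 2.31e5, 0.01)
  expect_equal(backward_rate(123.4, 0.5), 123.4)
  expect_equal(backward_rate(0, 0.3), 0)
  expect_error(backward_rate(100, 0), "zero")
  expect_error(backward_rate(100, 1), "strictly inside")
  # steady-state invariant kf (1 - pB) = kb pB across the study range
  for (T in seq(293, 353, by = 10)) {
    st <- exchange_state(tp_paper, T)
    expect_rel_equal(st$kf * (1 - st$pB), st$kb * st$pB, 1e-12)
  }
})

test_that("backward rate decreases with temperature for the fitted model", {
  Ts <- seq(293, 353, by = 5)
  sts <- lapply(Ts, exchange_state, params = tp_paper)
  kb <- vapply(sts, `[[`, numeric(1), "kb")
  expect_true(all(diff(kb) < 0))
})

test_that("fast-exchange R2 is the population-weighted mean", {
  expect_rel_equal(fast_exchange_r2(0.3, 450, 0.0013), 0.88461, 1e-4)
  expect_equal(fast_exchange_r2(7.7, 7.7, 0.42), 7.7)
  expect_equal(fast_exchange_r2(0.3, 450, 0), 0.3)
  expect_equal(fast_exchange_r2(0.3, 450, 1), 450)
  expect_warning(fast_exchange_r2(5, 1, 0.1), "negative relaxation contrast")
})

test_that("dark-pool R2 inversion is the exact inverse of the forward relation", {
  expect_rel_equal(invert_dark_r2(0.885, 0.3, 0.0013), 450.3, 1e-3)
  expect_equal(invert_dark_r2(2, 1, 0.5), 3)
  expect_error(invert_dark_r2(0.3, 0.3, 0.1), "no positive")
  expect_error(invert_dark_r2(0.29, 0.3, 0.1), "no positive")
  set.seed(42)
  for (i in 1:50) {
    R2A <- runif(1, 0.01, 5)
    R2B <- runif(1, R2A + 0.1, 2000)
    pB <- runif(1, 1e-4, 0.99)
    R2obs <- fast_exchange_r2(R2A, R2B, pB)
    expect_rel_equal(invert_dark_r2(R2obs, R2A, pB), R2B, 1e-10)
  }
})

test_that("exchange-regime ratio and fast-regime predicate", {
  expect_rel_equal(exchange_regime_ratio(354, 0.0013, 450), 605, 0.01)
  expect_equal(exchange_regime_ratio(6, 0.2, 30), 1)
  expect_equal(exchange_regime_ratio(0, 0.2, 30), 0)
  expect_error(exchange_regime_ratio(10, 0, 30), "must be > 0")
  expect_true(is_fast_regime(354, 0.0013, 450))
  expect_false(is_fast_regime(6, 0.2, 30))
})
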