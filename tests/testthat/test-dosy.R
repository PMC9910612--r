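st_b <- function(gamma = 1.08394e8, ds = 4e-3, db = 0.1)
  gamma^2 * ds^2 * (db - ds / 3)

make_dosy <- function(D, n = 16, noise = 0, ds = 4e-3, db = 0.1) {
  g <- design_gradients(D, n, delta_small = ds, delta_big = db)
  psi <- st_attenuation(g, D, delta_small = ds, delta_big = db)
  if (noise > 0) psi <- psi * (1 + rnorm(length(psi), 0, noise))
  dosy_dataset(g, psi, delta_small = ds, delta_big = db)
}

test_that("Stejskal-Tanner attenuation has its defining limits", {
  expect_equal(st_attenuation(0, 7.5e-10, delta_small = 4e-3, delta_big = 0.1), 1)
  expect_equal(st_attenuation(c(0.1, 0.4), 0, delta_small = 4e-3,
                              delta_big = 0.1), c(1, 1))
  # half-attenuation construction
  D <- 1e-9
  g_half <- sqrt(log(2) / (D * st_b()))
  expect_equal(st_attenuation(g_half, D, delta_small = 4e-3, delta_big = 0.1),
               0.5, tolerance = 1e-12)
  # strictly decreasing in g, D, delta and Delta
  expect_true(all(diff(st_attenuation(seq(0, 0.5, 0.05), D,
    delta_small = 4e-3, delta_big = 0.1)) < 0))
  expect_true(all(diff(vapply(c(1e-10, 1e-9, 5e-9), function(DD)
    st_attenuation(0.2, DD, delta_small = 4e-3, delta_big = 0.1),
    numeric(1))) < 0))
  expect_true(all(diff(vapply(c(2e-3, 4e-3, 8e-3), function(ds)
    st_attenuation(0.2, D, delta_small = ds, delta_big = 0.1),
    numeric(1))) < 0))
  expect_true(all(diff(vapply(c(0.05, 0.1, 0.2), function(db)
    st_attenuation(0.2, D, delta_small = 4e-3, delta_big = db),
    numeric(1))) < 0))
})

test_that("noiseless diffusion fits invert the generator exactly", {
  set.seed(21)
  for (i in 1:10) {
    D <- 10^runif(1, -10, -8.5)
    ds <- runif(1, 1e-3, 6e-3)
    db <- runif(1, 0.05, 0.3)
    fit <- fit_diffusion(make_dosy(D, ds = ds, db = db))
    expect_rel_equal(fit$D, D, 1e-10)
    expect_gt(fit$r2_linearity, 1 - 1e-12)
    expect_true(fit$single_component)
  }
})

test_that("a two-component mixture trips the nonlinearity flag", {
  D <- 7.5e-10
  g <- design_gradients(D, 16, delta_small = 4e-3, delta_big = 0.1)
  psi <- 0.5 * st_attenuation(g, D, delta_small = 4e-3, delta_big = 0.1) +
         0.5 * st_attenuation(g, 5 * D, delta_small = 4e-3, delta_big = 0.1)
  ds <- dosy_dataset(g, psi, delta_small = 4e-3, delta_big = 0.1)
  expect_warning(fit <- fit_diffusion(ds), "multi-component")
  expect_lt(fit$r2_linearity, 0.99)
  expect_false(fit$single_component)
})

test_that("diffusion recovery under multiplicative noise", {
  set.seed(99)
  errs1 <- replicate(100, {
    fit <- fit_diffusion(make_dosy(3.2e-9, noise = 0.01))
    (fit$D - 3.2e-9) / 3.2e-9
  })
  # 1% noise, 16 gradients: individual fits within ~3%
  expect_lt(median(abs(errs1)), 0.03)
  expect_lt(unname(quantile(abs(errs1), 0.9)), 0.03)
  # vanishing noise concentrates on truth with negligible bias
  errs2 <- replicate(100, {
    fit <- fit_diffusion(make_dosy(3.2e-9, noise = 1e-3))
    (fit$D - 3.2e-9) / 3.2e-9
  })
  expect_lt(abs(mean(errs2)), 1e-3)
})

test_that("input validation", {
  g <- design_gradients(1e-9, 8, delta_small = 4e-3, delta_big = 0.1)
  expect_error(dosy_dataset(g, c(rep(1, 7), -0.1), delta_small = 4e-3,
                            delta_big = 0.1), "positive")
  expect_error(dosy_dataset(rev(g), rep(1, 8), delta_small = 4e-3,
                            delta_big = 0.1), "increasing")
  expect_error(dosy_dataset(g, rep(1, 8), delta_small = 4e-3,
                            delta_big = 1e-3), "delta_big")
  d2 <- dosy_dataset(g[1:2], c(1, 0.9), delta_small = 4e-3, delta_big = 0.1)
  expect_error(fit_diffusion(d2), "at least 3")
})

test_that("designed gradient schedules attenuate the last point below 5%", {
  for (D in c(7.5e-10, 3.2e-9)) {
    g <- design_gradients(D, 16, delta_small = 4e-3, delta_big = 0.1)
    expect_length(g, 16)
    expect_true(all(diff(g) > 0))
    att <- st_attenuation(g[16], D, delta_small = 4e-3, delta_big = 0.1)
    expect_lt(att, 0.05)
  }
  # halving D scales the maximum gradient by sqrt(2)
  g1 <- design_gradients(1e-9, 16, delta_small = 4e-3, delta_big = 0.1)
  g2 <- design_gradients(5e-10, 16, delta_small = 4e-3, delta_big = 0.1)
  expect_rel_equal(max(g2) / max(g1), sqrt(2), 1e-10)
})
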