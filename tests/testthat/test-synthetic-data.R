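small_design <- function(noise = 0, seed = 1)
  study_design(temperatures_relax = seq(293, 343, by = 10),
               temperatures_cest = c(298, 343),
               offsets = seq(-4000, 4000, by = 500),
               nutations = c(150), noise_sigma = noise, seed = seed)

test_that("default truth reproduces the fitted model quantities", {
  truth <- default_truth()
  expect_equal(signif(dark_population(truth$thermo, 293), 2), 0.0013)
  expect_equal(signif(dark_population(truth$thermo, 353), 2), 0.0073)
  expect_equal(signif(forward_rate(truth$thermo, 353), 2), 660)
  expect_equal(r2b_at(truth, 293), 450)
  expect_equal(r2b_at(truth, 353), 1000)
  # R1A declines smoothly from 0.3 to 0.2 across the range
  expect_equal(r1a_at(truth, 293), 0.3)
  expect_equal(r1a_at(truth, 353), 0.2)
  expect_true(all(diff(r1a_at(truth, seq(293, 353, 5))) < 0))
})

test_that("study generation is bit-for-bit reproducible from its seed", {
  a <- generate_study(default_truth(), small_design(noise = 0.01, seed = 5))
  b <- generate_study(default_truth(), small_design(noise = 0.01, seed = 5))
  expect_identical(a$relaxation, b$relaxation)
  expect_identical(a$zspectra, b$zspectra)
  expect_identical(a$dosy, b$dosy)
  # a different seed changes the noise but not the noiseless observables
  c0 <- generate_study(default_truth(), small_design(noise = 0, seed = 5))
  d0 <- generate_study(default_truth(), small_design(noise = 0, seed = 6))
  expect_equal(c0$relaxation, d0$relaxation)
  expect_equal(c0$zspectra[[1]]$z, d0$zspectra[[1]]$z)
  c1 <- generate_study(default_truth(), small_design(noise = 0.01, seed = 6))
  expect_false(identical(a$relaxation$R2, c1$relaxation$R2))
})

test_that("zero noise passes the simulator output through unchanged", {
  truth <- default_truth()
  study <- generate_study(truth, small_design(noise = 0))
  zs <- study$zspectra[[1]]
  sys <- spin_system_at(truth$thermo, 298, R1A = r1a_at(truth, 298),
                        R2B = r2b_at(truth, 298))
  direct <- simulate_z_spectrum(
    sys, saturation_scheme(150, 5, seq(-4000, 4000, by = 500)),
    temperature = 298)
  expect_equal(zs$z, direct$z, tolerance = 1e-12)
  rates <- generate_relaxation_observables(truth, 313)
  expect_equal(study$relaxation$R2[study$relaxation$temperature_K == 313],
               unname(rates["R2obs"]), tolerance = 1e-12)
})

test_that("the multiplicative noise model is calibrated", {
  des <- lapply(1:40, function(s) small_design(noise = 0.005, seed = s))
  zmat <- vapply(des, function(d)
    generate_study(default_truth(), d)$zspectra[[1]]$z, numeric(17))
  z0 <- generate_study(default_truth(), small_design(noise = 0))$zspectra[[1]]$z
  rel_sd <- apply(zmat / z0 - 1, 1, sd)
  # per-point sample sd of the relative deviation within 15% of 0.005
  expect_lt(abs(mean(rel_sd) - 0.005) / 0.005, 0.15)
})

test_that("relaxation observables reproduce the study's signatures", {
  truth <- default_truth()
  Ts <- seq(293, 343, by = 10)
  obs <- t(vapply(Ts, function(T) generate_relaxation_observables(truth, T),
                  c(R1obs = 0, R2obs = 0)))
  # monotone R2 growth with temperature, R1 below R2 everywhere
  expect_true(all(diff(obs[, "R2obs"]) > 0))
  expect_true(all(obs[, "R2obs"] > obs[, "R1obs"]))
  # an order of magnitude separation at the upper temperatures
  hi <- Ts >= 323
  expect_true(all(obs[hi, "R2obs"] / obs[hi, "R1obs"] >= 10))
  # regime cross-check at 343 K
  r343 <- generate_relaxation_observables(truth, 343)[["R2obs"]]
  fast <- fast_exchange_r2(r1a_at(truth, 343), r2b_at(truth, 343),
                           dark_population(truth$thermo, 343))
  expect_rel_equal(r343, fast, 0.05)
  # disabling exchange collapses R2obs to the visible pool rate
  off <- default_truth(exchange = FALSE)
  expect_equal(generate_relaxation_observables(off, 313)[["R2obs"]],
               r1a_at(off, 313))
})

test_that("CEST dip widths grow with temperature in the default study", {
  truth <- default_truth()
  des <- study_design(temperatures_cest = c(298, 323, 353),
                      offsets = seq(-4000, 4000, by = 200),
                      nutations = 150, noise_sigma = 0)
  study <- generate_study(truth, des)
  widths <- vapply(study$zspectra[1:3], dip_width, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("a study round-trips through its directory representation", {
  study <- generate_study(default_truth(), small_design(noise = 0.01))
  dir <- withr::local_tempdir()
  write_study(study, dir)
  files <- list.files(dir)
  expect_true("relaxation.csv" %in% files)
  expect_true("truth.json" %in% files)
  expect_length(grep("^zspectrum_", files), length(study$zspectra))
  expect_length(grep("^dosy_", files), length(study$dosy))
  rel <- read_table(file.path(dir, "relaxation.csv"), "relaxation")
  expect_equal(rel, study$relaxation, tolerance = 1e-12)
  manifest <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(manifest$thermo$dH, 25000)
  expect_equal(manifest$seed, 1)
})
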