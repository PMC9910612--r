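## Synthetic-study generator: relaxation temperature series, CEST Z-spectra
## and DOSY datasets with known ground truth, reproducing the acquisition
## design of the phosphate-assembly study (Z-spectra -4000..4000 Hz in
## 200 Hz steps, 5 s cw saturation at 20-150 Hz nutation, relaxation series
## 293-343 K, 16-point linear DOSY gradient schedules).

## Evaluate `expr` under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Study acquisition design
#'
#' Defaults mirror the experimental protocol: relaxation series every 10 K
#' over 293-343 K; CEST temperature series at 298, 313, 323, 333, 343 and
#' 353 K with 150 Hz nutation; a saturation-power series at 298 K with
#' nutation frequencies of 20-150 Hz; saturation offsets -4000..4000 Hz in
#' 200 Hz steps for 5 s; DOSY at 293 and 343 K with 16 linearly spaced
#' gradients ending below 5% attenuation.
#'
#' @param temperatures_relax Relaxation-series temperatures, K.
#' @param temperatures_cest CEST-series temperatures, K.
#' @param offsets Saturation offsets, Hz.
#' @param nutations Nutation frequencies for the power series, Hz.
#' @param sat_duration Saturation duration, s.
#' @param temperatures_dosy DOSY temperatures, K.
#' @param n_gradients Number of DOSY gradient strengths.
#' @param delta_small,delta_big DOSY pulse width and diffusion delay, s.
#' @param noise_sigma Multiplicative Gaussian noise fraction per data point.
#' @param seed Integer RNG seed.
#' @return An object of class `study_design`.
#' @export
study_design <- function(temperatures_relax = seq(293, 343, by = 10),
                         temperatures_cest = c(298, 313, 323, 333, 343, 353),
                         offsets = seq(-4000, 4000, by = 200),
                         nutations = c(20, 30, 50, 100, 150),
                         sat_duration = 5,
                         temperatures_dosy = c(293, 343),
                         n_gradients = 16,
                         delta_small = 4e-3,
                         delta_big = 0.1,
                         noise_sigma = 0,
                         seed = 1L) {
  if (noise_sigma < 0) stop_input("noise_sigma must be >= 0")
  stopifnot(length(temperatures_relax) > 0, length(temperatures_cest) > 0,
            length(nutations) > 0, length(offsets) > 1)
  structure(list(temperatures_relax = temperatures_relax,
                 temperatures_cest = temperatures_cest,
                 offsets = offsets, nutations = nutations,
                 sat_duration = sat_duration,
                 temperatures_dosy = temperatures_dosy,
                 n_gradients = n_gradients,
                 delta_small = delta_small, delta_big = delta_big,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "study_design")
}

#' Ground-truth parameter set of the phosphate-assembly model
#'
#' The fitted exchange model: dH = 25 kJ/mol, dS = 30 J/(mol K),
#' k0 = 20,000 1/s, Ea = 10 kJ/mol; a dark-pool R2 schedule linear in
#' temperature from 450 1/s at 293 K to 1,000 1/s at 353 K; a visible-pool
#' R1 declining smoothly (exponentially) from 0.3 1/s at 293 K to 0.2 1/s
#' at 353 K; and translational diffusion coefficients of 7.5e-10 m^2/s at
#' 293 K and 3.2e-9 m^2/s at 343 K for the visible species.
#'
#' @param exchange If `FALSE`, exchange is disabled (kf = kb = 0, pB = 0);
#'   useful for no-exchange controls.
#' @return An object of class `study_truth`.
#' @export
default_truth <- function(exchange = TRUE) {
  structure(list(
    thermo = thermo_params(dH = 25e3, dS = 30, k0 = 2e4, Ea = 10e3),
    r1a_ref = c(`293` = 0.3, `353` = 0.2),
    r2b_ref = c(`293` = 450, `353` = 1000),
    dosy_D = c(`293` = 7.5e-10, `343` = 3.2e-9),
    exchange = isTRUE(exchange)),
    class = "study_truth")
}

#' Ground-truth per-temperature schedules
#'
#' `r1a_at()` interpolates the visible-pool R1 exponentially between its
#' reference endpoints; `r2b_at()` interpolates the dark-pool R2 linearly
#' between 293 K and 353 K.
#'
#' @param truth A [default_truth()] object.
#' @param T Temperature, K (vectorized).
#' @return Rate(s), 1/s.
#' @export
r1a_at <- function(truth, T) {
  ref <- truth$r1a_ref
  ref[["293"]] * exp(log(ref[["353"]] / ref[["293"]]) * (T - 293) / 60)
}

#' @rdname r1a_at
#' @export
r2b_at <- function(truth, T) {
  ref <- truth$r2b_ref
  ref[["293"]] + (ref[["353"]] - ref[["293"]]) * (T - 293) / 60
}

truth_spin_system <- function(truth, T) {
  if (truth$exchange) {
    spin_system_at(truth$thermo, T, R1A = r1a_at(truth, T),
                   R2B = r2b_at(truth, T))
  } else {
    r1 <- r1a_at(truth, T)
    spin_system(R1A = r1, R2A = r1, R1B = r1, R2B = r2b_at(truth, T),
                pB = 0, kf = 0, kb = 0)
  }
}

#' Noiseless observed relaxation rates implied by the truth
#'
#' Evaluates [observed_rates()] on the spin system implied by the ground
#' truth at temperature `T`.
#'
#' @param truth A [default_truth()] object.
#' @param T Temperature, K.
#' @return Named vector `c(R1obs = ..., R2obs = ...)`.
#' @export
generate_relaxation_observables <- function(truth, T) {
  observed_rates(truth_spin_system(truth, T))
}

apply_mult_noise <- function(x, sigma) {
  if (sigma == 0) return(x)
  x * (1 + stats::rnorm(length(x), 0, sigma))
}

#' Generate a complete synthetic study
#'
#' Computes every observable with the simulator modules (Bloch-McConnell
#' Z-spectra and observed rates, Stejskal-Tanner DOSY attenuation), then
#' applies independent multiplicative Gaussian noise of fraction
#' `design$noise_sigma` per data point under `design$seed`. Regenerating
#' with the same truth and design is bit-for-bit reproducible; changing
#' only the seed changes the noise but not the noiseless observables.
#'
#' @param truth A [default_truth()] object.
#' @param design A [study_design()].
#' @return An object of class `synthetic_study` with elements `truth`,
#'   `design`, `relaxation` (data frame `temperature_K`, `R1`, `R2`),
#'   `zspectra` (list of [zspectrum()]: the temperature series at the
#'   highest nutation, then the power series at the lowest CEST
#'   temperature), `dosy` (list of [dosy_dataset()]) and `seed`.
#' @export
generate_study <- function(truth = default_truth(), design = study_design()) {
  stopifnot(inherits(truth, "study_truth"), inherits(design, "study_design"))
  nut_main <- max(design$nutations)
  T_power <- min(design$temperatures_cest)

  relax0 <- t(vapply(design$temperatures_relax,
                     function(T) generate_relaxation_observables(truth, T),
                     c(R1obs = 0, R2obs = 0)))
  zs_temp <- lapply(design$temperatures_cest, function(T) {
    simulate_z_spectrum(truth_spin_system(truth, T),
                        saturation_scheme(nut_main, design$sat_duration,
                                          design$offsets),
                        temperature = T)
  })
  zs_power <- lapply(design$nutations, function(nu) {
    simulate_z_spectrum(truth_spin_system(truth, T_power),
                        saturation_scheme(nu, design$sat_duration,
                                          design$offsets),
                        temperature = T_power)
  })
  dosy0 <- lapply(design$temperatures_dosy, function(T) {
    key <- as.character(T)
    if (!key %in% names(truth$dosy_D))
      stop_input("no ground-truth diffusion coefficient at T = ", T, " K")
    D <- truth$dosy_D[[key]]
    g <- design_gradients(D, design$n_gradients,
                          delta_small = design$delta_small,
                          delta_big = design$delta_big)
    dosy_dataset(g, st_attenuation(g, D, delta_small = design$delta_small,
                                   delta_big = design$delta_big),
                 delta_small = design$delta_small,
                 delta_big = design$delta_big, temperature = T)
  })

  study <- with_seed(design$seed, {
    relax <- data.frame(temperature_K = design$temperatures_relax,
                        R1 = apply_mult_noise(relax0[, "R1obs"],
                                              design$noise_sigma),
                        R2 = apply_mult_noise(relax0[, "R2obs"],
                                              design$noise_sigma))
    zspectra <- lapply(c(zs_temp, zs_power), function(zs) {
      zspectrum(zs$offset_hz, apply_mult_noise(zs$z, design$noise_sigma),
                temperature = attr(zs, "temperature_K"),
                nutation = attr(zs, "nutation_hz"),
                duration = attr(zs, "duration_s"))
    })
    dosy <- lapply(dosy0, function(ds) {
      dosy_dataset(ds$gradients,
                   apply_mult_noise(ds$intensities, design$noise_sigma),
                   gamma = ds$gamma, delta_small = ds$delta_small,
                   delta_big = ds$delta_big, temperature = ds$temperature)
    })
    list(relaxation = relax, zspectra = zspectra, dosy = dosy)
  })

  structure(list(truth = truth, design = design,
                 relaxation = study$relaxation,
                 zspectra = study$zspectra,
                 dosy = study$dosy,
                 seed = design$seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic dark-state exchange study\n")
  cat(sprintf("  relaxation series: %d temperatures (%g-%g K)\n",
              nrow(x$relaxation), min(x$relaxation$temperature_K),
              max(x$relaxation$temperature_K)))
  cat(sprintf("  Z-spectra: %d; DOSY datasets: %d; noise = %g; seed = %d\n",
              length(x$zspectra), length(x$dosy),
              x$design$noise_sigma, x$seed))
  invisible(x)
}

#' Write a synthetic study to a directory
#'
#' Emits the CSV dialects consumed by [read_table()] plus a `truth.json`
#' manifest holding the ground-truth parameters and seed.
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(study$relaxation, file.path(dir, "relaxation.csv"))
  for (i in seq_along(study$zspectra)) {
    zs <- study$zspectra[[i]]
    write_table(zs, file.path(dir, sprintf("zspectrum_%02d_T%g_nu%g.csv", i,
                                           attr(zs, "temperature_K"),
                                           attr(zs, "nutation_hz"))))
  }
  for (i in seq_along(study$dosy)) {
    ds <- study$dosy[[i]]
    write_table(ds, file.path(dir, sprintf("dosy_T%g.csv", ds$temperature)))
  }
  tr <- study$truth
  manifest <- list(
    thermo = tr$thermo[c("dH", "dS", "k0", "Ea")],
    r1a_ref = as.list(tr$r1a_ref), r2b_ref = as.list(tr$r2b_ref),
    dosy_D = as.list(tr$dosy_D), exchange = tr$exchange,
    noise_sigma = study$design$noise_sigma, seed = study$seed)
  jsonlite::write_json(manifest, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
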