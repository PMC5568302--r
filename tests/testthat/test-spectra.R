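grid <- 350:750

test_that("difference spectra subtract pointwise and resample grids", {
  dark <- spectrum_curve(grid, pigment_template(grid, 544, "A1"))
  expect_true(all(abs(difference_spectrum(dark, dark)$absorbance) < 1e-12))
  zero <- spectrum_curve(grid, rep(0, length(grid)))
  expect_equal(difference_spectrum(dark, zero)$absorbance, dark$absorbance)
  # resampling onto the overlap of two different grids
  bleach <- spectrum_curve(seq(400, 700, by = 2), rep(0.1, 151))
  d <- difference_spectrum(dark, bleach)
  expect_gte(min(d$wavelength), 400)
  expect_lte(max(d$wavelength), 700)
  # difference peak sits at the pigment peak when the bleach product is flat
  expect_equal(estimate_lambda_max(d)$lambda_max,
               estimate_lambda_max(dark)$lambda_max, tolerance = 0.2)
  expect_error(difference_spectrum(dark, spectrum_curve(800:900, rep(0, 101))),
               "overlap")
})

test_that("peak estimation is accurate, equivariant, and averages replicates", {
  tmpl <- spectrum_curve(grid, pigment_template(grid, 523, "A2"))
  est <- estimate_lambda_max(tmpl)
  expect_lt(abs(est$lambda_max - 523), 0.5)
  expect_identical(est$se, 0)
  # translation equivariance: shifting the curve +10 nm shifts the estimate
  shifted <- spectrum_curve(grid + 10, tmpl$absorbance)
  expect_equal(estimate_lambda_max(shifted)$lambda_max, est$lambda_max + 10,
               tolerance = 1e-9)
  # standard error shrinks roughly as 1/sqrt(k) over noisy replicates
  noisy <- function(k, n) {
    lapply(seq_len(k), function(i) {
      simulate_spectrum(sim_spectrum_params(503, 523, 1, 0.01, grid,
                                            seed = 1000 * n + i))
    })
  }
  many <- estimate_lambda_max(noisy(10, 1))
  expect_lt(abs(many$lambda_max - 523), 2)
  spread <- sd(vapply(noisy(30, 2), function(cv) {
    estimate_lambda_max(cv)$lambda_max
  }, numeric(1)))
  expect_lt(many$se, spread)  # se of mean < single-curve spread
  # a peak on the window boundary is rejected
  expect_error(estimate_lambda_max(spectrum_curve(600:750,
    pigment_template(600:750, 595, "A2"))), "boundary")
})

test_that("standard template construction recovers the generating shape", {
  reps <- lapply(1:4, function(k) {
    simulate_spectrum(sim_spectrum_params(544, 595, 0, 0.005, grid, seed = k))
  })
  tmpl <- build_standard_template(reps)
  truth <- pigment_template(tmpl$rel_wavelength + 544, 544, "A1")
  truth <- truth / max(truth)
  keep <- abs(tmpl$rel_wavelength) <= 100
  expect_lt(max(abs(tmpl$absorbance[keep] - truth[keep])), 0.01)
  expect_equal(max(tmpl$absorbance), 1)
  # curves with different peak wavelengths but a common shape collapse to it
  shape <- function(lm) spectrum_curve(grid, pigment_template(grid, 520, "A1")
                                       [match(grid - (lm - 520), grid)] |>
                                         (\(v) ifelse(is.na(v), 0, v))())
  mixed <- list(shape(500), shape(520), shape(540))
  tm <- build_standard_template(mixed)
  ref <- pigment_template(tm$rel_wavelength + 520, 520, "A1")
  keep <- abs(tm$rel_wavelength) <= 80
  expect_lt(max(abs(tm$absorbance[keep] - (ref / max(ref))[keep])), 0.02)
  expect_error(build_standard_template(reps[1L]), "at least two")
})

test_that("template shifting is exact at the reference and round-trips", {
  reps <- lapply(1:4, function(k) {
    simulate_spectrum(sim_spectrum_params(503, 523, 1, 0, grid, seed = k))
  })
  tmpl <- build_standard_template(reps)
  at_ref <- shift_template(tmpl, 523)
  expect_lt(abs(estimate_lambda_max(at_ref)$lambda_max - 523), 0.1)
  # +20 then -20 returns the original within interpolation tolerance
  up <- shift_template(tmpl, 543, wavelength_grid = 420:640)
  t2 <- build_standard_template(list(up, up, up))
  back <- shift_template(t2, 523, wavelength_grid = 430:610)
  orig <- shift_template(tmpl, 523, wavelength_grid = 430:610)
  expect_lt(max(abs(back$absorbance - orig$absorbance)), 0.01)
  # argmax of the shifted curve lands on the target on a fine grid
  fine <- shift_template(tmpl, 510, wavelength_grid = seq(440, 580, by = 0.1))
  expect_lt(abs(fine$wavelength[which.max(fine$absorbance)] - 510), 0.2)
  expect_error(shift_template(tmpl, 510, wavelength_grid = 100:200), "coverage")
})

test_that("mixture fitting recovers the A2 fraction in both modes", {
  g <- 400:750
  t1 <- spectrum_curve(g, pigment_template(g, 544, "A1"))
  t2 <- spectrum_curve(g, pigment_template(g, 595, "A2"))
  # observed peak equal to the A1 template peak: pure A1
  f0 <- fit_a1_a2_mixture(estimate_lambda_max(t1)$lambda_max, t1, t2,
                          mode = "peak-match")
  expect_identical(f0$a2_fraction, 0)
  # noiseless mixtures recovered within one grid step in both modes
  for (phi in c(0.25, 0.5, 0.75)) {
    obs <- simulate_spectrum(sim_spectrum_params(544, 595, phi, 0, g, seed = 1))
    fc <- fit_a1_a2_mixture(obs, t1, t2, mode = "curve-match")
    fp <- fit_a1_a2_mixture(obs, t1, t2, mode = "peak-match")
    expect_lte(abs(fc$a2_fraction - phi), 0.01)
    expect_lte(abs(fp$a2_fraction - phi), 0.02)
  }
  # fitted mixture peak is monotone non-decreasing across the phi sweep
  pks <- vapply(seq(0, 1, 0.1), function(phi) {
    obs <- simulate_spectrum(sim_spectrum_params(544, 595, phi, 0, g, seed = 1))
    fit_a1_a2_mixture(obs, t1, t2, mode = "curve-match")$lambda_max
  }, numeric(1))
  expect_true(all(diff(pks) >= -1e-6))
  # observed peak outside the template interval is clamped with a warning
  expect_warning(fhi <- fit_a1_a2_mixture(650, t1, t2, mode = "peak-match"),
                 "clamping")
  expect_identical(fhi$a2_fraction, 1)
  expect_warning(flo <- fit_a1_a2_mixture(500, t1, t2, mode = "peak-match"),
                 "clamping")
  expect_identical(flo$a2_fraction, 0)
})

test_that("spectrum CSV round trip preserves the curve", {
  cv <- simulate_spectrum(sim_spectrum_params(544, 595, 0.4, 0.01, seed = 7))
  p <- file.path(tempdir(), "curve.csv")
  write_spectrum_csv(cv, p)
  back <- read_spectrum_csv(p)
  expect_equal(back$wavelength, cv$wavelength)
  expect_equal(back$absorbance, cv$absorbance, tolerance = 1e-12)
})
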