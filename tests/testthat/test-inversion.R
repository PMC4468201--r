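# Calibration and nonlinear least-squares inversion.

test_that("calibration identities hold exactly", {
  grid <- shared_grid()
  model <- exp(-(as.numeric(grid) - 550)^2 / 1e4)
  raw <- model * 3.7
  # raw_sample == raw_reference -> calibrated == model_reference
  cal <- calibrate_spectrum(raw, raw, model, grid = grid)
  expect_identical(cal$reflectance, model)
  # common drift factor on a frame and its SC channel cancels
  sc <- rep(2.0, length(grid))
  k <- 1.017
  a <- calibrate_spectrum(raw, raw * 0.9, model, sc_sample = sc,
                          sc_reference = sc, grid = grid)
  b <- calibrate_spectrum(raw * k, raw * 0.9, model, sc_sample = sc * k,
                          sc_reference = sc, grid = grid)
  expect_equal(a$reflectance, b$reflectance)
  expect_error(calibrate_spectrum(raw, raw * 0, model), "> 0")
  expect_error(calibrate_spectrum(raw, raw, model, sc_sample = sc * 0),
               "> 0")
})

test_that("noiseless synthetic frames calibrate back to the model exactly", {
  lut <- shared_lut(); grid <- shared_grid(); lib <- shared_library()
  quiet <- noise_model(drift_sd = 0.015, noise_sd = 0, sc_noise_sd = 0)
  sp <- render_phantom_spectra(lut, grid, noise = quiet, library = lib,
                               seed = 12)
  ph <- sp$phantoms
  ref <- 4
  model_ref <- sp$true[, ref]
  for (tgt in c(1, 9)) {
    cal <- calibrate_spectrum(sp$raw[, tgt], sp$raw[, ref], model_ref,
                              sc_sample = sp$sc[, tgt],
                              sc_reference = sp$sc[, ref], grid = grid)
    expect_equal(cal$reflectance, sp$true[, tgt], tolerance = 1e-10)
  }
})

test_that("noiseless closed-loop fits recover parameters within 1%", {
  lut <- shared_lut(); grid <- shared_grid(); lib <- shared_library()
  shape <- phantom_musp_shape(grid)
  ph <- phantom_specs()
  for (i in c(2, 8, 12)) {
    refl <- lut_reflectance(lut, ph$musp[i] * shape,
                            absorption_spectrum(c(hb = ph$hb[i]), lib, grid))
    fit <- fit_spectrum(refl, lut, grid, model = "phantom", library = lib)
    expect_lt(abs(fit$par[["hb"]] - ph$hb[i]) / ph$hb[i], 0.01)
    expect_lt(abs(fit$band_musp - ph$musp[i]) / ph$musp[i], 0.01)
    expect_lte(fit$rss, fit$rss_initial)   # monotone improvement
  }
  # tissue model closed loop, including the ratio endpoint
  tr <- tissue_reflectance(lut, grid, lib, bcar = 12, hb = 45,
                           musp = 8.2, b = 1)
  fit <- fit_spectrum(tr, lut, grid, model = "tissue", library = lib)
  expect_equal(fit$ratio, 12 / 8.2, tolerance = 0.01)
})

test_that("the zero-absorption phantom fits to [Hb] at the lower bound", {
  lut <- shared_lut(); grid <- shared_grid(); lib <- shared_library()
  shape <- phantom_musp_shape(grid)
  refl <- lut_reflectance(lut, 9.73 * shape, rep(0, length(grid)))
  fit <- fit_spectrum(refl, lut, grid, model = "phantom", library = lib)
  expect_lt(fit$par[["hb"]], 0.1)
  expect_lt(fit$band_mua, 0.01)
})

test_that("multi-starts agree on the optimum for well-posed inputs", {
  lut <- shared_lut(); grid <- shared_grid(); lib <- shared_library()
  shape <- phantom_musp_shape(grid)
  refl <- lut_reflectance(lut, 8.58 * shape,
                          absorption_spectrum(c(hb = 50.62), lib, grid))
  f2 <- fit_spectrum(refl, lut, grid, model = "phantom", library = lib,
                     n_starts = 2)
  f5 <- fit_spectrum(refl, lut, grid, model = "phantom", library = lib,
                     n_starts = 5)
  expect_equal(f5$par, f2$par, tolerance = 1e-3)
  expect_error(fit_spectrum(rep(0, length(grid)), lut, grid,
                            model = "phantom", library = lib), "all-zero")
})

test_that("noiseless leave-one-out errors are below 1%", {
  lut <- shared_lut(); grid <- shared_grid(); lib <- shared_library()
  quiet <- noise_model(drift_sd = 0.01, noise_sd = 0, sc_noise_sd = 0)
  cv <- loocv_phantom_errors(NULL, lut, grid, noise = quiet, seed = 3,
                             library = lib)
  expect_equal(cv$n_folds, 12)
  expect_equal(cv$n_per_fold, 11)
  expect_equal(nrow(cv$folds), 132)
  expect_lt(cv$summary[["musp_mean"]], 1)
  expect_lt(cv$summary[["mua_mean"]], 1)
  # the zero-absorption phantom is excluded from the percent aggregate
  expect_equal(sum(is.na(cv$folds$mua_err_pct)), 11)
  expect_error(loocv_phantom_errors(
    list(raw = matrix(1, 3, 1), sc = matrix(1, 3, 1),
         phantoms = phantom_specs()[1, ]), lut, grid), "2 phantoms")
})

test_that("parameter recovery over random draws: median error < 5%", {
  lut <- shared_lut(); grid <- shared_grid(); lib <- shared_library()
  shape <- phantom_musp_shape(grid)
  set.seed(60)
  draws <- data.frame(musp = runif(50, 7.03, 9.73),
                      hb = runif(50, 8, 115))
  errs <- t(vapply(seq_len(nrow(draws)), function(i) {
    mua <- absorption_spectrum(c(hb = draws$hb[i]), lib, grid)
    refl <- lut_reflectance(lut, draws$musp[i] * shape, mua) *
      (1 + rnorm(length(grid)) * 0.01)
    fit <- fit_spectrum(refl, lut, grid, model = "phantom", library = lib,
                        n_starts = 1)
    c(musp = 100 * abs(fit$band_musp - draws$musp[i]) / draws$musp[i],
      mua = 100 * abs(fit$band_mua - band_average(mua, grid)) /
        band_average(mua, grid))
  }, numeric(2)))
  expect_lt(median(errs[, "musp"]), 5)
  keep <- draws$hb * 0.077 > 0.5   # band <mu_a> above 0.5 cm^-1
  expect_lt(median(errs[keep, "mua"]), 5)
})
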