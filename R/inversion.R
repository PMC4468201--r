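# Reference-phantom calibration and nonlinear least-squares inversion of
# calibrated reflectance spectra against the lookup-table forward model,
# recovering [Hb], [beta-carotene] and mu_s'; plus the leave-one-out
# cross-validation harness over the phantom dilution series.

#' Calibrate a raw spectrum against a reference phantom
#'
#' Each raw frame is first divided by its parity's self-calibration channel
#' (cancelling within-measurement source intensity drift exactly), then
#' scaled by `raw_sample / raw_reference * model_reference`, putting the
#' measurement on the forward model's reflectance scale.  Multiplying a raw
#' spectrum and its SC channel by a common drift factor leaves the result
#' unchanged by construction.
#'
#' @param raw_sample,raw_reference Raw spectra on a common grid.
#' @param model_reference Forward-model reflectance of the reference
#'   phantom at its known optical properties.
#' @param sc_sample,sc_reference Optional matching self-calibration channel
#'   spectra.
#' @param grid Wavelength grid (kept with the result).
#' @return A `qdri_calibrated` object (grid + reflectance).
#' @export
calibrate_spectrum <- function(raw_sample, raw_reference, model_reference,
                               sc_sample = NULL, sc_reference = NULL,
                               grid = NULL) {
  ns <- length(raw_sample)
  if (length(raw_reference) != ns || length(model_reference) != ns)
    stop("all spectra must share one grid")
  if (!is.null(sc_sample)) {
    if (length(sc_sample) != ns) stop("sc_sample grid mismatch")
    if (any(sc_sample <= 0)) stop("self-calibration channel must be > 0")
    raw_sample <- raw_sample / sc_sample
  }
  if (!is.null(sc_reference)) {
    if (length(sc_reference) != ns) stop("sc_reference grid mismatch")
    if (any(sc_reference <= 0)) stop("self-calibration channel must be > 0")
    raw_reference <- raw_reference / sc_reference
  }
  if (any(!is.finite(raw_reference)) || any(raw_reference <= 0))
    stop("reference spectrum must be finite and > 0 on the band")
  refl <- raw_sample / raw_reference * model_reference
  structure(list(grid = grid, reflectance = as.numeric(refl)),
            class = "qdri_calibrated")
}

# Deterministic multi-start factors: the first start is the nominal initial
# point; later starts scale it geometrically within the bounds.
start_points <- function(init, lower, upper, n_starts) {
  f <- c(1, 0.35, 2.8, 0.12, 8)[seq_len(n_starts)]
  lapply(f, function(k) pmin(pmax(init * k, lower + 1e-9 * (upper - lower)),
                             upper - 1e-9 * (upper - lower)))
}

#' Fit a calibrated reflectance spectrum to the forward model
#'
#' Bounded nonlinear least squares over the analysis band against the
#' lookup-table forward model, with deterministic multi-starts (best
#' residual wins; ties broken by first index).  Two parameterizations:
#'
#' * `"phantom"`: \[Hb\] (uM) and band-averaged scattering magnitude
#'   `s` = <mu_s'> (cm^-1), with the Mie sphere spectral shape (phantoms
#'   contain no beta-carotene).
#' * `"tissue"`: \[Hb\], \[beta-carotene\] (uM), scattering magnitude and
#'   power-law exponent `b`, with `mu_s'(lambda) = a (lambda/550)^-b`
#'   normalized so the fitted magnitude is the band average.
#'
#' @param calibrated A [calibrate_spectrum()] result, or a bare reflectance
#'   vector on `grid`.
#' @param lut Forward lookup table ([build_reflectance_lut()]).
#' @param grid Wavelength grid of the spectrum.
#' @param model `"phantom"` or `"tissue"`.
#' @param library Absorber library (needed by both models for Hb, plus
#'   beta-carotene for tissue).
#' @param band Fit band, nm (the analysis band).
#' @param init,lower,upper Optional named parameter overrides.
#' @param n_starts Number of deterministic multi-starts.
#' @param control Passed to [stats::optim()] (`L-BFGS-B`).
#' @return A `qdri_fit`: fitted parameters, spectra, band averages, the
#'   beta-carotene/scattering ratio (tissue model), residual sum of
#'   squares, and a convergence flag (non-convergence is flagged, not an
#'   error).
#' @export
fit_spectrum <- function(calibrated, lut, grid,
                         model = c("phantom", "tissue"),
                         library = absorber_library(grid),
                         band = c(450, 600),
                         init = NULL, lower = NULL, upper = NULL,
                         n_starts = 3,
                         control = list(factr = 1e4, maxit = 500)) {
  model <- match.arg(model)
  refl <- if (inherits(calibrated, "qdri_calibrated"))
    calibrated$reflectance else as.numeric(calibrated)
  if (length(refl) != length(grid)) stop("spectrum/grid length mismatch")
  if (all(refl == 0)) stop("all-zero spectrum cannot be fitted")
  sel <- grid >= band[1] & grid <= band[2]
  if (!any(sel)) stop("empty fit band")
  gsub <- grid[sel]; ysub <- refl[sel]

  eps_hb <- library$hb$extinction[sel]
  if (model == "phantom") {
    shape <- phantom_musp_shape(grid, band)[sel]
    shape <- shape / mean(shape)   # band mean exactly 1 on the fit band
    p0 <- c(hb = 40, s = 8.5)
    lo <- c(hb = 0, s = max(1, min(lut$musp_grid)))
    hi <- c(hb = 300, s = min(20, max(lut$musp_grid)))
    fwd <- function(p) {
      mua <- log(10) * eps_hb * p[1] * 1e-6
      lut_reflectance(lut, p[2] * shape, mua)
    }
  } else {
    eps_bc <- library$beta_carotene$extinction[sel]
    pshape <- function(b) {
      s <- (gsub / 550)^(-b)
      s / mean(s)
    }
    p0 <- c(hb = 40, bcar = 10, a = 8.5, b = 1)
    lo <- c(hb = 0, bcar = 0, a = max(1, min(lut$musp_grid)), b = 0)
    hi <- c(hb = 300, bcar = 80, a = min(20, max(lut$musp_grid)), b = 4)
    fwd <- function(p) {
      mua <- log(10) * (eps_hb * p[1] + eps_bc * p[2]) * 1e-6
      lut_reflectance(lut, p[3] * pshape(p[4]), mua)
    }
  }
  if (!is.null(init)) p0[names(init)] <- init
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper

  # residuals normalized by the spectrum scale so the objective is O(1)
  # regardless of the absolute reflectance level (~1e-5 for this geometry)
  res_scale <- mean(abs(ysub))
  if (res_scale == 0) stop("all-zero spectrum cannot be fitted")
  obj <- function(p) sum(((fwd(p) - ysub) / res_scale)^2)
  rss0 <- obj(p0)
  best <- NULL
  for (st in start_points(p0, lo, hi, n_starts)) {
    fit <- tryCatch(
      optim(st, obj, method = "L-BFGS-B", lower = lo, upper = hi,
            control = c(control, list(parscale = pmax(abs(p0), 1e-3)))),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    return(structure(list(par = p0, rss = rss0, converged = FALSE),
                     class = "qdri_fit"))
  p <- best$par
  # derived spectra on the full grid
  eps_hb_full <- library$hb$extinction
  if (model == "phantom") {
    shape_full <- phantom_musp_shape(grid, band)
    musp_full <- p[["s"]] * shape_full / band_average(shape_full, grid, band)
    mua_full <- log(10) * eps_hb_full * p[["hb"]] * 1e-6
    bcar <- NA_real_
  } else {
    s <- (grid / 550)^(-p[["b"]])
    musp_full <- p[["a"]] * s / band_average(s, grid, band)
    mua_full <- log(10) * (eps_hb_full * p[["hb"]] +
                             library$beta_carotene$extinction * p[["bcar"]]) *
      1e-6
    bcar <- p[["bcar"]]
  }
  band_musp <- band_average(musp_full, grid, band)
  band_mua <- band_average(mua_full, grid, band)
  structure(list(par = p, model = model,
                 musp_spectrum = musp_full, mua_spectrum = mua_full,
                 band_musp = band_musp, band_mua = band_mua,
                 ratio = if (is.na(bcar)) NA_real_ else bcar / band_musp,
                 rss = best$value, rss_initial = rss0,
                 converged = best$convergence == 0,
                 fitted = fwd(p), band = band),
            class = "qdri_fit")
}

#' @export
print.qdri_fit <- function(x, ...) {
  cat("qdri spectral fit (", x$model, " model)\n", sep = "")
  print(signif(x$par, 5))
  cat("  band <mu_s'> =", signif(x$band_musp, 4),
      "cm^-1, band <mu_a> =", signif(x$band_mua, 4), "cm^-1\n")
  if (!is.na(x$ratio)) cat("  [b-carotene]/<mu_s'> =",
                           signif(x$ratio, 4), "uM cm\n")
  cat("  rss =", format(x$rss, digits = 4),
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  invisible(x)
}

#' Leave-one-out cross-validation over the phantom series
#'
#' Each of the 12 phantoms serves in turn as the calibration reference
#' against the remaining 11 (12 folds x 11 targets = 132 inversions).
#' Percent error is `100 |extracted - expected| / expected`; the
#' zero-absorption phantom is reported as an absolute mu_a error (cm^-1)
#' and excluded from the mu_a percent aggregate.
#'
#' @param spectra Rendered phantom spectra ([render_phantom_spectra()]);
#'   generated internally when `NULL`.
#' @param lut Forward lookup table.
#' @param grid Wavelength grid.
#' @param noise Noise model used when `spectra` is `NULL`.
#' @param seed Seed for internally rendered spectra.
#' @param library Absorber library.
#' @param ... Passed to [fit_spectrum()].
#' @return List: per-inversion `folds` data.frame, `summary` (mean and sd
#'   percent errors for band-averaged mu_a and mu_s', pooled mean),
#'   `mua_abs_phantom1` (mean absolute error, cm^-1), `n_folds`,
#'   `n_per_fold`.
#' @export
loocv_phantom_errors <- function(spectra = NULL, lut, grid = wavelength_grid(),
                                 noise = noise_model(), seed = 1,
                                 library = absorber_library(grid), ...) {
  if (is.null(spectra))
    spectra <- render_phantom_spectra(lut, grid, noise = noise,
                                      library = library, seed = seed)
  ph <- spectra$phantoms
  np <- nrow(ph)
  if (np < 2) stop("need at least 2 phantoms")
  shape <- phantom_musp_shape(grid)
  rows <- vector("list", np * (np - 1L))
  k <- 0L
  for (ref in seq_len(np)) {
    model_ref <- lut_reflectance(lut, ph$musp[ref] * shape,
                                 absorption_spectrum(c(hb = ph$hb[ref]),
                                                     library, grid))
    for (tgt in seq_len(np)) {
      if (tgt == ref) next
      cal <- calibrate_spectrum(spectra$raw[, tgt], spectra$raw[, ref],
                                model_ref, sc_sample = spectra$sc[, tgt],
                                sc_reference = spectra$sc[, ref], grid = grid)
      fit <- fit_spectrum(cal, lut, grid, model = "phantom",
                          library = library, ...)
      k <- k + 1L
      rows[[k]] <- data.frame(
        reference = ref, target = tgt,
        musp_hat = fit$band_musp, mua_hat = fit$band_mua,
        musp_err_pct = 100 * abs(fit$band_musp - ph$musp[tgt]) /
          ph$musp[tgt],
        mua_err_pct = if (ph$mua[tgt] > 0)
          100 * abs(fit$band_mua - ph$mua[tgt]) / ph$mua[tgt] else NA_real_,
        mua_err_abs = abs(fit$band_mua - ph$mua[tgt]),
        converged = fit$converged)
    }
  }
  folds <- do.call(rbind, rows)
  musp_e <- folds$musp_err_pct
  mua_e <- folds$mua_err_pct[!is.na(folds$mua_err_pct)]
  summary <- c(musp_mean = mean(musp_e), musp_sd = sd(musp_e),
               mua_mean = mean(mua_e), mua_sd = sd(mua_e),
               pooled_mean = mean(c(musp_e, mua_e)))
  list(folds = folds, summary = summary,
       mua_abs_phantom1 = mean(folds$mua_err_abs[is.na(folds$mua_err_pct)]),
       n_folds = np, n_per_fold = np - 1L)
}
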