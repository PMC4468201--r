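# Synthetic-data generators: the 12-phantom dilution series used for
# accuracy validation, breast-margin-like tissue maps with class-dependent
# optical parameters, and raw-frame synthesis with the instrument noise
# model (lamp spectral shape, <= 2% source drift shared with the
# self-calibration channel, shot-like noise).

#' The 12-phantom dilution series
#'
#' Liquid tissue-simulating phantoms: 1 um polystyrene spheres for
#' scattering and hemoglobin added in increasing aliquots for absorption.
#' Values are the expected band-averaged (450--600 nm) properties of the
#' validation series: mu_s' decreases (dilution) while mu_a and \[Hb\]
#' increase; phantom 1 is absorber-free.
#'
#' @return data.frame with columns `id`, `musp` (cm^-1), `mua` (cm^-1),
#'   `hb` (uM).
#' @export
phantom_specs <- function() {
  data.frame(
    id = 1:12,
    musp = c(9.73, 9.41, 9.12, 8.84, 8.58, 8.34, 8.10, 7.89, 7.68, 7.48,
             7.29, 7.03),
    mua = c(0, 1.07, 2.07, 3.01, 3.90, 4.70, 5.50, 6.25, 6.96, 7.63, 8.26,
            8.86),
    hb = c(0, 13.89, 26.87, 39.07, 50.62, 61.00, 71.39, 81.12, 90.34,
           99.04, 107.22, 115.01))
}

#' LED lamp spectral shape
#'
#' Smooth positive spectral shape emulating the dual-channel white LED
#' source (blue and cyan pumps plus phosphor hump, approximately flat
#' 420--600 nm, declining to the red), normalized to mean 1.
#'
#' @param grid Wavelength grid, nm.
#' @export
lamp_spectrum <- function(grid = wavelength_grid()) {
  validate_grid(grid)
  s <- 0.35 +
    0.9 * exp(-((grid - 452) / 14)^2) +
    0.55 * exp(-((grid - 473) / 12)^2) +
    0.5 * exp(-((grid - 512) / 16)^2) +
    0.75 * exp(-((grid - 560) / 45)^2)
  s <- s * (1 - 0.5 * pmax(0, (grid - 620) / 80)^2)
  as.numeric(s / mean(s))
}

# ---- tissue classes -------------------------------------------------------

#' Tissue-class optical parameter defaults
#'
#' Invented but internally consistent per-class parameters for the
#' synthetic margins.  Constraints honoured: the adipose class band
#' averages match the printed worst-case crosstalk medium (mu_s' = 6.9,
#' mu_a = 4.6 cm^-1, the latter via its hemoglobin concentration), and the
#' median beta-carotene to scattering ratio is strictly ordered
#' adipose > fat+fibroglandular > fibroadipose > fibroglandular (> DCIS).
#' `musp` is the band-averaged reduced scattering; the spectral shape is a
#' power law `(lambda/550)^-b`.
#'
#' @return data.frame, one row per class.
#' @export
tissue_class_defaults <- function() {
  d <- data.frame(
    class = c("adipose", "fat_fibroglandular", "fibroadipose",
              "fibroglandular", "dcis"),
    bcar = c(18, 12, 8, 4.5, 3.5),          # uM
    musp = c(6.9, 8.2, 9.2, 10.8, 12.5),    # cm^-1 band average
    b = c(0.7, 1.0, 1.2, 1.4, 1.6),         # scattering power-law exponent
    hb = c(59.7, 45, 40, 35, 50),           # uM
    bcar_rel_sd = 0.15,
    musp_rel_sd = 0.08)
  d$ratio <- d$bcar / d$musp
  d
}

# Gaussian random field on an nr x nc grid via FFT smoothing of white noise,
# standardized to zero mean / unit sd. corr_px = correlation length in pixels.
gaussian_field <- function(nr, nc, corr_px) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  fx <- c(0:(floor(nr / 2)), -((ceiling(nr / 2) - 1):1)) / nr
  fy <- c(0:(floor(nc / 2)), -((ceiling(nc / 2) - 1):1)) / nc
  K <- exp(-2 * pi^2 * corr_px^2 * (outer(fx^2, fy^2, `+`)))
  s <- Re(fft(fft(z) * K, inverse = TRUE)) / (nr * nc)
  (s - mean(s)) / sd(s)
}

#' Generate a synthetic breast-margin specimen
#'
#' Tissue-class map on a fine grid with per-pixel true optical parameters
#' and a known boundary mask.  Class textures are thresholded Gaussian
#' random fields; high-breast-density (HBD) margins get a larger
#' fibroglandular area fraction than low-density (LBD) ones (defaults 0.55
#' vs 0.20).  Reproducible bit-for-bit from `seed`.
#'
#' @param stratum `"LBD"` or `"HBD"` (sets the default `fg_fraction`).
#' @param fg_fraction Fibroglandular area fraction inside the boundary;
#'   overrides the stratum default.
#' @param size_mm Square field of view, mm (probe footprint 42 mm).
#' @param pitch_mm Fine-grid pixel pitch, mm.
#' @param lesion Optional list `(diameter_mm, class, center_mm)` describing
#'   a focal patch (e.g. a DCIS-like inclusion >= 1 mm).
#' @param classes Class parameter table ([tissue_class_defaults()]).
#' @param corr_mm Texture correlation length, mm.
#' @param baseline_sd Relative sd of the long-range (12 mm correlation)
#'   baseline beta-carotene heterogeneity emulating inter-patient /
#'   inter-region variability in adipocyte carotenoid content -- the
#'   dominant spread of real margin landscapes and what lets volume
#'   averaging mask small inclusions at native resolution.
#' @param seed RNG seed.
#' @return A `qdri_margin`: `class_map` (character matrix; NA outside the
#'   specimen), true parameter fields `bcar`, `musp` (band average), `b`,
#'   `hb`, `ratio`, the boundary `mask`, and geometry metadata.
#' @export
generate_margin <- function(stratum = c("LBD", "HBD"), fg_fraction = NULL,
                            size_mm = 42, pitch_mm = 0.25, lesion = NULL,
                            classes = tissue_class_defaults(),
                            corr_mm = 3, baseline_sd = 0.35, seed = 1) {
  stratum <- match.arg(stratum)
  if (is.null(fg_fraction))
    fg_fraction <- if (stratum == "HBD") 0.55 else 0.20
  n <- round(size_mm / pitch_mm)
  with_seed(seed, {
    u <- gaussian_field(n, n, corr_mm / pitch_mm)
    # boundary: slightly irregular disc inscribed in the field of view
    cx <- size_mm / 2; cy <- size_mm / 2
    xs <- (col(u) - 0.5) * pitch_mm
    ys <- (row(u) - 0.5) * pitch_mm
    rad <- size_mm * 0.45 * (1 + 0.06 * gaussian_field(n, n, 8 / pitch_mm))
    mask <- sqrt((xs - cx)^2 + (ys - cy)^2) <= rad

    # class partition by quantiles of the texture field (inside the mask):
    # top fg_fraction -> fibroglandular, then thin transition bands.
    qs <- quantile(u[mask],
                   probs = c(1 - fg_fraction,
                             max(0, 1 - fg_fraction - 0.15),
                             max(0, 1 - fg_fraction - 0.25)))
    cls <- matrix(NA_character_, n, n)
    cls[mask] <- "adipose"
    cls[mask & u >= qs[3]] <- "fat_fibroglandular"
    cls[mask & u >= qs[2]] <- "fibroadipose"
    cls[mask & u >= qs[1]] <- "fibroglandular"

    if (!is.null(lesion)) {
      if (lesion$diameter_mm > size_mm) stop("lesion larger than margin")
      lc <- if (is.null(lesion$center_mm)) c(cx, cy) else lesion$center_mm
      inles <- sqrt((xs - lc[1])^2 + (ys - lc[2])^2) <= lesion$diameter_mm / 2
      if (!all(mask[inles])) stop("lesion must lie inside the boundary")
      cls[inles] <- lesion$class
    }

    # per-pixel truth: class means modulated by smooth lognormal texture
    tb <- classes[match(cls, classes$class), ]
    tex_b <- gaussian_field(n, n, 2 / pitch_mm)
    tex_s <- gaussian_field(n, n, 2 / pitch_mm)
    tex_base <- gaussian_field(n, n, 12 / pitch_mm)
    bcar <- matrix(tb$bcar * exp(tb$bcar_rel_sd * as.numeric(tex_b) -
                                   tb$bcar_rel_sd^2 / 2) *
                     exp(baseline_sd * as.numeric(tex_base) -
                           baseline_sd^2 / 2), n, n)
    musp <- matrix(tb$musp * exp(tb$musp_rel_sd * as.numeric(tex_s) -
                                   tb$musp_rel_sd^2 / 2), n, n)
    bexp <- matrix(tb$b, n, n)
    hb <- matrix(tb$hb, n, n)
    structure(list(class_map = cls, bcar = bcar, musp = musp, b = bexp,
                   hb = hb, ratio = bcar / musp, mask = mask,
                   size_mm = size_mm, pitch_mm = pitch_mm,
                   stratum = stratum, fg_fraction = fg_fraction,
                   lesion = lesion, seed = seed),
              class = "qdri_margin")
  })
}

#' Sample a margin truth field at probe resolution
#'
#' The acquisition resolution model: at upsample factor `n` each map pixel
#' covers a `(6/n) mm` square cell and reports the cell average of the fine
#' truth field (volume averaging is what masks small inclusions at low
#' resolution).  Cells whose centre is outside the specimen are NA.
#'
#' @param margin A [generate_margin()].
#' @param n Upsample factor.
#' @param what Field to sample (`"ratio"`, `"bcar"`, `"musp"`, `"hb"`,
#'   `"b"`).
#' @return `(7n) x (7n)` matrix with a `mask` attribute.
#' @export
sample_map <- function(margin, n = 8,
                       what = c("ratio", "bcar", "musp", "hb", "b")) {
  what <- match.arg(what)
  field <- margin[[what]]
  step <- 6 / n
  npx <- 7L * n
  fine <- margin$pitch_mm
  out <- matrix(NA_real_, npx, npx)
  msk <- matrix(FALSE, npx, npx)
  nf <- nrow(field)
  for (i in seq_len(npx)) {
    r0 <- floor((i - 1) * step / fine) + 1L
    r1 <- min(nf, max(r0, ceiling(i * step / fine)))
    for (j in seq_len(npx)) {
      c0 <- floor((j - 1) * step / fine) + 1L
      c1 <- min(nf, max(c0, ceiling(j * step / fine)))
      cell <- field[r0:r1, c0:c1]
      inm <- margin$mask[r0:r1, c0:c1]
      if (mean(inm) >= 0.5) {
        out[i, j] <- mean(cell[inm])
        msk[i, j] <- TRUE
      }
    }
  }
  attr(out, "mask") <- msk
  attr(out, "pitch_mm") <- step
  out
}

# ---- frame rendering ------------------------------------------------------

#' Instrument noise model
#'
#' @param drift_sd Per-snapshot multiplicative source drift (shared by the
#'   tissue channels and the matching self-calibration channel; the source
#'   specification bounds it at 2%, clinical scan-to-scan variation is
#'   ~0.9%).
#' @param noise_sd Per-wavelength multiplicative shot-like noise on tissue
#'   channels.
#' @param sc_noise_sd Noise on the (bright) self-calibration channels.
#' @param background Reflectance floor for channels off the specimen
#'   (model-scale reflectance for this probe geometry is ~1e-5, so the
#'   default floor is ~1% of a typical tissue signal).
#' @export
noise_model <- function(drift_sd = 0.009, noise_sd = 0.01,
                        sc_noise_sd = 0.001, background = 1e-7) {
  if (drift_sd < 0 || drift_sd > 0.02)
    stop("drift_sd must be within the source specification [0, 0.02]")
  structure(list(drift_sd = drift_sd, noise_sd = noise_sd,
                 sc_noise_sd = sc_noise_sd, background = background),
            class = "qdri_noise_model")
}

#' Forward reflectance spectrum for tissue parameters
#'
#' Evaluates the lookup-table forward model for the tissue
#' parameterization: `mu_s'(lambda) = a (lambda/lambda0)^-b` (normalized so
#' `musp` is the band average) and `mu_a` from hemoglobin plus
#' beta-carotene.
#'
#' @param lut Reflectance lookup table.
#' @param grid Wavelength grid.
#' @param library Absorber library on `grid`.
#' @param bcar,hb Concentrations, uM.
#' @param musp Band-averaged reduced scattering, cm^-1.
#' @param b Scattering power-law exponent.
#' @param lambda0 Reference wavelength, nm.
#' @export
tissue_reflectance <- function(lut, grid, library, bcar, hb, musp, b,
                               lambda0 = 550) {
  shape <- (grid / lambda0)^(-unname(b))
  musp_l <- unname(musp) * shape / band_average(shape, grid)
  mua_l <- absorption_spectrum(c(hb = unname(hb),
                                 beta_carotene = unname(bcar)),
                               library, grid)
  lut_reflectance(lut, musp_l, mua_l)
}

#' Render raw probe frames from a synthetic margin
#'
#' Evaluates the forward model at each channel's footprint-averaged true
#' properties, multiplies by the lamp spectral shape and a per-snapshot
#' drift factor (also applied to that parity's self-calibration channel),
#' and adds multiplicative shot-like noise.  Channels off the specimen see
#' a near-zero background.
#'
#' @param margin A [generate_margin()].
#' @param plan A [plan_raster()].
#' @param lut Reflectance lookup table ([build_reflectance_lut()]).
#' @param grid Wavelength grid.
#' @param noise A [noise_model()].
#' @param library Absorber library on `grid`.
#' @param seed RNG seed.
#' @return A `qdri_frames` object: list of frames, each with `spectra`
#'   (wavelength x 51 matrix: ch01..ch49, sc1, sc2), offsets `ix`, `iy`,
#'   per-parity drift factors, plus the plan and grid.
#' @export
render_frames <- function(margin, plan, lut, grid = wavelength_grid(),
                          noise = noise_model(),
                          library = absorber_library(grid), seed = 1) {
  arr <- probe_array()
  lamp <- lamp_spectrum(grid)
  nl <- length(grid)
  n <- plan$n
  frames <- vector("list", nrow(plan$offsets))
  with_seed(seed, {
    for (f in seq_len(nrow(plan$offsets))) {
      ix <- plan$offsets$ix[f]; iy <- plan$offsets$iy[f]
      spectra <- matrix(0, nl, 51L)
      colnames(spectra) <- c(sprintf("ch%02d", 1:49), "sc1", "sc2")
      drift <- 1 + rnorm(2) * noise$drift_sd  # odd snapshot, even snapshot
      for (r in 1:7) for (cc in 1:7) {
        ch <- arr$index[r, cc]
        par_i <- if (arr$parity[r, cc] == "odd") 1L else 2L
        val <- channel_footprint(margin, r, cc, ix, iy, n)
        if (is.null(val)) {
          refl <- rep(noise$background, nl)
        } else {
          refl <- tissue_reflectance(lut, grid, library, val["bcar"],
                                     val["hb"], val["musp"], val["b"])
        }
        spectra[, ch] <- pmax(0, refl * lamp * drift[par_i] *
                                (1 + rnorm(nl) * noise$noise_sd) +
                                noise$background * rnorm(nl) * 0.1)
      }
      spectra[, "sc1"] <- lamp * drift[1] * (1 + rnorm(nl) * noise$sc_noise_sd)
      spectra[, "sc2"] <- lamp * drift[2] * (1 + rnorm(nl) * noise$sc_noise_sd)
      frames[[f]] <- list(spectra = spectra, ix = ix, iy = iy, drift = drift)
    }
  })
  structure(list(frames = frames, plan = plan, grid = grid,
                 margin_meta = list(size_mm = margin$size_mm,
                                    stratum = margin$stratum),
                 noise = noise, seed = seed),
            class = "qdri_frames")
}

# Footprint-averaged true tissue parameters for channel (r, c) of the probe
# at sub-offset (ix, iy); NULL if the cell is off the specimen.
channel_footprint <- function(margin, r, cc, ix, iy, n) {
  step <- 6 / n
  fine <- margin$pitch_mm
  x0 <- (cc - 1) * 6 + ix * step; x1 <- x0 + step
  y0 <- (r - 1) * 6 + iy * step; y1 <- y0 + step
  c0 <- max(1L, floor(x0 / fine) + 1L); c1 <- min(ncol(margin$mask),
                                                  max(c0, ceiling(x1 / fine)))
  r0 <- max(1L, floor(y0 / fine) + 1L); r1 <- min(nrow(margin$mask),
                                                  max(r0, ceiling(y1 / fine)))
  inm <- margin$mask[r0:r1, c0:c1]
  if (mean(inm) < 0.5) return(NULL)
  c(bcar = mean(margin$bcar[r0:r1, c0:c1][inm]),
    musp = mean(margin$musp[r0:r1, c0:c1][inm]),
    b = mean(margin$b[r0:r1, c0:c1][inm]),
    hb = mean(margin$hb[r0:r1, c0:c1][inm]))
}

#' Render calibrated single-channel phantom spectra
#'
#' Raw (lamp-shaped, drifted, noisy) spectra plus the matching
#' self-calibration channel for each phantom of the dilution series, as
#' measured through one probe channel.  The forward model is the package's
#' own lookup table; the phantom scattering shape is the Mie spectrum of
#' the 1 um spheres and the absorption is the bundled hemoglobin spectrum.
#'
#' @param lut Reflectance lookup table.
#' @param grid Wavelength grid.
#' @param phantoms Phantom table ([phantom_specs()]).
#' @param noise A [noise_model()]; 1% multiplicative noise by default.
#' @param library Absorber library on `grid`.
#' @param seed RNG seed.
#' @return List with `raw` (wavelength x 12 matrix), `sc` (wavelength x 12),
#'   `true` model reflectance, the grid and the phantom table.
#' @export
render_phantom_spectra <- function(lut, grid = wavelength_grid(),
                                   phantoms = phantom_specs(),
                                   noise = noise_model(),
                                   library = absorber_library(grid),
                                   seed = 1) {
  shape <- phantom_musp_shape(grid)
  lamp <- lamp_spectrum(grid)
  nl <- length(grid)
  np <- nrow(phantoms)
  true <- raw <- sc <- matrix(0, nl, np)
  with_seed(seed, {
    for (i in seq_len(np)) {
      musp_l <- phantoms$musp[i] * shape
      mua_l <- absorption_spectrum(c(hb = phantoms$hb[i]), library, grid)
      true[, i] <- lut_reflectance(lut, musp_l, mua_l)
      drift <- 1 + rnorm(1) * noise$drift_sd
      raw[, i] <- true[, i] * lamp * drift * (1 + rnorm(nl) * noise$noise_sd)
      sc[, i] <- lamp * drift * (1 + rnorm(nl) * noise$sc_noise_sd)
    }
  })
  list(raw = raw, sc = sc, true = true, grid = grid, phantoms = phantoms,
       seed = seed)
}
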