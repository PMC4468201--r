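# Phantom table, synthetic margins, and the frame renderer.

test_that("the phantom dilution series satisfies its invariants", {
  ph <- phantom_specs()
  expect_equal(nrow(ph), 12)
  expect_true(all(diff(ph$musp) < 0))     # dilution lowers scattering
  expect_true(all(diff(ph$mua) > 0))      # aliquots raise absorption
  expect_true(all(diff(ph$hb) > 0))
  expect_equal(unlist(ph[1, c("musp", "mua", "hb")]),
               c(musp = 9.73, mua = 0, hb = 0))
  expect_equal(unlist(ph[12, c("musp", "mua", "hb")]),
               c(musp = 7.03, mua = 8.86, hb = 115.01))
})

test_that("tissue-class defaults honour the ratio ordering contract", {
  d <- tissue_class_defaults()
  r <- d$ratio[match(c("adipose", "fat_fibroglandular", "fibroadipose",
                       "fibroglandular"), d$class)]
  expect_true(all(diff(r) < 0))
  # adipose band averages match the worst-case crosstalk medium
  expect_equal(d$musp[d$class == "adipose"], 6.9)
  expect_equal(log(10) * 33458.5 * d$hb[d$class == "adipose"] * 1e-6, 4.6,
               tolerance = 0.01)
})

test_that("margins are reproducible bit-for-bit from the seed", {
  a <- generate_margin("HBD", seed = 21)
  b <- generate_margin("HBD", seed = 21)
  expect_identical(a, b)
  c <- generate_margin("HBD", seed = 22)
  expect_false(identical(a$ratio, c$ratio))
})

test_that("HBD margins sit left of LBD margins in true ratio", {
  mh <- generate_margin("HBD", seed = 5)
  ml <- generate_margin("LBD", seed = 6)
  expect_lt(median(mh$ratio[mh$mask]), median(ml$ratio[ml$mask]))
  expect_gt(mean(mh$class_map[mh$mask] == "fibroglandular"),
            mean(ml$class_map[ml$mask] == "fibroglandular"))
})

test_that("pooled class landscapes are separable (KS D > 0.5)", {
  m <- generate_margin("LBD", seed = 8)
  ad <- m$ratio[m$class_map == "adipose" & m$mask]
  fg <- m$ratio[m$class_map == "fibroglandular" & m$mask]
  expect_gt(ks_two_sample(ad, fg)$D, 0.5)
})

test_that("a focal lesion occupies the expected pixel count", {
  les <- list(diameter_mm = 1.5, class = "dcis", center_mm = c(21, 21))
  m <- generate_margin("LBD", lesion = les, seed = 30)
  npix <- sum(m$class_map == "dcis", na.rm = TRUE)
  want <- pi * (1.5 / 2 / 0.25)^2          # ~28 fine pixels
  expect_gt(npix, want * 0.7)
  expect_lt(npix, want * 1.3)
  expect_true(all(m$mask[which(m$class_map == "dcis")]))
  expect_error(generate_margin("LBD", lesion = list(diameter_mm = 100,
                                                    class = "dcis")),
               "larger than margin")
})

test_that("frame rendering applies drift to channel and SC alike", {
  lut <- shared_lut(); grid <- shared_grid(); lib <- shared_library()
  m <- generate_margin("LBD", seed = 3)
  plan <- plan_raster(1)
  quiet <- noise_model(drift_sd = 0.015, noise_sd = 0, sc_noise_sd = 0)
  fr <- render_frames(m, plan, lut, grid, noise = quiet, library = lib,
                      seed = 9)
  f <- fr$frames[[1]]
  arr <- probe_array()
  # frame/SC ratio is drift-free: it equals the model reflectance
  r <- 4; cc <- 4   # center channel, odd parity
  val <- qdri:::channel_footprint(m, r, cc, 0, 0, 1)
  model <- tissue_reflectance(lut, grid, lib, val["bcar"], val["hb"],
                              val["musp"], val["b"]) * lamp_spectrum(grid)
  got <- f$spectra[, arr$index[r, cc]] / f$spectra[, "sc1"]
  expect_equal(got, model / lamp_spectrum(grid), tolerance = 1e-4)
  # and the raw channel does carry the drift factor
  expect_equal(f$spectra[, "sc1"], lamp_spectrum(grid) * f$drift[1])
})

test_that("replicate renders with 0.9% drift reproduce ~0.9% RSD", {
  lut <- shared_lut(); grid <- shared_grid(); lib <- shared_library()
  m <- generate_margin("LBD", seed = 3)
  plan <- plan_raster(4)
  nm <- noise_model(drift_sd = 0.009)
  maps <- lapply(1:3, function(k)
    frames_band_map(render_frames(m, plan, lut, grid, noise = nm,
                                  library = lib, seed = 200 + k)))
  msk <- maps[[1]] > 1e-6
  stack <- lapply(maps, function(x) { x[!msk] <- NA; x })
  expect_lt(abs(as.numeric(rsd(stack)) - 0.9), 0.25)
})

test_that("full-pipeline recovery: render, invert, stitch, ratio (scaled down)", {
  # production claim is n = 8; run at n = 2 to keep the suite fast --- the
  # per-pixel fit problem is identical, only the pixel count changes
  lut <- shared_lut(); grid <- wavelength_grid(by = 5)
  lib <- absorber_library(grid)
  m <- generate_margin("LBD", seed = 3)
  plan <- plan_raster(2)
  fr <- render_frames(m, plan, lut, grid, library = lib, seed = 5)
  ph <- phantom_specs()
  sp <- render_phantom_spectra(lut, grid, library = lib, seed = 6)
  shape <- phantom_musp_shape(grid)
  ref <- list(raw = sp$raw[, 5], sc = sp$sc[, 5],
              model = lut_reflectance(lut, ph$musp[5] * shape,
                                      absorption_spectrum(c(hb = ph$hb[5]),
                                                          lib, grid)))
  inv <- invert_frames(fr, ref, lut, library = lib)
  maps <- lapply(c(bcar = "bcar", musp = "musp"), function(nm)
    stitch(lapply(inv, function(f)
      list(ix = f$ix, iy = f$iy, values = f[[nm]])), plan))
  got <- ratio_map(maps$bcar, maps$musp)
  truth <- sample_map(m, 2)
  ok <- is.finite(got) & attr(truth, "mask")
  expect_gt(sum(ok), 80)
  err <- abs(got[ok] - truth[ok]) / truth[ok]
  expect_lt(median(err), 0.05)
})
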