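# Monte Carlo photon transport and the single-baseline scaling model.
# Photon counts are reduced from production values for test runtime; all
# stochastic comparisons use block standard errors.

test_that("energy is conserved in the transport ledger", {
  med <- make_medium(optical_layer(mua = 1, mus = 50, g = 0.8, n = 1.37))
  sim <- run_mc(med, 2e4, seed = 5)
  led <- sim$ledger
  total <- sum(led[c("specular", "diffuse", "transmitted", "absorbed",
                     "lost", "roulette_loss")]) - led[["roulette_gain"]]
  expect_lt(abs(total - sim$n_photons) / sim$n_photons, 1e-9)
  expect_true(all(sim$records$weight > 0 & sim$records$weight <= 1))
  expect_true(all(sim$records$radius >= 0))
  expect_true(all(sim$records$path >= 0))
})

test_that("identical (medium, n_photons, seed) gives identical records", {
  med <- make_medium(optical_layer(mua = 0.5, mus = 60, g = 0.9))
  a <- run_mc(med, 5000, seed = 77)
  b <- run_mc(med, 5000, seed = 77)
  expect_identical(a$records, b$records)
  c <- run_mc(med, 5000, seed = 78)
  expect_false(identical(a$records$radius, c$records$radius))
})

test_that("index-matched non-absorbing medium returns all light", {
  med <- make_medium(optical_layer(mua = 0, mus = 30, g = 0.8, n = 1.0),
                     n_ambient = 1.0)
  sim <- run_mc(med, 1e4, seed = 3, z_kill_cm = 100, r_kill_cm = 1e4)
  expect_gt(sim$ledger[["diffuse"]] / sim$n_photons, 0.99)
  expect_equal(sim$ledger[["specular"]], 0)
})

test_that("channel reflectance strictly decreases with absorption", {
  refs <- lapply(c(0.5, 2, 5), function(mua) {
    d <- run_mc(make_medium(optical_layer(mua = mua, mus = 90, g = 0.9)),
                1.5e5, seed = 21)
    reflectance_with_se(d$records, n_photons = d$n_photons)
  })
  for (i in 1:2) {
    gap <- refs[[i]]$reflectance - refs[[i + 1]]$reflectance
    se <- sqrt(refs[[i]]$se^2 + refs[[i + 1]]$se^2)
    expect_gt(gap, 3 * se)
  }
})

test_that("scaling to the baseline properties is the identity, bit for bit", {
  b <- shared_baseline()
  sc <- scale_to_target(b, b$baseline$musp, 0)
  expect_identical(sc$radius, b$records$radius)
  expect_identical(sc$weight, b$records$weight)
  r0 <- channel_reflectance(b$records, n_photons = b$n_photons)
  expect_identical(channel_reflectance(sc), r0)
})

test_that("absorption scaling reweights a single record by exp(-mua*l)", {
  fake <- structure(list(
    records = list(radius = 0.05, cos_exit = 1, weight = 0.8,
                   path = matrix(2.5, 1, 1)),
    n_photons = 1L,
    baseline = list(musp = 9, mus = 90, g = 0.9, n_medium = 1.37)),
    class = c("qdri_baseline", "qdri_mc"))
  sc <- scale_to_target(fake, 9, 1.3)
  expect_equal(sc$weight, 0.8 * exp(-1.3 * 2.5))
  # radius and path scale with the interaction-coefficient ratio
  sc2 <- scale_to_target(fake, 4.5, 0)
  expect_equal(sc2$radius, 0.10)
  expect_equal(sc2$pathlen, 5.0)
  expect_error(scale_to_target(fake, 9, -1), "mua")
  expect_warning(scale_to_target(fake, 9, 20), "validated scaling range")
})

test_that("scaled reflectance matches direct simulation within 3 SE", {
  b <- shared_baseline()
  for (pair in list(c(9.73, 1.07), c(7.03, 8.86))) {
    s <- reflectance_with_se(scale_to_target(b, pair[1], pair[2]))
    d <- run_mc(make_medium(optical_layer(mua = pair[2],
                                          mus = pair[1] / 0.1, g = 0.9)),
                8e4, seed = 31)
    dr <- reflectance_with_se(d$records, n_photons = d$n_photons)
    expect_lt(abs(s$reflectance - dr$reflectance),
              3 * sqrt(s$se^2 + dr$se^2))
  }
})

test_that("with NA = 1 and an unbounded detector all exit weight is seen", {
  b <- shared_baseline()
  got <- channel_reflectance(b$records, n_photons = b$n_photons,
                             na = 1, det_radius_cm = Inf, rmax_cm = 3.5)
  expect_equal(got, sum(b$records$weight) / b$n_photons, tolerance = 1e-12)
  expect_error(channel_reflectance(list(weight = numeric(0))), "empty")
})

test_that("convolution collection agrees with an explicit-geometry run", {
  # oracle: launch photons uniformly over a source fiber disc and collect
  # explicitly over the detector disc at the source-detector separation
  geom <- probe_geometry()
  med <- make_medium(optical_layer(mua = 2, mus = 90, g = 0.9))
  d <- run_mc(med, 1.2e5, seed = 41, launch_radius_cm = geom$fiber_radius_cm)
  cos_min <- sqrt(1 - geom$na^2)
  hit <- (d$records$x - geom$sds_cm)^2 + d$records$y^2 <=
    geom$fiber_radius_cm^2 & d$records$cos_exit >= cos_min
  blocks <- ceiling(seq_along(d$records$weight) / (length(d$records$weight) / 25))
  per_block <- vapply(1:25, function(k)
    sum(d$records$weight[hit & blocks == k]) / (d$n_photons / 25), numeric(1))
  explicit <- mean(per_block)
  explicit_se <- sd(per_block) / sqrt(25)

  p <- run_mc(med, 1.2e5, seed = 42)
  conv <- reflectance_with_se(p$records, geometry = geom,
                              n_photons = p$n_photons)
  expect_lt(abs(explicit - conv$reflectance),
            3 * sqrt(explicit_se^2 + conv$se^2))
})

test_that("a thin scattering layer over a dark slab reads darker than a thick one", {
  # total diffuse reflectance (which samples past the margin depth) drops
  # when the absorbing slab sits closer to the surface
  top <- function(th) optical_layer(mua = 0.5, mus = 90, g = 0.9,
                                    thickness_cm = th)
  dark <- optical_layer(mua = 20, mus = 50, g = 0.9)
  rd <- lapply(c(0.2, 0.4), function(th) {
    d <- run_mc(make_medium(top(th), dark), 6e4, seed = 55)
    blk <- ceiling(seq_along(d$records$weight) /
                     (length(d$records$weight) / 25))
    per <- vapply(1:25, function(k)
      sum(d$records$weight[blk == k]) * 25 / d$n_photons, numeric(1))
    list(rd = mean(per), se = sd(per) / sqrt(25))
  })
  expect_gt(rd[[2]]$rd - rd[[1]]$rd,
            3 * sqrt(rd[[1]]$se^2 + rd[[2]]$se^2))
})

test_that("crosstalk vanishes at very large pitch and rejects bad pitch", {
  b <- shared_baseline()
  ct <- crosstalk_fraction(b$baseline$musp, 4.6, pitch_mm = 60,
                           baseline = b)
  expect_lt(ct$percent, 0.01)
  expect_error(crosstalk_fraction(9, 4.6, pitch_mm = 0, baseline = b),
               "pitch")
})

test_that("lookup table interpolates the scaled model", {
  b <- shared_baseline()
  lut <- shared_lut()
  # exact at a grid node
  i <- which(lut$musp_grid == 8)[1]; j <- which(lut$mua_grid == 1)[1]
  expect_equal(lut_reflectance(lut, 8, 1), lut$R[i, j])
  # close to a freshly scaled value off-node
  direct <- channel_reflectance(scale_to_target(b, 8.4, 3.3))
  expect_equal(lut_reflectance(lut, 8.4, 3.3), direct, tolerance = 0.02)
  # monotone in absorption along a table row
  expect_true(all(diff(lut$R[i, ]) < 0))
})

test_that("baseline cache round-trips through the plain-text format", {
  b <- mc_baseline(musp = 8, n_photons = 2000, seed = 9)
  dir <- tempfile("cache")
  save_baseline(b, dir)
  b2 <- load_baseline(dir)
  expect_equal(b2$records$radius, b$records$radius)
  expect_equal(b2$baseline$musp, 8)
  expect_equal(rowSums(b$records$path), b2$records$path[, 1])
  expect_equal(channel_reflectance(scale_to_target(b2, 8, 2)),
               channel_reflectance(scale_to_target(b, 8, 2)))
})
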