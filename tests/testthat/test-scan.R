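# Raster planning, stitching, parity, segmentation, SNR/RSD utilities.

test_that("raster plans reproduce the probe arithmetic", {
  p6 <- plan_raster(6)
  expect_equal(nrow(p6$offsets), 36)
  expect_equal(p6$step_mm, 1)
  p1 <- plan_raster(1)
  expect_equal(nrow(p1$offsets), 1)
  expect_equal(p1$step_mm, 6)
  p8 <- plan_raster(8)
  expect_equal(nrow(p8$offsets), 64)
  expect_equal(p8$step_mm, 0.75)
  expect_error(plan_raster(0), "positive integer")
  expect_error(plan_raster(2.5), "positive integer")
  # offsets form a regular n x n sub-grid regardless of serpentine order
  expect_setequal(paste(p6$offsets$ix, p6$offsets$iy),
                  paste(rep(0:5, 6), rep(0:5, each = 6)))
})

test_that("parity partitions the 49 channels 25/24 and is rotation-invariant", {
  arr <- probe_array()
  ps <- parity_split(arr)
  expect_length(ps$odd, 25)
  expect_length(ps$even, 24)
  expect_length(intersect(ps$odd, ps$even), 0)
  expect_setequal(c(ps$odd, ps$even), 1:49)
  # center channel (4,4) = channel 25 belongs to the odd (SC1) group
  expect_true(25 %in% ps$odd)
  # checkerboard is invariant under 180-degree rotation of the array
  rot <- arr$parity[7:1, 7:1]
  expect_identical(rot, arr$parity)
})

test_that("stitching is a bijection and spans 42 mm at any n", {
  for (n in c(1, 3, 8)) {
    plan <- plan_raster(n)
    frames <- lapply(seq_len(nrow(plan$offsets)), function(f) {
      list(ix = plan$offsets$ix[f], iy = plan$offsets$iy[f],
           values = matrix(f * 100 + 1:49, 7, 7, byrow = TRUE))
    })
    map <- stitch(frames, plan)
    expect_equal(dim(map), c(7 * n, 7 * n))
    expect_false(anyNA(map))
    expect_equal(attr(map, "pitch_mm") * nrow(map), 42)
    back <- unstitch(map, plan)
    for (f in seq_along(frames))
      expect_identical(back[[f]]$values, frames[[f]]$values)
  }
  expect_equal(prod(dim(stitch(lapply(1:64, function(f) {
    p <- plan_raster(8)
    list(ix = p$offsets$ix[f], iy = p$offsets$iy[f], values = matrix(0, 7, 7))
  }), plan_raster(8)))), 3136)
})

test_that("stitching validates offsets and constant fields stay constant", {
  plan <- plan_raster(2)
  frames <- lapply(1:4, function(f)
    list(ix = plan$offsets$ix[f], iy = plan$offsets$iy[f],
         values = matrix(5, 7, 7)))
  map <- stitch(frames, plan)
  expect_equal(sd(map), 0)
  expect_error(stitch(frames[c(1, 1, 2, 3)], plan), "duplicate")
  expect_error(stitch(frames[1:3], plan), "expected 4 frames")
  bad <- frames; bad[[1]]$ix <- 5
  expect_error(stitch(bad, plan), "do not match")
})

test_that("a 1.5 mm checkerboard is recovered at n = 8 but aliased at n = 1", {
  # synthetic fine field sampled through the acquisition (cell-average) model
  fine <- 0.25
  npx <- round(42 / fine)
  xs <- (col(matrix(0, npx, npx)) - 0.5) * fine
  ys <- (row(matrix(0, npx, npx)) - 0.5) * fine
  lev <- c(1, 3)
  field <- matrix(lev[1 + (floor(xs / 1.5) + floor(ys / 1.5)) %% 2], npx, npx)
  m <- structure(list(ratio = field, mask = matrix(TRUE, npx, npx),
                      pitch_mm = fine, size_mm = 42),
                 class = "qdri_margin")
  truth_at <- function(n) {
    step <- 6 / n
    cx <- (col(matrix(0, 7 * n, 7 * n)) - 0.5) * step
    cy <- (row(matrix(0, 7 * n, 7 * n)) - 0.5) * step
    matrix(lev[1 + (floor(cx / 1.5) + floor(cy / 1.5)) %% 2], 7 * n, 7 * n)
  }
  correct <- function(n) {
    got <- sample_map(m, n)
    mean(abs(got - truth_at(n)) < 0.25 * diff(lev))
  }
  expect_gte(correct(8), 0.95)
  expect_lt(correct(1), 0.5)   # cell averages sit at the midpoint
})

test_that("segmentation recovers a known boundary", {
  # uniform disc on zero background
  d <- matrix(0, 48, 48)
  d[(row(d) - 24)^2 + (col(d) - 24)^2 <= 15^2] <- 2
  seg <- segment_margin(d)
  expect_equal(seg, d > 0)
  # synthetic margin at n = 8 with 1% noise: Jaccard >= 0.95
  mg <- generate_margin("LBD", seed = 9)
  truth <- sample_map(mg, 8, "musp")
  tm <- attr(truth, "mask")
  map <- truth; map[!tm] <- 0
  set.seed(31)
  map <- map * (1 + 0.01 * rnorm(length(map)))
  seg <- segment_margin(map)
  expect_gte(sum(seg & tm) / sum(seg | tm), 0.95)
  # all-background map: empty mask with a warning
  expect_warning(empty <- segment_margin(matrix(0, 20, 20)), "empty mask")
  expect_false(any(empty))
})

test_that("SNR follows the printed mean/variance formula", {
  # deterministic stack with known mean and variance
  mu <- 30000; d <- 900
  x <- rbind(mu - d, mu, mu + d)[, c(1, 1, 1)]
  expect_equal(snr_db(x), rep(20 * log10(mu / d^2), 3))
  expect_equal(snr_db(x, formula = "mean_sd"), rep(20 * log10(mu / d), 3))
  # zero variance reported as +Inf sentinel
  expect_equal(snr_db(rbind(c(1, 2), c(1, 2))), c(Inf, Inf))
  # simulated Gaussian stack matches the closed form to 0.1 dB
  set.seed(8)
  n <- 1e5
  g <- matrix(rnorm(3 * n, mean = mu, sd = 30), n, 3)
  expect_lt(max(abs(snr_db(g) - 20 * log10(mu / 30^2))), 0.1)
  expect_error(snr_db(matrix(1, 1, 3)), ">= 2 replicates")
})

test_that("RSD reports replicate-scan variation in percent", {
  m0 <- matrix(runif(400, 1, 2), 20, 20)
  expect_equal(as.numeric(rsd(list(m0, m0, m0))), 0)
  # known multiplicative jitter of 0.9%
  set.seed(12)
  reps <- lapply(1:3, function(k) m0 * (1 + 0.009 * matrix(rnorm(400), 20)))
  r <- as.numeric(rsd(reps))
  expect_lt(abs(r - 0.9), 0.2)
  # zero-mean pixels are masked, not propagated
  m1 <- m0; m1[1, 1] <- 0
  r2 <- rsd(list(m1, m1 * 1.01, m1 * 0.99))
  expect_true(is.na(attr(r2, "pixelwise")[1, 1]))
  expect_true(is.finite(as.numeric(r2)))
  expect_error(rsd(list(m0)), ">= 2 replicate")
})
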