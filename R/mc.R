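# Forward Monte Carlo photon transport for the 8-around-1 fiber channel and
# the single-baseline ("scalable") reflectance model built on it.
#
# Units: lengths in cm internally; probe dimensions are specified in the
# units the instrument is described in (um for fibers, mm for channel pitch)
# and converted once here.

#' Probe channel geometry
#'
#' One channel of the imaging probe: 8 illumination fibers on a ring around a
#' single detection fiber.  Defaults follow the clinical probe: 200 um
#' fibers, NA 0.22, 700 um center-to-center source--detector separation,
#' channels on a 6 mm pitch.
#'
#' @param sds_um Source--detector separation (ring radius), um.
#' @param fiber_diameter_um Fiber core diameter, um (both source and
#'   detection fibers).
#' @param na Numerical aperture (acceptance applied in air above the
#'   medium).
#' @param n_illumination Number of illumination fibers per channel.
#' @param pitch_mm Inter-channel spacing, mm.
#' @export
probe_geometry <- function(sds_um = 700, fiber_diameter_um = 200, na = 0.22,
                           n_illumination = 8, pitch_mm = 6) {
  if (sds_um <= fiber_diameter_um / 2)
    stop("sds must exceed the fiber radius")
  if (pitch_mm <= 0) stop("pitch must be > 0")
  if (na <= 0 || na > 1) stop("NA must be in (0, 1]")
  structure(list(sds_cm = sds_um * 1e-4,
                 fiber_radius_cm = fiber_diameter_um / 2 * 1e-4,
                 na = na,
                 n_illumination = as.integer(n_illumination),
                 pitch_cm = pitch_mm / 10),
            class = "qdri_geometry")
}

#' Homogeneous medium layer
#'
#' @param mua,mus Absorption and scattering coefficients, cm^-1.
#' @param g Henyey--Greenstein anisotropy, in (-1, 1).
#' @param n Refractive index (tissue default 1.37).
#' @param thickness_cm Layer thickness, cm; `Inf` for the semi-infinite
#'   bottom layer.
#' @export
optical_layer <- function(mua, mus, g = 0.9, n = 1.37, thickness_cm = Inf) {
  if (mua < 0 || mus <= 0) stop("need mua >= 0 and mus > 0")
  if (g <= -1 || g >= 1) stop("g must be in (-1, 1)")
  if (n < 1) stop("refractive index must be >= 1")
  if (thickness_cm <= 0) stop("thickness must be > 0")
  structure(list(mua = mua, mus = mus, g = g, n = n,
                 thickness_cm = thickness_cm), class = "qdri_layer")
}

#' Layered medium
#'
#' @param ... [optical_layer()]s ordered from the surface down; the last must
#'   be semi-infinite (infinite thickness) unless transmission through a slab
#'   is intended.
#' @param n_ambient Refractive index above the medium (air by default; NA
#'   acceptance is applied there).
#' @export
make_medium <- function(..., n_ambient = 1.0) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1]]) &&
      !inherits(layers[[1]], "qdri_layer")) layers <- layers[[1]]
  if (!length(layers)) stop("need at least one layer")
  ok <- vapply(layers, inherits, logical(1), "qdri_layer")
  if (!all(ok)) stop("all layers must be optical_layer objects")
  fin <- vapply(head(layers, -1L), function(l) is.finite(l$thickness_cm),
                logical(1))
  if (length(fin) && !all(fin))
    stop("only the last layer may be semi-infinite")
  structure(list(layers = layers, n_ambient = n_ambient),
            class = "qdri_medium")
}

medium_matrix <- function(medium) {
  t(vapply(medium$layers, function(l)
    c(l$mua, l$mus, l$g, l$n, l$thickness_cm), numeric(5)))
}

#' Run the forward Monte Carlo simulation
#'
#' Hop--drop--spin photon transport with Henyey--Greenstein scattering,
#' Fresnel reflection/refraction at every index boundary and Russian-roulette
#' termination.  Photons are launched as a pencil beam at the origin (or
#' uniformly over a source disc when `launch_radius_cm > 0`, the explicit
#' direct-geometry mode used as a validation oracle).  Every photon exiting
#' the top surface is recorded (exit position, direction cosine after
#' refraction into the ambient medium, residual weight, per-layer path
#' length); the run is reproducible for a fixed seed.
#'
#' @param medium A [make_medium()] object.
#' @param n_photons Number of photons (>= 1; production baselines use
#'   >= 1e5).
#' @param seed Integer RNG seed (the engine has its own deterministic RNG
#'   and does not touch R's).
#' @param w_min,p_survive Roulette threshold and survival probability.
#' @param z_kill_cm,r_kill_cm,max_steps Termination safeguards: photons
#'   deeper than `z_kill_cm`, farther than `r_kill_cm` laterally, or past
#'   `max_steps` interactions are dropped into the `lost` ledger entry.
#' @param launch_radius_cm Source disc radius for the explicit-geometry
#'   mode; 0 = pencil beam.
#' @return A `qdri_mc` object: `records` (data.frame radius, x, y, cos_exit,
#'   weight, path length per layer), `ledger` (specular, diffuse,
#'   transmitted, absorbed, lost, roulette terms; together with the records
#'   they conserve launched weight exactly), the medium and run metadata.
#' @export
run_mc <- function(medium, n_photons, seed, w_min = 1e-4, p_survive = 0.1,
                   z_kill_cm = 2, r_kill_cm = 3, max_steps = 1e7,
                   launch_radius_cm = 0) {
  if (!inherits(medium, "qdri_medium")) stop("medium must be a qdri_medium")
  n_photons <- as.integer(n_photons)
  if (is.na(n_photons) || n_photons < 1) stop("n_photons must be >= 1")
  res <- run_mc_cpp(medium_matrix(medium), medium$n_ambient, n_photons,
                    as.integer(seed), w_min, p_survive, z_kill_cm, r_kill_cm,
                    max_steps, launch_radius_cm)
  structure(list(records = list(radius = res$radius, x = res$x, y = res$y,
                                cos_exit = res$cos_exit, weight = res$weight,
                                path = res$path),
                 ledger = res$ledger,
                 medium = medium, n_photons = n_photons, seed = seed,
                 w_min = w_min, p_survive = p_survive,
                 z_kill_cm = z_kill_cm, r_kill_cm = r_kill_cm),
            class = "qdri_mc")
}

#' @export
print.qdri_mc <- function(x, ...) {
  cat("qdri Monte Carlo run:", x$n_photons, "photons,",
      length(x$records$weight), "exit records\n")
  cat("  diffuse reflectance:",
      signif(x$ledger[["diffuse"]] / x$n_photons, 4), "\n")
  invisible(x)
}

#' Baseline simulation for the scalable reflectance model
#'
#' Runs a zero-absorption Monte Carlo simulation at a fixed reduced
#' scattering and anisotropy.  Its exit records can then be rescaled to any
#' target optical properties by [scale_to_target()], which is orders of
#' magnitude cheaper than a fresh simulation per property pair.
#'
#' @param musp Baseline reduced scattering, cm^-1 (mu_s = musp / (1 - g)).
#' @param g Anisotropy (tissue default 0.9).
#' @param n_medium Medium refractive index.
#' @param n_photons,seed,... Passed to [run_mc()].
#' @return A `qdri_baseline` (a `qdri_mc` with baseline metadata).
#' @export
mc_baseline <- function(musp = 9, g = 0.9, n_medium = 1.37,
                        n_photons = 1e6, seed = 1, ...) {
  med <- make_medium(optical_layer(mua = 0, mus = musp / (1 - g), g = g,
                                   n = n_medium))
  sim <- run_mc(med, n_photons, seed, ...)
  sim$baseline <- list(musp = musp, mus = musp / (1 - g), g = g,
                       n_medium = n_medium)
  class(sim) <- c("qdri_baseline", class(sim))
  sim
}

# Validated scaling envelope: the phantom-table property range +/- 50%.
.scaling_range <- list(musp = c(7.03, 9.73) * c(0.5, 1.5),
                       mua = c(0, 8.86 * 1.5))

#' Scale a baseline simulation to target optical properties
#'
#' Similarity scaling of a zero-absorption baseline: for a target with the
#' same anisotropy, exit radii and path lengths scale by the ratio of
#' baseline to target interaction (scattering) coefficient and each record
#' is reweighted by `exp(-mua * path)` for the target absorption.  Exact in
#' distribution for a homogeneous semi-infinite medium with fixed g.
#'
#' @param baseline A [mc_baseline()] result.
#' @param musp Target reduced scattering, cm^-1.
#' @param mua Target absorption, cm^-1 (>= 0).
#' @return Scaled record set (list with radius, cos_exit, weight, pathlen,
#'   n_photons) suitable for [channel_reflectance()].
#' @export
scale_to_target <- function(baseline, musp, mua) {
  if (!inherits(baseline, "qdri_baseline"))
    stop("baseline must come from mc_baseline()")
  stopifnot_scalar_number(musp, "musp", lo = 1e-6)
  if (!is.numeric(mua) || length(mua) != 1L || is.na(mua) || mua < 0)
    stop("mua must be a single number >= 0")
  if (musp < .scaling_range$musp[1] || musp > .scaling_range$musp[2] ||
      mua > .scaling_range$mua[2])
    warning("target (musp = ", musp, ", mua = ", mua,
            ") is outside the validated scaling range; ",
            "prefer a direct run_mc() simulation")
  rscale <- baseline$baseline$musp / musp
  L <- rowSums(baseline$records$path) * rscale
  list(radius = baseline$records$radius * rscale,
       cos_exit = baseline$records$cos_exit,
       weight = baseline$records$weight * exp(-mua * L),
       pathlen = L,
       n_photons = baseline$n_photons)
}

# ---- geometric collection over the probe face -----------------------------

# Equal-weight quadrature nodes over a disc of radius R (equal-area rings).
disc_points <- function(R, nr = 2, nang = 6) {
  radii <- R * sqrt((seq_len(nr) - 0.5) / nr)
  out <- lapply(seq_len(nr), function(i) {
    th <- 2 * pi * (seq_len(nang) - 1) / nang + (i - 1) * pi / nang
    cbind(radii[i] * cos(th), radii[i] * sin(th))
  })
  do.call(rbind, out)
}

# Fraction of a circle of radius r, centred at distance d from the axis of a
# detector disc of radius R, that lies inside the disc (thin-annulus overlap).
arc_fraction <- function(r, d, R) {
  if (!is.finite(R)) return(rep(1, length(r)))
  out <- numeric(length(r))
  inside <- r <= R - d           # annulus fully inside the disc
  outside <- r >= R + d          # fully outside
  mid <- !inside & !outside & r > 0
  out[inside] <- 1
  if (any(mid)) {
    cosv <- (d^2 + r[mid]^2 - R^2) / (2 * d * r[mid])
    cosv <- pmin(1, pmax(-1, cosv))
    out[mid] <- acos(cosv) / pi
  }
  if (d <= R) out[r == 0] <- 1
  out
}

# Radial histogram of exit weights (NA-filtered), bin width dr out to
# nbins * dr.  Records carry one row per exiting photon.
collect_weights <- function(records, dr, nbins, na = 1, n_ambient = 1) {
  keep <- rep(TRUE, length(records$weight))
  if (na < 1) {
    cos_min <- sqrt(1 - min(1, (na / n_ambient))^2)
    keep <- records$cos_exit >= cos_min
  }
  b <- floor(records$radius[keep] / dr) + 1
  w <- records$weight[keep]
  ok <- b >= 1 & b <= nbins
  W <- numeric(nbins)
  if (any(ok)) {
    agg <- rowsum(w[ok], b[ok])
    W[as.integer(rownames(agg))] <- agg[, 1]
  }
  W
}

# Expected collected weight for a single source fiber whose centre is at
# distance d from the detection fiber axis: thin-annulus overlap of the
# radial exit histogram with the detector disc, averaged over quadrature
# points on the source fiber face.
fiber_signal <- function(W, dr, d, det_radius, src_radius) {
  rmid <- (seq_along(W) - 0.5) * dr
  if (src_radius > 0) {
    pts <- disc_points(src_radius)
    dists <- sqrt((d + pts[, 1])^2 + pts[, 2]^2)
  } else dists <- d
  acc <- 0
  for (dd in dists) acc <- acc + sum(W * arc_fraction(rmid, dd, det_radius))
  acc / length(dists)
}

#' Per-channel reflectance from exit records
#'
#' Integrates the radially binned exit weight over the detection fiber face
#' for each of the ring of illumination fibers (pencil-beam convolution),
#' after NA acceptance on the exit angle.  For a homogeneous medium all
#' ring fibers are equivalent by symmetry, so the channel reflectance equals
#' the single-fiber collected fraction.
#'
#' @param records Scaled records from [scale_to_target()] or the `records`
#'   of a [run_mc()] result (then give `n_photons`).
#' @param geometry A [probe_geometry()].
#' @param n_photons Launched photon count (taken from `records` if present).
#' @param na Acceptance NA; use 1 to accept all exit angles.
#' @param det_radius_cm Detection fiber radius; `Inf` collects everything.
#' @param dr,rmax_cm Radial histogram bin width and extent (10 um bins to
#'   2 cm by default; exits beyond `rmax_cm` are not collectable).
#' @return Dimensionless channel reflectance (collected / launched weight).
#' @export
channel_reflectance <- function(records, geometry = probe_geometry(),
                                n_photons = records$n_photons,
                                na = geometry$na,
                                det_radius_cm = geometry$fiber_radius_cm,
                                dr = 0.001, rmax_cm = 2) {
  if (is.null(records$weight) || !length(records$weight))
    stop("empty record set")
  if (is.null(n_photons)) stop("n_photons not supplied")
  nbins <- ceiling(rmax_cm / dr)
  W <- collect_weights(records, dr, nbins, na = na)
  s <- fiber_signal(W, dr, geometry$sds_cm, det_radius_cm,
                    src_radius = geometry$fiber_radius_cm)
  s / n_photons
}

#' Channel reflectance with a Monte Carlo standard error
#'
#' Splits the exit records into photon blocks and reports the block-mean
#' channel reflectance with its standard error, used wherever estimates
#' must be compared "beyond k standard errors".
#'
#' @inheritParams channel_reflectance
#' @param n_blocks Number of photon blocks.
#' @param ... Passed to [channel_reflectance()].
#' @return List with `reflectance`, `se` and the per-block values.
#' @export
reflectance_with_se <- function(records, geometry = probe_geometry(),
                                n_photons = records$n_photons,
                                n_blocks = 25, ...) {
  n <- length(records$weight)
  blk <- ceiling(seq_len(n) / (n / n_blocks))
  vals <- vapply(seq_len(n_blocks), function(b) {
    idx <- blk == b
    sub <- lapply(records[c("radius", "cos_exit", "weight")],
                  function(v) v[idx])
    channel_reflectance(sub, geometry, n_photons = n_photons / n_blocks, ...)
  }, numeric(1))
  list(reflectance = mean(vals), se = sd(vals) / sqrt(n_blocks),
       blocks = vals)
}

#' Inter-channel optical crosstalk for a center pixel
#'
#' Simulates the fraction of signal collected by a central detection fiber
#' that originates from the illumination fibers of the 8 neighbouring
#' channels surrounding it at the given pitch (the worst case on the probe
#' face), as a percentage of the total collected signal.  Uses a
#' zero-absorption baseline simulation at the target scattering level,
#' scaled to the target absorption, so that the exponentially attenuated
#' long-range signal is estimated smoothly rather than from rare photon
#' counts.
#'
#' @param musp,mua Band-averaged optical properties of the medium, cm^-1.
#' @param pitch_mm Channel spacing, mm.
#' @param geometry Probe geometry ([probe_geometry()]).
#' @param g,n_medium Medium anisotropy and refractive index.
#' @param n_photons,seed Baseline simulation size and seed.
#' @param baseline Optional precomputed [mc_baseline()] at `musp`, `g`,
#'   zero absorption (reused across pitches).
#' @param n_blocks Photon blocks for the Monte Carlo standard error.
#' @return List: `percent` (crosstalk %), `se` (MC standard error of the
#'   percent), `own`, `neighbour` collected weights.
#' @export
crosstalk_fraction <- function(musp, mua, pitch_mm = 6,
                               geometry = probe_geometry(),
                               g = 0.9, n_medium = 1.37,
                               n_photons = 1e6, seed = 1,
                               baseline = NULL, n_blocks = 25) {
  if (pitch_mm <= 0) stop("pitch must be > 0")
  if (is.null(baseline))
    baseline <- mc_baseline(musp = musp, g = g, n_medium = n_medium,
                            n_photons = n_photons, seed = seed)
  sc <- scale_to_target(baseline, musp = musp, mua = mua)

  p <- pitch_mm / 10
  ring <- geometry$sds_cm
  nf <- geometry$n_illumination
  ang <- 2 * pi * (seq_len(nf) - 1) / nf
  # neighbour channel centres (8 surrounding a center pixel)
  cx <- p * c(-1, 0, 1, -1, 1, -1, 0, 1)
  cy <- p * c(-1, -1, -1, 0, 0, 1, 1, 1)

  dr <- 0.001
  rmax <- max(sqrt(cx^2 + cy^2)) + ring + 0.1
  nbins <- ceiling(rmax / dr)

  n <- length(sc$weight)
  blk <- ceiling(seq_len(n) / (n / n_blocks))
  own_b <- numeric(n_blocks); nb_b <- numeric(n_blocks)
  for (b in seq_len(n_blocks)) {
    idx <- blk == b
    sub <- list(radius = sc$radius[idx], cos_exit = sc$cos_exit[idx],
                weight = sc$weight[idx])
    W <- collect_weights(sub, dr, nbins, na = geometry$na)
    # own channel: nf ring fibers all at distance `ring`, 1/nf launch each
    own_b[b] <- fiber_signal(W, dr, ring, geometry$fiber_radius_cm,
                             geometry$fiber_radius_cm)
    # neighbours: each channel's nf fibers at its own ring positions
    acc <- 0
    for (k in seq_along(cx)) {
      fx <- cx[k] + ring * cos(ang)
      fy <- cy[k] + ring * sin(ang)
      d <- sqrt(fx^2 + fy^2)
      for (dd in d)
        acc <- acc + fiber_signal(W, dr, dd, geometry$fiber_radius_cm,
                                  geometry$fiber_radius_cm) / nf
    }
    nb_b[b] <- acc
  }
  pct_b <- 100 * nb_b / (own_b + nb_b)
  list(percent = 100 * sum(nb_b) / (sum(own_b) + sum(nb_b)),
       se = sd(pct_b) / sqrt(n_blocks),
       own = sum(own_b) / n, neighbour = sum(nb_b) / n,
       pitch_mm = pitch_mm)
}

# ---- reflectance lookup table ---------------------------------------------

#' Build a channel-reflectance lookup table from a baseline simulation
#'
#' Tabulates the forward model R(mu_s', mu_a) for the probe channel geometry
#' on a rectangular property grid, by similarity scaling of a single
#' zero-absorption baseline.  The inversion routine interpolates this table
#' bilinearly; this is the "Monte-Carlo generated reflectance look-up table"
#' at the heart of the fast inverse model.
#'
#' @param baseline A [mc_baseline()].
#' @param musp_grid,mua_grid Property grids, cm^-1.
#' @param geometry Probe geometry.
#' @param dr Radial bin width, cm.
#' @return A `qdri_lut` with the reflectance matrix `R` (musp x mua).
#' @export
build_reflectance_lut <- function(baseline,
                                  musp_grid = c(seq(2, 16, by = 0.25),
                                                seq(16.5, 40, by = 0.5)),
                                  mua_grid = c(seq(0, 2, by = 0.1),
                                               seq(2.25, 8, by = 0.25),
                                               seq(8.5, 20, by = 0.5),
                                               seq(21, 76, by = 2.5)),
                                  geometry = probe_geometry(),
                                  dr = 0.001) {
  if (!inherits(baseline, "qdri_baseline"))
    stop("baseline must come from mc_baseline()")
  cos_min <- sqrt(1 - min(1, geometry$na)^2)
  keep <- baseline$records$cos_exit >= cos_min
  r0 <- baseline$records$radius[keep]
  L0 <- rowSums(baseline$records$path)[keep]
  w0 <- baseline$records$weight[keep]

  rmax <- geometry$sds_cm + 4 * geometry$fiber_radius_cm
  nbins <- ceiling(rmax / dr)
  rmid <- (seq_len(nbins) - 0.5) * dr
  # detector-overlap kernel averaged over the source fiber face
  pts <- disc_points(geometry$fiber_radius_cm)
  dists <- sqrt((geometry$sds_cm + pts[, 1])^2 + pts[, 2]^2)
  M <- rowMeans(vapply(dists, function(dd)
    arc_fraction(rmid, dd, geometry$fiber_radius_cm), numeric(nbins)))

  R <- matrix(NA_real_, length(musp_grid), length(mua_grid))
  for (i in seq_along(musp_grid)) {
    rscale <- baseline$baseline$musp / musp_grid[i]
    Wm <- scaled_bin_weights_cpp(r0, L0, w0, rscale, mua_grid, dr, nbins)
    R[i, ] <- as.numeric(crossprod(Wm, M)) / baseline$n_photons
  }
  structure(list(R = R, musp_grid = musp_grid, mua_grid = mua_grid,
                 geometry = geometry,
                 baseline = c(baseline$baseline,
                              list(n_photons = baseline$n_photons,
                                   seed = baseline$seed)),
                 dr = dr, schema = "qdri-lut-1"),
            class = "qdri_lut")
}

#' Interpolate channel reflectance from a lookup table
#'
#' Bilinear interpolation of the tabulated forward model; vectorized over
#' property pairs.  Queries are clamped to the table edges (the default
#' table spans far beyond the physical property range, so clamping only
#' affects unphysical optimizer excursions).
#'
#' @param lut A [build_reflectance_lut()] table.
#' @param musp,mua Property vectors (recycled to a common length), cm^-1.
#' @export
lut_reflectance <- function(lut, musp, mua) {
  n <- max(length(musp), length(mua))
  musp <- rep_len(musp, n); mua <- rep_len(mua, n)
  if (any(!is.finite(musp)) || any(!is.finite(mua)) || any(mua < 0))
    stop("properties must be finite and mua >= 0")
  xg <- lut$musp_grid; yg <- lut$mua_grid
  musp <- pmin(pmax(musp, xg[1]), xg[length(xg)])
  mua <- pmin(pmax(mua, yg[1]), yg[length(yg)])
  i <- pmin(findInterval(musp, xg), length(xg) - 1L)
  j <- pmin(findInterval(mua, yg), length(yg) - 1L)
  tx <- (musp - xg[i]) / (xg[i + 1L] - xg[i])
  ty <- (mua - yg[j]) / (yg[j + 1L] - yg[j])
  R <- lut$R
  (1 - tx) * (1 - ty) * R[cbind(i, j)] +
    tx * (1 - ty) * R[cbind(i + 1L, j)] +
    (1 - tx) * ty * R[cbind(i, j + 1L)] +
    tx * ty * R[cbind(i + 1L, j + 1L)]
}

#' Save / load a baseline record cache as plain text
#'
#' Versioned plain-text cache (JSON metadata + CSV records) for baseline
#' simulations, so that expensive runs can be reused across sessions.
#'
#' @param baseline A [mc_baseline()].
#' @param dir Cache directory (created if needed).
#' @export
save_baseline <- function(baseline, dir) {
  if (!inherits(baseline, "qdri_baseline")) stop("not a baseline")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(schema = "qdri-baseline-1",
               musp = baseline$baseline$musp, g = baseline$baseline$g,
               n_medium = baseline$baseline$n_medium,
               n_photons = baseline$n_photons, seed = baseline$seed)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  d <- data.frame(radius = baseline$records$radius,
                  cos_exit = baseline$records$cos_exit,
                  weight = baseline$records$weight,
                  pathlen = rowSums(baseline$records$path))
  write.csv(d, file.path(dir, "records.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname save_baseline
#' @export
load_baseline <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$schema, "qdri-baseline-1"))
    stop("unrecognized baseline cache schema")
  d <- read.csv(file.path(dir, "records.csv"))
  structure(list(records = list(radius = d$radius, cos_exit = d$cos_exit,
                                weight = d$weight,
                                path = matrix(d$pathlen, ncol = 1)),
                 ledger = NULL, n_photons = meta$n_photons, seed = meta$seed,
                 baseline = list(musp = meta$musp,
                                 mus = meta$musp / (1 - meta$g),
                                 g = meta$g, n_medium = meta$n_medium)),
            class = c("qdri_baseline", "qdri_mc"))
}
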