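# Probe-array geometry, raster-scan planning, frame-to-map stitching,
# parity handling, margin segmentation and the SNR / RSD figures of merit.

#' The 7x7 probe channel array
#'
#' 49 channels on a 6 mm pitch, indexed row-major, with the checkerboard
#' odd/even illumination parity (the odd group, which contains the center
#' channel and self-calibration channel SC1, has 25 channels; the even
#' group with SC2 has 24).  Two consecutive spectral snapshots -- odd
#' channels lit, then even -- make one full 49-channel frame.
#'
#' @param rows,cols Array dimensions.
#' @param pitch_mm Channel spacing.
#' @export
probe_array <- function(rows = 7, cols = 7, pitch_mm = 6) {
  idx <- matrix(seq_len(rows * cols), rows, cols, byrow = TRUE)
  par <- ifelse((row(idx) + col(idx)) %% 2 == 0, "odd", "even")
  structure(list(rows = rows, cols = cols, pitch_mm = pitch_mm,
                 index = idx, parity = par,
                 sc = c(odd = "sc1", even = "sc2")),
            class = "qdri_probe_array")
}

#' Split the array channels by illumination parity
#'
#' @param array A [probe_array()].
#' @return List with integer channel vectors `odd` (25) and `even` (24).
#' @export
parity_split <- function(array = probe_array()) {
  list(odd = sort(array$index[array$parity == "odd"]),
       even = sort(array$index[array$parity == "even"]))
}

#' Plan a raster scan
#'
#' Upsample factor `n` means `n^2` placements of the whole probe on a
#' regular n x n sub-grid with step `pitch/n` mm: n = 6 gives 36 placements
#' in 1 mm increments, n = 8 gives 64 placements at 0.75 mm (3136 map
#' pixels).  Offsets are enumerated serpentine for acquisition realism, but
#' stitching keys on the offset values, not the order.
#'
#' @param n Upsample factor (positive integer).
#' @param pitch_mm Channel pitch.
#' @return A `qdri_raster_plan`: `n`, `step_mm`, and an `offsets`
#'   data.frame (`ix`, `iy`, `dx_mm`, `dy_mm`).
#' @export
plan_raster <- function(n, pitch_mm = 6) {
  if (length(n) != 1L || !is.numeric(n) || is.na(n) || n < 1 ||
      n != round(n)) stop("upsample factor n must be a positive integer")
  n <- as.integer(n)
  step <- pitch_mm / n
  offs <- do.call(rbind, lapply(0:(n - 1L), function(iy) {
    ix <- if (iy %% 2 == 0) 0:(n - 1L) else (n - 1L):0  # serpentine
    data.frame(ix = ix, iy = iy)
  }))
  offs$dx_mm <- offs$ix * step
  offs$dy_mm <- offs$iy * step
  structure(list(n = n, step_mm = step, pitch_mm = pitch_mm,
                 offsets = offs),
            class = "qdri_raster_plan")
}

#' Stitch per-frame channel values into a parameter map
#'
#' Channel (r, c) of the frame at sub-offset (ix, iy) fills map cell
#' `(r-1)*n + iy + 1, (c-1)*n + ix + 1` (0-based: `r*n + iy, c*n + ix`);
#' every cell is filled exactly once, with no interpolation.  The map is
#' `(7n) x (7n)` at pixel pitch `6/n` mm, spanning the fixed 42 mm probe
#' footprint for every n.
#'
#' @param frame_values List of frames, each a list with `ix`, `iy` and
#'   `values` (a 7x7 matrix of per-channel scalars).
#' @param plan The matching [plan_raster()].
#' @return Matrix map with attributes `pitch_mm` and `n`.
#' @export
stitch <- function(frame_values, plan) {
  n <- plan$n
  if (length(frame_values) != n^2)
    stop("expected ", n^2, " frames, got ", length(frame_values))
  keys <- vapply(frame_values, function(f) paste(f$ix, f$iy), character(1))
  want <- paste(plan$offsets$ix, plan$offsets$iy)
  if (anyDuplicated(keys)) stop("duplicate frame offsets")
  if (!setequal(keys, want)) stop("frame offsets do not match the plan")
  map <- matrix(NA_real_, 7L * n, 7L * n)
  for (f in frame_values) {
    v <- f$values
    if (!all(dim(v) == c(7L, 7L))) stop("frame values must be 7x7")
    rows <- (seq_len(7L) - 1L) * n + f$iy + 1L
    cols <- (seq_len(7L) - 1L) * n + f$ix + 1L
    map[rows, cols] <- v
  }
  attr(map, "pitch_mm") <- plan$step_mm
  attr(map, "n") <- n
  map
}

#' Recover per-frame channel values from a stitched map
#'
#' Exact inverse of [stitch()] (stitching is a bijection between
#' (frame, channel) pairs and map cells).
#'
#' @param map Stitched map.
#' @param plan The [plan_raster()] used.
#' @export
unstitch <- function(map, plan) {
  n <- plan$n
  lapply(seq_len(nrow(plan$offsets)), function(f) {
    ix <- plan$offsets$ix[f]; iy <- plan$offsets$iy[f]
    rows <- (seq_len(7L) - 1L) * n + iy + 1L
    cols <- (seq_len(7L) - 1L) * n + ix + 1L
    list(ix = ix, iy = iy, values = map[rows, cols])
  })
}

# ---- segmentation ---------------------------------------------------------

# Otsu threshold for a numeric vector (256-bin histogram).
otsu_threshold <- function(x) {
  x <- x[is.finite(x)]
  h <- hist(x, breaks = 256, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mut <- mu[length(mu)]
  sigma_b <- (mut * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

shift_mat <- function(m, dr, dc, fill = 0) {
  n <- matrix(fill, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)) - dr; cs <- seq_len(ncol(m)) - dc
  ok_r <- rs >= 1 & rs <= nrow(m); ok_c <- cs >= 1 & cs <= ncol(m)
  n[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  n
}

dilate3 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1)
    out <- out | shift_mat(m, dr, dc, FALSE)
  out
}
erode3 <- function(m) !dilate3(!m)

# 4-connected flood fill from the border over `open` cells.
flood_from_border <- function(open) {
  reach <- matrix(FALSE, nrow(open), ncol(open))
  reach[1, ] <- open[1, ]; reach[nrow(open), ] <- open[nrow(open), ]
  reach[, 1] <- reach[, 1] | open[, 1]
  reach[, ncol(open)] <- reach[, ncol(open)] | open[, ncol(open)]
  repeat {
    grown <- reach
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
      grown <- grown | (shift_mat(reach, d[1], d[2], FALSE) & open)
    if (identical(grown, reach)) break
    reach <- grown
  }
  reach
}

#' Segment the specimen from a parameter or reflectance map
#'
#' Gradient-magnitude edge detection (central differences, Otsu threshold)
#' followed by morphological closing of the edge set, background flood fill
#' from the map border, and hole filling; pixels darker than the midpoint
#' between background and specimen intensity are then pruned.  Intended for
#' maps whose off-specimen (no-contact) pixels are near zero.
#'
#' @param map Numeric matrix (NA treated as background).
#' @return Logical in-specimen mask; all-`FALSE` (with a warning) when no
#'   specimen is found.
#' @export
segment_margin <- function(map) {
  m <- map
  m[!is.finite(m)] <- 0
  gx <- (shift_mat(m, 0, -1, 0) - shift_mat(m, 0, 1, 0)) / 2
  gy <- (shift_mat(m, -1, 0, 0) - shift_mat(m, 1, 0, 0)) / 2
  gmag <- sqrt(gx^2 + gy^2)
  if (max(gmag) <= 0 || sd(as.numeric(m)) == 0) {
    warning("no specimen boundary found; returning empty mask")
    return(matrix(FALSE, nrow(map), ncol(map)))
  }
  edges <- gmag > otsu_threshold(gmag)
  closed <- erode3(dilate3(edges))          # morphological closing
  background <- flood_from_border(!closed)
  mask <- !background
  # prune edge-band pixels that are background-dark, then refill holes
  lvl_bg <- if (any(background)) median(m[background]) else min(m)
  if (any(mask)) {
    lvl_fg <- median(m[mask])
    if (lvl_fg > lvl_bg) {
      mask <- mask & (m > (lvl_bg + lvl_fg) / 2)
      mask <- !flood_from_border(!mask)
    }
  }
  if (!any(mask)) {
    warning("no specimen boundary found; returning empty mask")
    return(matrix(FALSE, nrow(map), ncol(map)))
  }
  mask
}

# ---- figures of merit -----------------------------------------------------

#' Signal-to-noise ratio of a replicate stack
#'
#' Computed exactly as the instrument characterization defines it:
#' `SNR = 20 * log10(mean / variance)` over replicates (the printed form;
#' dimensionally unusual but reproduced verbatim), with the conventional
#' `20 * log10(mean / sd)` available via `formula = "mean_sd"`.
#'
#' @param x Replicates x measurements matrix (rows = replicates) of
#'   background-corrected intensities.
#' @param formula `"printed"` (mean/variance) or `"mean_sd"`.
#' @return Per-measurement SNR in dB; `Inf` where the replicate variance is
#'   zero.
#' @export
snr_db <- function(x, formula = c("printed", "mean_sd")) {
  formula <- match.arg(formula)
  if (!is.matrix(x) || nrow(x) < 2) stop("need >= 2 replicates (rows)")
  m <- colMeans(x)
  v <- apply(x, 2, var)
  den <- if (formula == "printed") v else sqrt(v)
  out <- ifelse(den == 0, Inf, 20 * log10(m / den))
  out
}

#' Relative standard deviation across replicate maps
#'
#' `RSD = |sigma / mu|` per pixel across replicate scans, expressed in
#' percent and aggregated as the mean over (unmasked) pixels -- the
#' scan-to-scan reproducibility figure of merit.
#'
#' @param maps List of replicate matrices (same shape), or a 3-d array with
#'   replicates along the third dimension.
#' @return Scalar mean RSD in percent, with the per-pixel percent map as
#'   attribute `"pixelwise"`.  Pixels with zero mean are masked.
#' @export
rsd <- function(maps) {
  if (is.list(maps)) maps <- simplify2array(maps)
  if (length(dim(maps)) != 3 || dim(maps)[3] < 2)
    stop("need >= 2 replicate maps")
  mu <- apply(maps, c(1, 2), mean)
  sg <- apply(maps, c(1, 2), sd)
  px <- 100 * abs(sg / mu)
  px[!is.finite(mu) | mu == 0] <- NA
  out <- mean(px, na.rm = TRUE)
  attr(out, "pixelwise") <- px
  out
}

#' @importFrom stats var
#' @importFrom graphics hist
NULL

#' Stitch the band-averaged raw intensity of rendered frames into a map
#'
#' Collapses each channel's raw spectrum to its analysis-band mean and
#' stitches the `n^2` frames into a `(7n) x (7n)` intensity map --- the
#' uncalibrated reflectance image used for specimen segmentation and for
#' scan-to-scan reproducibility (RSD) checks.
#'
#' @param frames A [render_frames()] result.
#' @param band Averaging band, nm.
#' @return Stitched intensity map.
#' @export
frames_band_map <- function(frames, band = c(450, 600)) {
  arr <- probe_array()
  grid <- frames$grid
  sel <- grid >= band[1] & grid <= band[2]
  fv <- lapply(frames$frames, function(f) {
    vals <- matrix(NA_real_, 7, 7)
    for (r in 1:7) for (cc in 1:7)
      vals[r, cc] <- mean(f$spectra[sel, arr$index[r, cc]])
    list(ix = f$ix, iy = f$iy, values = vals)
  })
  stitch(fv, frames$plan)
}
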