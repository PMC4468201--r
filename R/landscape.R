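# The analysis layer: beta-carotene/scattering ratio maps, empirical CDFs
# of margin- or site-level pixel values ("landscapes"), two-sample
# Kolmogorov-Smirnov comparisons, and breast-density stratification.

#' Elementwise beta-carotene / scattering ratio map
#'
#' @param bcar_map,musp_map Co-registered maps (same shape); NA propagates.
#' @param eps Scattering floor, cm^-1; pixels with `musp <= eps` are masked
#'   (NA).
#' @return Ratio map in uM cm.
#' @export
ratio_map <- function(bcar_map, musp_map, eps = 0.01) {
  if (!all(dim(bcar_map) == dim(musp_map)))
    stop("maps must have the same shape")
  out <- bcar_map / musp_map
  out[!is.finite(musp_map) | musp_map <= eps] <- NA_real_
  attributes(out) <- attributes(bcar_map)
  out
}

#' Empirical cumulative distribution of a landscape
#'
#' Right-continuous step function with jump 1/N at each order statistic
#' (ties stack); the distributional summary of a margin or site region.
#'
#' @param values Finite scalars (a vectorized parameter map region);
#'   non-finite entries are dropped.
#' @param provenance Optional label (margin / site / stratum id).
#' @return A `qdri_ecdf`: sorted `values`, evaluator `F(x)`, `n`.
#' @export
landscape_ecdf <- function(values, provenance = NULL) {
  v <- sort(values[is.finite(values)])
  if (!length(v)) stop("no finite values")
  n <- length(v)
  F <- function(x) findInterval(x, v) / n
  structure(list(values = v, F = F, n = n, provenance = provenance),
            class = "qdri_ecdf")
}

#' @export
print.qdri_ecdf <- function(x, ...) {
  cat("qdri eCDF: n =", x$n,
      if (!is.null(x$provenance)) paste0("(", x$provenance, ")"), "\n")
  print(quantile(x$values))
  invisible(x)
}

# Asymptotic Kolmogorov survival function Q(t) = P(sup|B| > t).
kolmogorov_q <- function(t) {
  if (t < 0.05) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(1, max(0, p))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D = sup_x |F_a(x) - F_b(x)|` evaluated over the pooled sample points,
#' with a two-sided p-value from the asymptotic Kolmogorov distribution at
#' effective size `n_eff = n_a n_b / (n_a + n_b)`.  `exact = TRUE`
#' delegates the p-value to [stats::ks.test()]'s exact small-sample
#' computation.
#'
#' @param a,b `qdri_ecdf` objects or numeric vectors.
#' @param exact Use the exact conditional p-value (small samples, no ties).
#' @return List with `D`, `p`, `n_a`, `n_b`.
#' @export
ks_two_sample <- function(a, b, exact = FALSE) {
  if (!inherits(a, "qdri_ecdf")) a <- landscape_ecdf(a)
  if (!inherits(b, "qdri_ecdf")) b <- landscape_ecdf(b)
  pooled <- sort(unique(c(a$values, b$values)))
  D <- max(abs(a$F(pooled) - b$F(pooled)))
  ne <- a$n * b$n / (a$n + b$n)
  p <- if (exact) {
    suppressWarnings(stats::ks.test(a$values, b$values, exact = TRUE)$p.value)
  } else kolmogorov_q(sqrt(ne) * D)
  list(D = D, p = p, n_a = a$n, n_b = b$n)
}

#' Pairwise KS comparison of pooled group landscapes
#'
#' Pools pixel values within each group (density stratum, pathology label,
#' ...) and performs all pairwise two-sample KS tests.  Groups with fewer
#' than `min_n` values are excluded with a logged reason (insufficient
#' statistical power).
#'
#' @param groups Named list of numeric vectors (pooled pixel values per
#'   group).
#' @param min_n Minimum pooled count for a group to enter the comparison.
#' @param exact Passed to [ks_two_sample()].
#' @return data.frame (`group_a`, `group_b`, `D`, `p`, `n_a`, `n_b`), with
#'   the excluded group names in attribute `"excluded"`.
#' @export
compare_strata <- function(groups, min_n = 5, exact = FALSE) {
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be named")
  sizes <- vapply(groups, function(v) sum(is.finite(v)), integer(1))
  excluded <- names(groups)[sizes < min_n]
  for (g in excluded)
    message("excluding group '", g, "': n = ", sizes[[g]], " < ", min_n)
  keep <- setdiff(names(groups), excluded)
  if (length(keep) < 2) stop("fewer than 2 eligible groups")
  combs <- utils::combn(keep, 2)
  rows <- lapply(seq_len(ncol(combs)), function(i) {
    ks <- ks_two_sample(groups[[combs[1, i]]], groups[[combs[2, i]]],
                        exact = exact)
    data.frame(group_a = combs[1, i], group_b = combs[2, i],
               D = ks$D, p = ks$p, n_a = ks$n_a, n_b = ks$n_b)
  })
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- excluded
  out
}

#' Map the mammographic density score to a density stratum
#'
#' Scores 1--2 are low breast density (LBD), 3--4 high (HBD).
#'
#' @param mbd Integer score(s) in 1..4.
#' @return Character vector `"LBD"` / `"HBD"`.
#' @export
density_stratum <- function(mbd) {
  if (any(!mbd %in% 1:4)) stop("MBD scores must be 1, 2, 3 or 4")
  ifelse(mbd <= 2, "LBD", "HBD")
}

#' Extract site-level values from a parameter map
#'
#' A "site" is the footprint of one native probe channel (6 x 6 mm); at
#' upsample n it covers the n x n block of map pixels centred on that
#' channel.  There are 49 possible sites per margin.
#'
#' @param map Stitched `(7n) x (7n)` parameter map.
#' @param site_row,site_col Native channel coordinates in 1..7.
#' @return Numeric vector of the site's pixel values (NAs dropped).
#' @export
site_values <- function(map, site_row, site_col) {
  n <- nrow(map) / 7L
  if (n != round(n)) stop("map is not a 7n x 7n stitched map")
  if (site_row < 1 || site_row > 7 || site_col < 1 || site_col > 7)
    stop("site coordinates must be in 1..7")
  rows <- ((site_row - 1L) * n + 1L):(site_row * n)
  cols <- ((site_col - 1L) * n + 1L):(site_col * n)
  v <- as.numeric(map[rows, cols])
  v[is.finite(v)]
}
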