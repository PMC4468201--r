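# Chromophore absorption and Mie-sphere scattering models: the map from
# physical composition (absorber concentrations, sphere size/density) to the
# optical coefficients mu_a(lambda) and mu_s'(lambda) that drive photon
# transport.

#' Wavelength grid constructor
#'
#' Builds and validates the wavelength grid (nm) on which all spectra in the
#' package live.  The instrument collects over the visible band 420--700 nm;
#' scalar summaries are band averages over 450--600 nm (see
#' [band_average()]).
#'
#' @param from,to Grid endpoints in nm, within \[420, 700\].
#' @param by Grid step in nm.
#' @return Numeric vector of strictly increasing wavelengths with class
#'   `qdri_grid`.
#' @examples
#' g <- wavelength_grid(450, 600, by = 5)
#' @export
wavelength_grid <- function(from = 420, to = 700, by = 1) {
  g <- seq(from, to, by = by)
  validate_grid(g)
  structure(g, class = c("qdri_grid", "numeric"))
}

validate_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 2L)
    stop("wavelength grid needs at least 2 numeric points")
  if (any(diff(grid) <= 0)) stop("wavelength grid must be strictly increasing")
  if (min(grid) < 420 - 1e-9 || max(grid) > 700 + 1e-9)
    stop("wavelength grid must lie within [420, 700] nm")
  invisible(grid)
}

#' Read a molar extinction spectrum from CSV
#'
#' One file per absorber: two named columns `wavelength_nm` and
#' `extinction_1_per_M_cm`, header row required.
#'
#' @param path CSV file path.
#' @param name Absorber label; defaults to the file name stem.
#' @return A `qdri_absorber` object (label, tabulated extinction, provenance).
#' @export
read_absorber_csv <- function(path, name = NULL) {
  if (!file.exists(path)) stop("absorber file not found: ", path)
  d <- read.csv(path)
  need <- c("wavelength_nm", "extinction_1_per_M_cm")
  if (!all(need %in% names(d)))
    stop("absorber CSV must have columns: ", paste(need, collapse = ", "))
  if (any(d$extinction_1_per_M_cm < 0)) stop("extinction must be >= 0")
  if (is.null(name)) name <- sub("\\.csv$", "", basename(path))
  structure(list(name = name,
                 wavelength = d$wavelength_nm,
                 extinction = d$extinction_1_per_M_cm,
                 source = path),
            class = "qdri_absorber")
}

#' Bundled absorber library
#'
#' Loads the packaged extinction spectra (hemoglobin and beta-carotene;
#' synthetic literature-like compilations, see the file names) and
#' interpolates them onto `grid`.
#'
#' @param grid Wavelength grid (nm).
#' @param dir Directory of absorber CSV files.
#' @return Named list of `qdri_absorber` objects with an `extinction` vector
#'   matched to `grid`.
#' @export
absorber_library <- function(grid = wavelength_grid(),
                             dir = system.file("extdata", package = "qdri")) {
  validate_grid(grid)
  files <- c(hb = "hb_extinction_synthetic.csv",
             beta_carotene = "beta_carotene_extinction_synthetic.csv")
  out <- lapply(names(files), function(nm) {
    a <- read_absorber_csv(file.path(dir, files[[nm]]), name = nm)
    if (min(a$wavelength) > min(grid) || max(a$wavelength) < max(grid))
      stop("absorber ", nm, " does not cover the wavelength grid")
    a$extinction <- approx(a$wavelength, a$extinction, xout = grid)$y
    a$wavelength <- as.numeric(grid)
    a
  })
  names(out) <- names(files)
  out
}

#' Beer--Lambert absorption spectrum of an absorber mixture
#'
#' `mu_a(lambda) = ln(10) * sum_i eps_i(lambda) * C_i`, with extinction in
#' 1/(M cm) and concentrations in uM (converted internally to M), yielding
#' cm^-1.  Linear in each concentration; additive across absorbers.
#'
#' @param concs Named numeric vector of molar concentrations, uM.
#' @param library Absorber library from [absorber_library()] on the same grid.
#' @param grid Wavelength grid (nm).
#' @return Absorption coefficient spectrum, cm^-1, on `grid`.
#' @export
absorption_spectrum <- function(concs, library, grid) {
  validate_grid(grid)
  if (length(concs) && is.null(names(concs)))
    stop("concentrations must be named by absorber")
  if (any(concs < 0)) stop("concentrations must be >= 0")
  mua <- numeric(length(grid))
  for (nm in names(concs)) {
    a <- library[[nm]]
    if (is.null(a)) stop("unknown absorber: ", nm)
    if (length(a$extinction) != length(grid) ||
        any(abs(a$wavelength - grid) > 1e-9))
      stop("absorber ", nm, " is not tabulated on this grid")
    mua <- mua + log(10) * a$extinction * concs[[nm]] * 1e-6
  }
  mua
}

# ---- Mie theory for homogeneous spheres -----------------------------------

# Scattering efficiency and asymmetry for one size parameter x and real
# relative index m, by the standard partial-wave sum with the logarithmic
# derivative computed by downward recurrence (numerically stable for the
# x ~ 5-12 regime of 1 um spheres in the visible).
mie_single <- function(x, m) {
  if (m < 1) stop("relative refractive index must be >= 1")
  if (x <= 0) stop("size parameter must be > 0")
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  nmx <- nmax + 15L
  mx <- m * x
  D <- numeric(nmx)                 # D[k] = psi_k'(mx) / psi_k(mx)
  for (k in (nmx - 1L):1) {
    f <- (k + 1) / mx
    D[k] <- f - 1 / (D[k + 1L] + f)
  }

  a <- complex(nmax); b <- complex(nmax)
  psi_nm1 <- cos(x); psi_n <- sin(x)       # psi_{-1}, psi_0
  chi_nm1 <- -sin(x); chi_n <- cos(x)      # chi_{-1}, chi_0
  for (n in seq_len(nmax)) {
    psi <- (2 * n - 1) / x * psi_n - psi_nm1
    chi <- (2 * n - 1) / x * chi_n - chi_nm1
    psi_nm1 <- psi_n; psi_n <- psi
    chi_nm1 <- chi_n; chi_n <- chi
    xi <- complex(real = psi, imaginary = -chi)
    xi_nm1 <- complex(real = psi_nm1, imaginary = -chi_nm1)
    da <- D[n] / m + n / x
    db <- D[n] * m + n / x
    a[n] <- (da * psi - psi_nm1) / (da * xi - xi_nm1)
    b[n] <- (db * psi - psi_nm1) / (db * xi - xi_nm1)
  }
  n <- seq_len(nmax)
  qsca <- (2 / x^2) * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2))
  n1 <- seq_len(nmax - 1L)
  gq <- (4 / x^2) * (
    sum(n1 * (n1 + 2) / (n1 + 1) *
          Re(a[n1] * Conj(a[n1 + 1L]) + b[n1] * Conj(b[n1 + 1L]))) +
    sum((2 * n + 1) / (n * (n + 1)) * Re(a * Conj(b))))
  list(qsca = qsca, g = gq / qsca)
}

#' Mie scattering efficiency and anisotropy
#'
#' @param x Size parameter(s) `pi * d * n_medium / lambda` (d and lambda in
#'   the same units).
#' @param m Relative refractive index `n_sphere / n_medium` (real).
#' @return List with vectors `qsca` and `g`.
#' @export
mie_efficiencies <- function(x, m) {
  res <- lapply(x, mie_single, m = m)
  list(qsca = vapply(res, `[[`, numeric(1), "qsca"),
       g = vapply(res, `[[`, numeric(1), "g"))
}

#' Sphere scatterer specification
#'
#' @param diameter_um Sphere diameter, um.
#' @param n_sphere,n_medium Refractive indices (dispersion neglected;
#'   polystyrene 1.59 in water 1.33 by default).
#' @param number_density Spheres per mL.
#' @export
sphere_spec <- function(diameter_um = 1, n_sphere = 1.59, n_medium = 1.33,
                        number_density = 1) {
  stopifnot_scalar_number(diameter_um, "diameter_um", lo = 1e-6)
  if (n_sphere < 1 || n_medium < 1) stop("refractive indices must be >= 1")
  if (number_density < 0) stop("number_density must be >= 0")
  structure(list(diameter_um = diameter_um, n_sphere = n_sphere,
                 n_medium = n_medium, number_density = number_density),
            class = "qdri_sphere_spec")
}

#' Reduced scattering spectrum of a sphere suspension
#'
#' Independent-scatterer Mie model: `mu_s = rho * Qsca * pi * (d/2)^2` and
#' `mu_s' = mu_s * (1 - g)`; exactly linear in number density.
#'
#' @param spec A [sphere_spec()].
#' @param grid Wavelength grid, nm.
#' @return List with `musp` (cm^-1), `mus` (cm^-1) and `g` on `grid`.
#' @export
mie_reduced_scattering <- function(spec, grid) {
  validate_grid(grid)
  if (!inherits(spec, "qdri_sphere_spec")) stop("spec must be a sphere_spec")
  lam_um <- grid / 1000
  x <- pi * spec$diameter_um * spec$n_medium / lam_um
  m <- spec$n_sphere / spec$n_medium
  eff <- mie_efficiencies(x, m)
  geom_cm2 <- pi * (spec$diameter_um / 2 * 1e-4)^2
  mus <- spec$number_density * eff$qsca * geom_cm2
  list(musp = mus * (1 - eff$g), mus = mus, g = eff$g)
}

#' Calibrate sphere number density against a target band-averaged mu_s'
#'
#' @param target_musp Target band-averaged reduced scattering, cm^-1.
#' @param spec Sphere spec (its `number_density` is ignored).
#' @param grid Wavelength grid.
#' @param band Averaging band, nm.
#' @return Number density (spheres/mL) such that the 450--600 nm (default)
#'   band average of mu_s' equals `target_musp`.
#' @export
calibrate_sphere_density <- function(target_musp, spec = sphere_spec(),
                                     grid = wavelength_grid(),
                                     band = c(450, 600)) {
  spec$number_density <- 1
  unit <- mie_reduced_scattering(spec, grid)$musp
  target_musp / band_average(unit, grid, band)
}

#' Band average of a spectrum
#'
#' Mean of the spectrum over grid points inside the closed band; the scalar
#' summaries quoted throughout (e.g. band-averaged mu_a and mu_s') use the
#' 450--600 nm analysis band.
#'
#' @param spectrum Numeric vector on `grid`.
#' @param grid Wavelength grid, nm.
#' @param band Length-2 `c(lo, hi)` in nm.
#' @export
band_average <- function(spectrum, grid, band = c(450, 600)) {
  if (length(spectrum) != length(grid))
    stop("spectrum and grid lengths differ")
  sel <- grid >= band[1] & grid <= band[2]
  if (!any(sel)) stop("empty band: no grid points in [",
                      band[1], ", ", band[2], "]")
  mean(spectrum[sel])
}

#' Phantom scattering spectral shape
#'
#' Mie mu_s' spectral shape of the 1 um polystyrene phantom spheres,
#' normalized so its band average is exactly 1: a phantom with band-averaged
#' `<mu_s'> = s` has `mu_s'(lambda) = s * shape(lambda)`.
#'
#' @param grid Wavelength grid, nm.
#' @param band Normalization band, nm.
#' @export
phantom_musp_shape <- function(grid, band = c(450, 600)) {
  musp <- mie_reduced_scattering(sphere_spec(number_density = 1), grid)$musp
  musp / band_average(musp, grid, band)
}
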