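# Shared fixtures for the test suite.  Expensive Monte Carlo objects are
# built once per test run (lazily) and reused across files; photon counts
# are scaled down from production values to keep the suite fast, which
# widens Monte Carlo standard errors but does not change any physics.

.fixtures <- new.env(parent = emptyenv())

# Baseline simulation shared by the LUT / inversion / acceptance tests.
shared_baseline <- function() {
  if (is.null(.fixtures$baseline))
    .fixtures$baseline <- mc_baseline(musp = 9, g = 0.9, n_medium = 1.37,
                                      n_photons = 2e5, seed = 424242)
  .fixtures$baseline
}

shared_lut <- function() {
  if (is.null(.fixtures$lut))
    .fixtures$lut <- build_reflectance_lut(shared_baseline())
  .fixtures$lut
}

shared_grid <- function() wavelength_grid(by = 2)

shared_library <- function() {
  if (is.null(.fixtures$library))
    .fixtures$library <- absorber_library(shared_grid())
  .fixtures$library
}

# ---- independent Mie oracle ----------------------------------------------
# Brute-force partial-wave sum built on R's half-integer Bessel functions
# (upward evaluation, no logarithmic-derivative recurrence): an
# implementation fully independent of the package's Mie code.

oracle_psi <- function(n, x) sqrt(pi * x / 2) * besselJ(x, n + 0.5)
oracle_chi <- function(n, x) -sqrt(pi * x / 2) * besselY(x, n + 0.5)

oracle_mie <- function(x, m) {
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  mx <- m * x
  n <- seq_len(nmax)
  psi_x <- oracle_psi(n, x); psi_xm1 <- oracle_psi(n - 1, x)
  psi_mx <- oracle_psi(n, mx); psi_mxm1 <- oracle_psi(n - 1, mx)
  chi_x <- oracle_chi(n, x); chi_xm1 <- oracle_chi(n - 1, x)
  dpsi_x <- psi_xm1 - n / x * psi_x
  dpsi_mx <- psi_mxm1 - n / mx * psi_mx
  xi_x <- complex(real = psi_x, imaginary = -chi_x)
  dxi_x <- complex(real = dpsi_x, imaginary = -(chi_xm1 - n / x * chi_x))
  a <- (m * psi_mx * dpsi_x - psi_x * dpsi_mx) /
    (m * psi_mx * dxi_x - xi_x * dpsi_mx)
  b <- (psi_mx * dpsi_x - m * psi_x * dpsi_mx) /
    (psi_mx * dxi_x - m * xi_x * dpsi_mx)
  qsca <- (2 / x^2) * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2))
  n1 <- seq_len(nmax - 1)
  gq <- (4 / x^2) * (
    sum(n1 * (n1 + 2) / (n1 + 1) *
          Re(a[n1] * Conj(a[n1 + 1]) + b[n1] * Conj(b[n1 + 1]))) +
    sum((2 * n + 1) / (n * (n + 1)) * Re(a * Conj(b))))
  list(qsca = qsca, g = gq / qsca)
}
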