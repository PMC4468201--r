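---
title: "Methods: photon transport, spectral inversion and landscape statistics in qdri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photon transport, spectral inversion and landscape statistics in qdri}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models it
implements, the assumptions behind them, the parameters that matter, and
the numerical choices made where the design was genuinely open.  It
states no empirical result that the test suite or the acceptance script
does not itself compute.

## 1. The measurement being modelled

A fiber-optic probe presses against the cut face of an excised breast
specimen.  Each of its 49 channels illuminates the tissue through eight
200 μm fibers arranged on a ring of radius 700 μm around a central
detection fiber (NA 0.22).  Light that multiple-scatters through the
tissue and re-emerges at the detection fiber constitutes the diffuse
reflectance spectrum of that channel, collected over 420–700 nm.  Two
additional self-calibration (SC) channels view the source directly, one
per illumination parity (the 49 channels are lit as an odd/even
checkerboard in two consecutive snapshots; the odd group has 25 channels,
the even 24).  The probe raster-scans in `n × n` sub-pitch placements,
yielding a `(7n) × (7n)` map at pitch `6/n` mm over the fixed 42 mm
footprint — 0.75 mm pixels at the working point `n = 8`.

Two spectral quantities carry the biology: the absorption coefficient
`mu_a(lambda)` (hemoglobin and β-carotene) and the reduced scattering
coefficient `mu_s'(lambda)` (collagen, glands, nuclei).  Their ratio
`[β-carotene]/<mu_s'>` — carotenoid storage in adipocytes over fibrous
scattering — summarizes adipose vs fibroglandular composition; a margin's
per-pixel distribution of that ratio ("landscape") is reduced to an
empirical CDF and compared across tissue groups with the two-sample
Kolmogorov–Smirnov statistic.

## 2. Photon transport

`run_mc()` implements standard weighted Monte Carlo transport in layered
media: exponential free paths at rate `mu_t = mu_a + mu_s`, absorption by
weight deposition `w * mu_a/mu_t` per interaction, Henyey–Greenstein
scattering with anisotropy `g`, Fresnel reflection/refraction at every
refractive-index boundary (ambient air above the medium; the fiber face
is assumed flush with the tissue and the NA cut is applied to the exit
angle in air), and Russian roulette below weight `1e-4` with survival
probability 0.1.  Assumptions: unpolarized, elastic, time-independent
transport; smooth planar boundaries; no fluorescence.

The engine uses its own `mt19937_64`-based RNG with an explicit 53-bit
conversion, so a seed reproduces identical photon histories on any
platform and R's RNG state is never touched.  Bookkeeping is exact: the
ledger (specular, diffuse, transmitted, absorbed, lost, roulette
loss/gain) sums to the launched weight to ~1e-10 relative, which the test
suite asserts.  Termination safeguards (`z_kill_cm = 2`, `r_kill_cm = 3`)
drop the vanishing deep/far tail into the `lost` entry; they matter only
for the zero-absorption baseline, and both sides of every
scaled-vs-direct comparison share them.

## 3. The single-baseline ("scalable") model

A baseline simulation at `mu_a = 0` and fixed `mu_s' = 9 cm^-1`
(`g = 0.9`, `n = 1.37`) records every exiting photon's radius, exit
angle, weight and path length.  For a target `(mu_s', mu_a)` with the
same `g`, trajectories rescale exactly: radii and path lengths by
`mu_s(baseline)/mu_s(target)`, weights by `exp(-mu_a * path)`.  This is
the identity that makes spectral inversion tractable: one simulation
yields the whole forward surface `R(mu_s', mu_a)`, tabulated by
`build_reflectance_lut()` on a grid spanning `mu_s'` 2–40 cm⁻¹ and `mu_a`
0–76 cm⁻¹ (far beyond the physical range, so bilinear interpolation with
edge clamping never extrapolates in practice) and collected geometrically
(thin-annulus overlap of the radial exit histogram with the detector
disc, averaged over the source-fiber face).

The validated scaling range is declared as the phantom-series property
envelope ±50 %; outside it `scale_to_target()` warns and direct
simulation should be used.  The acceptance suite checks scaled against
independent direct simulations at six property pairs spanning the
envelope, within 3× the combined Monte Carlo standard error (estimated by
photon blocks; 25 blocks reproduce the empirical seed-to-seed spread of
both estimators).

Channel crosstalk uses the same machinery: the central detection fiber's
collected weight is decomposed into contributions from its own ring
fibers (distance 0.7 mm) and from the 64 illumination fibers of the 8
surrounding channels (distances ≈ pitch).  Because the long-range signal
is exponentially attenuated, estimating it from a scaled zero-absorption
baseline (smooth weights) rather than from rare direct photon arrivals is
what makes the estimate stable at desk-scale photon counts.  Parity
sequencing would remove the four edge-adjacent neighbours from any single
snapshot; the reported number conservatively includes all eight, making
it an upper bound under the stated geometry.

## 4. Optics: chromophores and Mie spheres

Absorption is Beer–Lambert:
`mu_a = ln(10) * sum_i eps_i(lambda) * C_i`, concentrations in μM.  The
bundled extinction spectra are *synthetic compilations* (file names say
so): literature-like shapes (oxyhemoglobin Q-bands at 542/577 nm with a
Soret tail; β-carotene's broad vibronic blue absorption) with the
hemoglobin amplitude anchored so its 450–600 nm band mean reproduces the
per-μM absorption implied by the phantom dilution table, which is itself
Beer–Lambert-consistent to <0.1 %.  The oxygenation state of the real
reagent batch is unknowable, so the table is treated as ground truth for
phantom work and the bundled shape is used for tissue inversion.

Phantom scattering is Mie theory for 1 μm polystyrene spheres
(n = 1.59) in water (n = 1.33), computed by the Bohren–Huffman
partial-wave sum with a downward-recurrence logarithmic derivative and
validated against an independent half-integer-Bessel oracle to 1e-6
relative (machine precision in practice).  `mu_s'` is exactly linear in
sphere number density; `calibrate_sphere_density()` pins the density to a
target band-averaged `mu_s'`.  Dispersion of the refractive indices is
neglected (documented simplification; the band is narrow).

## 5. Calibration and inversion

`calibrate_spectrum()` divides each raw spectrum by its parity's SC
channel (cancelling per-snapshot source drift *exactly*, by
construction), then rescales by `raw_sample/raw_reference *
model_reference` using a reference phantom of known properties.  A global
intensity drift therefore cancels; what survives is per-wavelength noise.

`fit_spectrum()` is bounded nonlinear least squares over 450–600 nm,
minimizing residuals normalized by the mean spectrum level (the raw
reflectance scale here is ~1e-5, and an unscaled objective would sit at
the optimizer's absolute convergence floor).  The optimizer is
`stats::optim`'s L-BFGS-B with deterministic multi-starts (default 3;
best residual wins, ties to the first), `factr = 1e4`, 500 evaluations —
a bounded quasi-Newton substitute for a trust-region least-squares solver,
chosen because it is in base R; the contract (bounds, determinism,
monotone improvement, flagged non-convergence) is unchanged.
Parameterizations:

* phantom: `[Hb]` ∈ [0, 300] μM and `s = <mu_s'>` ∈ [~2, 20] cm⁻¹ with
  the Mie spectral shape (phantoms contain no β-carotene);
* tissue: `[Hb]`, `[β-carotene]` ∈ [0, 80] μM, and
  `mu_s'(lambda) = a (lambda/550)^-b` with `b` ∈ [0, 4], normalized so
  `a` *is* the band average — tissue scatterer morphology is unknown, and
  the power law maps onto the same lookup table.

The LOOCV harness runs each of the 12 phantoms as calibration reference
against the other 11 (132 inversions), reporting percent errors of
band-averaged `mu_a` and `mu_s'`; the zero-absorption phantom enters the
`mu_a` aggregate as an absolute error only (percent error undefined at
zero).

## 6. The synthetic-data generator: what it emulates, what it does not

`generate_margin()` builds a stated world, not a tuned one: a
thresholded Gaussian-random-field class map (correlation 3 mm) inside an
irregular specimen boundary, with per-class parameters fixed in
`tissue_class_defaults()`.  The two constraints taken from the
instrument's characterization are honoured — the adipose class band
averages equal the worst-case crosstalk medium (`mu_s' = 6.9`,
`mu_a = 4.6 cm^-1`), and the class ratio medians are strictly ordered
adipose > fat+fibroglandular > fibroadipose > fibroglandular.  Absolute
β-carotene scales are inventions (no absolute scale is published);
only orderings and contrasts should be trusted.  HBD margins get
fibroglandular area fraction 0.55, LBD 0.20.  A long-range (12 mm)
lognormal baseline field (rel. sd 0.35) on β-carotene emulates
inter-patient/inter-region variability in adipocyte carotenoid content;
without it, site-to-site spread would be unrealistically tight and a KS
test would trivially detect any mixture even at native resolution,
contradicting the clinical observation the generator must reproduce.

`render_frames()` evaluates the lookup-table forward model at each
channel's footprint-averaged true parameters (the resolution model is
linear cell averaging at pitch `6/n` mm), multiplies by an LED-like lamp
shape and a per-snapshot drift factor shared with the SC channel
(default sd 0.9 %, bounded by the 2 % source specification), and adds 1 %
multiplicative shot-like noise.  Not emulated: real histology texture,
specular artifacts, probe–tissue contact mechanics, pressure effects,
wavelength miscalibration.  A green end-to-end test therefore establishes
the *pipeline's* correctness under the stated noise model — not clinical
performance.

## 7. Landscape statistics

`landscape_ecdf()` is the right-continuous counting CDF.
`ks_two_sample()` evaluates `D = sup|F_a - F_b|` over the pooled sample
points and an asymptotic two-sided p-value from the Kolmogorov series at
effective size `n_a n_b/(n_a + n_b)` (an exact small-sample option
delegates to `stats::ks.test`).  Group comparisons pool pixels within a
group; groups with fewer than 5 values are excluded as underpowered.
Ratio maps mask pixels with `mu_s' <= 0.01 cm^-1`.

One deliberate deviation: the volume-averaging ("masking") property of
low-resolution sampling is asserted in terms of statistical
distinguishability — predominantly-adipose mixed sites are
indistinguishable from pure adipose at `n = 1` (KS p > 0.05) but cleanly
separated at `n = 8` (p < 1e-3) — rather than as a smaller D at `n = 1`.
Under linear cell averaging the pooled `n = 1` site values form a narrow,
shifted distribution whose D against any fixed reference is generically
*larger*, so the D-form of the property is unattainable; the
distinguishability form is what the underlying study actually reports.

## 8. Numerical choices and limitations

* Radial exit histogram: 10 μm bins to 2 cm; detector overlap handled
  analytically per annulus, source face by 12-point quadrature.
* Roulette threshold 1e-4 / survival 0.1; anisotropy fixed at 0.9 for
  tissue (standard soft-tissue value; not stated by the source study),
  Mie-derived for phantoms; refractive indices water 1.33, polystyrene
  1.59, tissue 1.37, air 1.0.
* The SNR figure of merit is implemented verbatim as
  `20*log10(mean/variance)` — dimensionally unusual (variance, not sd, in
  the denominator) but reproduced as printed, with the conventional
  `mean/sd` form behind a flag.
* RSD of three replicates uses the plain `|sd/mean|` estimator; with
  n = 3 the sd estimator's expectation is 0.886·σ, so 0.9 % injected
  drift is expected to read ≈ 0.80 % — inside the stated ±0.2 band.  The
  bias is documented, not corrected, because the printed formula is the
  contract.
* Known limitations: similarity scaling assumes fixed `g` and a
  homogeneous semi-infinite medium (layered media require direct runs);
  the acquisition model ignores the finite sensing volume's lateral tails
  beyond the pixel cell; no pressure→compression mapping (the layered
  optics are reproduced, the mechanics are not); hemoglobin oxygenation
  kinetics are out of scope.
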