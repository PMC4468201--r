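# qdri — quantitative diffuse reflectance imaging of tissue margins

`qdri` re-implements, end to end, the computational pipeline of a
49-channel quantitative diffuse reflectance imaging (QDRI) system for
breast tumor margin assessment.  During breast conserving surgery the
excised specimen's margins must be checked for residual disease; a
multiplexed fiber-optic probe (a 7×7 array of channels on a 6 mm pitch,
each channel 8 illumination fibers around one detection fiber, 700 μm
source–detector separation) measures diffuse reflectance spectra across
the visible band (420–700 nm), raster-scans the probe in sub-pitch
increments to reach 0.75 mm resolution, and converts every pixel's
spectrum to tissue optical properties.  The package is aimed at
biomedical-optics researchers who want to simulate, invert and analyze
such measurements without the instrument.

## What it computes

* **Forward photon transport** (`run_mc`, Rcpp engine): MCML-style
  hop–drop–spin Monte Carlo with Henyey–Greenstein scattering
  (μs′ = μs·(1−g)), Fresnel boundaries and Russian roulette, for
  homogeneous and layered media, with exact energy bookkeeping.
* **Scalable single-baseline model** (`mc_baseline`, `scale_to_target`,
  `build_reflectance_lut`): one zero-absorption simulation is rescaled to
  any (μs′, μa) by similarity scaling of exit radii and `exp(-μa·ℓ)`
  reweighting, giving a fast lookup-table forward model
  R(μs′, μa) for the probe channel.
* **Inversion** (`calibrate_spectrum`, `fit_spectrum`,
  `loocv_phantom_errors`): reference-phantom calibration (with
  self-calibration-channel drift cancellation) and bounded nonlinear least
  squares over the 450–600 nm analysis band, recovering [Hb],
  [β-carotene] and μs′(λ), including the 12-phantom leave-one-out
  cross-validation harness.
* **Scan imaging** (`plan_raster`, `stitch`, `segment_margin`, `snr_db`,
  `rsd`): n² probe placements at pitch 6/n mm stitched into (7n)×(7n)
  parameter maps, margin segmentation, and the instrument figures of
  merit.
* **Landscape statistics** (`ratio_map`, `landscape_ecdf`,
  `ks_two_sample`, `compare_strata`): the per-margin empirical CDF of
  [β-carotene]/⟨μs′⟩ — an adipose-vs-fibroglandular composition
  surrogate — and two-sample Kolmogorov–Smirnov comparisons across
  breast-density strata (MBD 1–2 = LBD, 3–4 = HBD).
* **Synthetic data** (`phantom_specs`, `generate_margin`,
  `render_frames`): the phantom dilution series, breast-margin-like
  specimens with class-dependent optical parameters, and raw 49(+2)
  channel frames with lamp shape, ≤2 % source drift and shot-like noise —
  so the entire pipeline is testable offline.

## Worked example

```r
library(qdri)

## forward model: one zero-absorption baseline -> lookup table
base <- mc_baseline(musp = 9, n_photons = 2e5, seed = 42)
lut  <- build_reflectance_lut(base)
grid <- wavelength_grid(by = 2)
lib  <- absorber_library(grid)

## phantom accuracy: 12-fold leave-one-out, 1% spectral noise
cv <- loocv_phantom_errors(NULL, lut, grid,
                           noise = noise_model(noise_sd = 0.01),
                           seed = 7, library = lib)
round(cv$summary, 2)
#>   musp_mean     musp_sd    mua_mean      mua_sd pooled_mean
#>        0.46        0.45        0.49        0.39        0.47

## center-pixel crosstalk for the adipose worst case at the native pitch
ct <- crosstalk_fraction(6.9, 4.6, pitch_mm = 6, n_photons = 2e5, seed = 11)
sprintf("crosstalk: %.2f%% (se %.2f)", ct$percent, ct$se)
#> "crosstalk: 0.29% (se 0.05)"

## landscape contrast between breast-density strata
ml <- generate_margin("LBD", seed = 1)
mh <- generate_margin("HBD", seed = 2)
ks <- ks_two_sample(ml$ratio[ml$mask], mh$ratio[mh$mask])
c(D = ks$D, p = ks$p)
#> D = 0.372, p = 0   (medians: LBD 1.57, HBD 0.62 uM cm)
```

The LOOCV numbers say that, with 1 % multiplicative measurement noise,
band-averaged μs′ and μa are recovered to well under 1 % on average — far
inside the <10 % accuracy the instrument class achieves on real phantom
measurements (where lamp, probe and reagent non-idealities dominate).
The crosstalk number is the percentage of collected signal that
originates from neighbouring channels' illumination fibers; the HBD
landscape sits left of the LBD one because fibroglandular tissue carries
less β-carotene and scatters more.

## Full pipeline and CLI

```r
cfg <- qdri_config(seed = 1, n = 2, n_photons = 2e5, stratum = "LBD")
run_pipeline(cfg, "out/")   # maps, eCDF table, mask, checksummed manifest
```

A thin command-line wrapper lives at `inst/cli/qdri.R`
(`Rscript $(Rscript -e 'cat(system.file("cli","qdri.R",package="qdri"))') plan --n 8`),
with subcommands `plan`, `crosstalk`, `mc-baseline`, `fixtures`,
`pipeline`; exit codes 0/2/3/4 for success / config error / data error /
numerical failure.

## Documentation

The methods vignette (`vignettes/qdri-methods.Rmd`) describes the
transport model and its assumptions, the scaling trick and its validated
range, the inversion parameterization, what the synthetic-data generator
does and does not emulate, and the package's numerical choices.
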