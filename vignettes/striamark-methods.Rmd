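---
title: "Striated tool-mark signatures: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Striated tool-mark signatures: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striamark)
```

## The problem

Striated cut marks carry the individualizing pattern of a blade's cutting
edge. To decide whether a test material or casting medium is suitable for
comparative examination, one needs quantitative answers to three
questions: how *consistent* is a single mark (do all cross-sections carry
the same pattern?), how *reproducible* are marks from the same blade, and
how *distinguishable* are marks from different blades. `striamark`
operationalizes all three through normalized cross-correlation of
striation profiles, and surrounds this core with the supporting analyses a
material-comparison study needs (contrast photometry, indentation
elasticity, cleaning scores) plus a synthetic data generator that makes
every stage testable.

## Signature model

A scan is a height grid of `S` rows by `P` columns; rows run along the cut
direction, so each row is one profile across the striations. The defaults
`S = 261`, `P = 1004` and `dx = dy = 3` µm mirror a common tool-mark
scanner export of 262,044 points.

**Detrending.** Each profile is normalized by subtracting its centered
moving average (default window 51 samples ≈ 153 µm). The window is chosen
to sit well above the striation spacing (tens of µm) and well below the
wavelength of specimen form (mm); it is exposed as a parameter. At the
profile ends the window shrinks symmetrically, which makes the moving
average of any affine profile equal the profile itself — so constant
offsets and linear tilts are removed *exactly*, and the whole pipeline is
invariant (to ~1e-9) under adding affine form to the scan. A centered
(not trailing) average was chosen because a trailing window would shift
the striation phase by half a window.

**Correlation and lag search.** Profiles are compared with the
overlap-normalized cross-correlation
\[
X(L)=\frac{\sum_i S_1[i]\,S_2[i+L]}
{\sqrt{\sum_i S_1[i]^2 \sum_i S_2[i+L]^2}} ,
\]
where all three sums run over the overlap region only — the indices where
both `i` and `i+L` are in range (and not invalidated). With non-zero lag
the summation bounds of the textbook formula are ambiguous; restricting
*numerator and both denominator terms* to the overlap keeps
self-comparison at lag 0 exactly 1 and introduces no padding artifacts.
The positive-lag convention follows the index form `S2[i + L]`: the best
lag for a copy of a signal delayed by `k` samples is `+k`. The search is
exhaustive over integer lags in `[-max_lag, +max_lag]` (default ±50
samples; the largest mean lags seen in practice are ~12). Ties are broken
toward the smaller `|lag|`, then toward the negative lag, purely for
determinism. Sub-sample (interpolated) lags are deliberately out of
scope.

**Sequential alignment.** Signal 2 is aligned to signal 1; signal `j ≥ 3`
to the running per-sample mean of the already-aligned signals. Samples
shifted out of range are invalidated, never wrapped — physical profiles
are not periodic. The `S − 1` maximal coefficients and lags yield
`X_max` (their mean; within-mark quality) and `L_Xmax` (mean *absolute*
lag; straightness). Signed lags would partially cancel and could report a
crooked mark as straight, so the absolute value is used. `X_max` is a
plain unweighted mean over steps, although later steps are aligned
against larger averages.

**Signature.** The aligned signals are averaged per sample. End samples
covered by fewer than 90% of the signals are trimmed from both ends; the
threshold bounds edge bias while keeping at least `P − 2·max_lag` samples.
The per-sample contribution count is kept as `coverage`. Averaging `S`
aligned rows suppresses independent per-row noise by `1/S` in variance,
which is why between-mark scores of same-knife pairs can exceed the
within-mark step coefficients.

**Comparison.** Two signatures are compared with the same lag search; the
maximum is the score `X_C`. Signatures of unequal length (trimming can
differ by up to `2·max_lag`) are compared over their common span,
left-aligned. In a study, known matches are the two marks of each knife;
because a study design does not enumerate which cross-knife pairs serve
as known non-matches, the default is a deterministic cyclic derangement
(mark A of knife *i* vs mark B of knife *i + 1*), giving one KNM per
knife; an all-pairs scheme is available. KM/KNM separation is tested with
the two-sided Mann–Whitney U test, and materials are compared pairwise on
any raw metric the same way. P-values are reported raw by default (an
optional Holm adjustment is behind a flag) to match the convention of
reporting unadjusted pairwise tests in material-comparison studies.

## Synthetic data generator

The generator exists so that every pipeline stage has ground truth. A
*knife* is a stationary Gaussian edge profile: white noise smoothed to a
correlation length (default 30 µm), centered and scaled to an amplitude
(default SD 1.5 µm). A *mark* stamps that profile into every row, then
degrades it per a `material_model`:

* `lag_sd` — integer per-row lateral jitter (samples); iid by default,
  optionally a random walk to model progressive drift. iid matches the
  per-step alignment statistic; the recovered lags undo the applied
  shifts.
* `noise_sd` — iid Gaussian height noise per point (µm).
* `form_amplitude` — a smooth mark-level tilt plus single-period bow
  (µm), removed by detrending.
* dots — grain-like bumps emulating casting material that filled
  chondrocyte lacunae on cartilage casts: centers from a spatial Poisson
  process (`dot_density` per mm²), diameters truncated-normal with mean
  26.3 µm and SD 5.1 µm (the scale of lacunae; truncation correction
  < 1% at these values), cosine-profile bumps of height `dot_height`.
  Dots are *elevations* and the generator emits cast-convention grids.
* Rows shifted past the profile ends are filled by edge-value extension,
  not wraparound, to avoid spurious periodic correlation.

Four presets span the fidelity range: `high-fidelity` (agarose-like;
lag_sd 0.6, noise_sd 0.1), `medium-fidelity`, `low-fidelity`
(gelatine-like; lag_sd 5, noise_sd 0.8) and `cartilage-like` (dots
enabled). These parameter values are invented engineering constants chosen
once to produce the qualitative ordering such materials show; they are
documented here and in `?material_presets` and are *not* fitted to any
measured material. The `E` fields carry representative printed moduli of
such materials purely as simulation inputs.

What the generator does **not** emulate: cutting mechanics (chatter,
friction, abrasion), correlated (non-white) scanner noise, rotation or
scale errors between marks, partial marks, and the real spatial
statistics of cartilage striations, which are not characterized. Passing
tests therefore demonstrate the correctness and discriminating behaviour
of the *analysis*, not the field performance of any physical material.

A whole study (`generate_study`) derives per-knife and per-mark sub-seeds
deterministically from one seed, so every dataset is a pure function of
its configuration.

## Photometry

Image contrast is the sample standard deviation of all 8-bit pixel
brightness values. The renderer is a minimal model honouring the
reflectance law `I_R = I_I · |sin λ| · τ`: per-pixel normals from
central-difference gradients, incidence angle `λ` between the incoming
ray and the local tangent plane, brightness `base + gain · I_R` with
`base = 255 · LRV / 100` and the gain calibrated so a 45° facet at
`τ = 1, I_I = 1` adds 64 counts. Facets facing away from the light get
`λ = 0`; cast shadows, diffuse interreflection, translucency and
diffraction are not modelled. Quantization rounds half away from zero and
clamps to `[0, 255]`, for cross-platform determinism. Instrument-specific
settings (gamma, saturation) are metadata, not part of the model.

## Indentation

The spherical Hertzian model `F = (4/3)·E/(1−ν²)·√R·h^{3/2}` is simulated
with the standard protocol defaults (R = 1.5 mm, ν = 0.5 for an
incompressible solid, re-zeroed after a 0.1 N preload, ramp at 0.5 mm/s
to h_max = 0.9 mm, sampled at 50 Hz — 90 samples), loading segment only.
Two estimators invert it: the default origin-constrained regression of
`F` on `h^{3/2}` (noise-robust), and a pointwise mean of the per-sample
`E_i`, which excludes depths below `0.05·h_max` because the `h^{-3/2}`
factor amplifies noise near zero. Both agree exactly on noiseless curves;
the regression stays within 2% of truth at 1% force noise.

## Scoring and tests

Cleaning scores follow the five-criterion scheme (coarse striations, fine
striations, complete mark, no shine, no dots; the last may score −1 when
more dots appear than on the reference), so totals lie in `[−1, 5]`; the
printed TS values are treated as per-sample means, and the delta score is
`DS = TS_sample − TS_reference`. The summary-statistic t-test is computed
from `(mean, sd, n)` directly — Welch by default, pooled available, since
the flavor used with printed summaries is usually unrecoverable; both are
verified against raw-data `t.test` to 1e-9. The Mann–Whitney U wrapper
uses the exact distribution for combined `n ≤ 25` without ties and the
tie-corrected normal approximation otherwise (fully tied inputs therefore
get the approximation). Normality checks use Lilliefors (KS with
estimated parameters) and Shapiro–Wilk. The conventional significance
threshold is exported as `SIGNIFICANCE_LEVEL` (0.05).

## File formats and degenerate inputs

Grid-text height maps (`#`-header + delimited rows) round-trip exactly;
the 16-bit raster format stores counts with a user-held scale/offset, so
round-trip error is bounded by `scale/2`; STL (ASCII and binary) meshes
are resampled by in-triangle linear interpolation, which is exact on
affine surfaces, and folded meshes are rejected because they are not
height fields. After resampling, the grid is greedily trimmed to a full
rectangle from the boundary. Degenerate inputs fail loudly: ragged or
non-finite grids, all-zero correlation overlaps, alignments with fewer
than 3 overlapping samples, signatures shorter than 10 samples after
trimming, single-pixel images, zero-variance samples.

## Problem sizes used in the test suite

The KM/KNM separation checks run the full reference design (10 knives ×
2 marks on 261 × 1004 grids) across five study seeds. Property and
monotonicity suites (e.g. mean `X_max` decreasing over noise
`{0, 0.5, 1, 2}` µm, mean `L_Xmax` increasing over jitter `{0, 1, 3, 6}`
samples, 20 seeds per level) use reduced marks of 30 × 300 points, a size
at which the rank orderings are already stable; oracle-equivalence checks
for the lag search use profiles up to length 60 where the brute-force
double loop is cheap.

## Known limitations

Integer-lag alignment only; no 2D (areal) correlation, rotation
correction or striae-counting (CMS) methods; no likelihood-ratio
calibration of scores; the renderer is not a full photometric model; the
indentation module excludes viscoelasticity, adhesion and
finite-thickness corrections. These are deliberate scope boundaries, not
planned features.
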