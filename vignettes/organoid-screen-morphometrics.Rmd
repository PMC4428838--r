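---
title: "Morphometric profiling of 3D organoid invasion screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric profiling of 3D organoid invasion screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Prostate-cancer cells grown in laminin-rich extracellular matrix form
multicellular organoids whose shape reports their state: differentiated,
non-invasive cultures form round acini, while invasive cultures grow
stellate structures with branch-like multicellular protrusions penetrating
the matrix. A phenotypic compound screen in this format asks, for every
compound x concentration x cell line, three questions: did the organoids
grow (size), did they invade (shape), and did they die (dead-cell stain)?
`organoscreen` implements that read-out chain on two-channel
maximum-intensity projections — green for the live stain (calcein AM-like)
and red for the dead stain (ethidium homodimer-like) — together with a
synthetic image generator so the whole chain can be validated against known
ground truth without any microscopy data.

## The three read-outs

Per segmented organoid, with `A` the number of pixels in the object and `P`
the number of its border pixels:

* **Size** — `a = log A`. The log of organoid area is close to Gaussian, so
  downstream medians and anchors operate on the log scale.
* **Shape complexity** — organoid populations follow a tight power law
  between perimeter and area; on log scales it is close to linear, and a
  robustly fitted line `log P = b log A + c` estimates the *average*
  perimeter of a structure of a given size. An organoid's deviation above
  that average is its shape complexity. The intercept is lowered to
  `c0 = min_i(log P_i - b log A_i) - eps`, so that the most circle-like
  object in the fitting sample sits at the positive floor `eps` and every
  residual `r = log P - (b log A + c0)` is strictly positive; `kappa =
  log r` is the per-organoid complexity score. The fit uses Theil–Sen
  regression (median of pairwise slopes): deterministic, robust, no tuning.
* **Cell death** — `rho = R / A`, the fraction of object pixels whose red
  intensity exceeds the red threshold: the relative area of dead cells
  within the organoid.

A fourth, supplementary measure is the isoperimetric roundness
`100 * 4 pi A / P^2` (capped at 100), used for time-course invasion
trajectories in 2D validation work.

Wells are summarised by the medians of `a`, `kappa` and `rho` over their
organoids; medians keep debris and segmentation outliers from steering the
well value.

### Properties and caveats of the complexity statistic

* It is *scale-aware*, not scale-free: discs of any size stay within a
  narrow residual band (< 0.1 log units in our oracle tests) while any
  branched shape exceeds it.
* The reference line must be fitted across the full round-to-stellate
  spectrum. Fitted on heavily branched objects alone, the slope drifts from
  ~0.5 towards 1 and residuals pick up a spurious size dependence. The
  pipeline therefore pools all objects of one cell line (controls and
  treatments) for the fit; with fewer than ten usable objects the fit is
  refused.
* `kappa = log r` is close to symmetric when rounded organoids dominate the
  population, which is when `r` itself is strongly right-skewed. In
  invasive-dominated populations `r` is left-skewed and the log
  overcorrects; moreover the anchoring object sits at `r = eps` by
  construction, an extreme point in log space. Summaries of `kappa` are
  medians throughout, which are insensitive to both effects.
* The perimeter is literally a border-pixel *count*, not a contour length.
  A digital disc of radius `r` has about `0.89 * 2 pi r` border pixels, and
  nearest-neighbour x2 upscaling multiplies the count by ~2.45 for
  staircase boundaries (exactly ~2 for axis-aligned ones). All downstream
  statistics are built on ratios or robust fits of this count against area,
  so the convention cancels; absolute perimeter values should not be
  compared against continuum formulas.

## Control-anchored scaling

Raw medians are not comparable across read-outs, plates or cell lines, so
every read-out is linearly re-expressed against the plate's own controls:

```
score = 100 * (x - m_dmso) / |m_pax - m_dmso|
```

with `m_dmso` and `m_pax` the medians of the well-medians over vehicle
(DMSO) and positive-control (paclitaxel) wells of the same cell line (at
least two wells each). The vehicle thus maps to 0 and the positive control
to -100 on read-outs it lowers (area, complexity) and +100 on read-outs it
raises (cell death). The absolute-value denominator is the only single
expression that produces both signs correctly; dividing by the signed
difference would flip the death axis. Scores are not clipped — a compound
can beat the positive control. Scaling is affine-invariant in the raw
read-out and idempotent (re-anchoring anchored scores changes nothing).
If the positive control does not separate from vehicle on some read-out,
the anchors are degenerate and scaling refuses with an error rather than
amplifying noise.

## Clustering and compound calls

Profiles (one row per compound x concentration, columns
read-out x cell line, missing cell-line blocks imputed to 0 with a flag)
are clustered with Euclidean distance and Ward linkage — compact classes on
a common anchored scale, with average/complete linkage available. The
dendrogram is deterministic and invariant to input row order and to uniform
rescaling of all features.

Cluster structure is descriptive; the compound *calls* are rule-based on
the anchored scores, with defaults `T_strong = 60`, `T_weak = 25` and
tolerance bands of 25:

* `growth_inhibitory`: `s_area <= -60` (takes precedence over all
  anti-invasive calls);
* `anti_invasive_strong`: `s_complexity <= -60` with `s_area >= -25` and
  `s_death <= 25` (shape reverted without killing or shrinking);
* `anti_invasive_weak`: `-60 < s_complexity <= -25` under the same side
  conditions;
* `inactive` otherwise.

The thresholds are package defaults on the anchored scale, not empirical
constants; they sit far from the planted effect sizes used in validation
(|s| >= 60 vs noise sd ~10), so the calls there are insensitive to the
exact values. Classification is monotone: strengthening complexity
suppression at fixed area/death never demotes a call.

## The synthetic-data generator

The generator emulates exactly the features the read-outs consume:

* **Size law** — total structure area is log-normal, `log A ~ N(mu,
  sigma^2)` with defaults `mu = 8.0`, `sigma = 0.4` (median ~3000 px,
  organoid radius ~30 px at the default scale). The law governs the *total*
  structure: the core radius is solved from the target area given the
  branch geometry, so suppressing invasion reshapes an organoid without
  mechanically shrinking it, and a purely anti-invasive compound leaves the
  size read-out near zero.
* **Shape** — a core disc with `Pois(lambda)` radial branches (default
  baseline `lambda = 6`, invasive), branch length one core radius beyond
  the rim, width a quarter radius, angles uniform; low-order harmonic
  boundary roughness (`jitter = 0.1` by default; 0 gives exact digital
  discs for oracle work). Branches start at the centre, so every organoid
  is one 8-connected component.
* **Death** — a contiguous sub-mask of `round(death_fraction * A)` pixels
  (nearest-to-seed pixels within the organoid) is rendered into the red
  channel, making the dead ratio exactly recoverable; baseline
  `death_fraction = 0.05`.
* **Pharmacology** — per-compound Hill effects `emax * c^h / (ec50^h +
  c^h)` on three targets: *invasiveness* scales branch number and length
  down, *growth* scales the core radius down, *death* moves the dead
  fraction towards a 0.9 ceiling. Vehicle wells ignore all effects;
  positive-control wells use a fixed paclitaxel-like preset (growth 0.5,
  invasiveness 0.9, death 0.8) — strong growth suppression and death
  induction at any listed concentration.
* **Imaging** — additive Gaussian noise at SNR 10 (foreground contrast
  over noise sd) on a [0, 1] intensity scale (foreground 0.8, background
  0.05), 16-bit TIFF output, default canvas 1024 px at a nominal 2 µm/px;
  all measures are reported in pixels and the µm calibration is left
  configurable because only relative, control-anchored quantities are used.
* **Placement** — rejection-sampled centres with a minimum separation and a
  border margin; organoids that cannot be placed within the packing limit
  are dropped with a warning and never enter the ground truth, keeping the
  conservation invariant (sum of ground-truth areas = foreground of the
  label image) exact.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: optics (PSF, z-attenuation, uneven
illumination), cell-scale texture inside organoids, touching/overlapping
structures (real plates have them; the segmenter flags rather than splits
merged objects, and no watershed separation is attempted), plate-position
effects, and any cell-line biology beyond parameter presets.

## Numerical choices

* Otsu thresholding per image on the green channel; the red threshold is
  Otsu with a contrast guard (fallback to a fixed 0.5 when the upper class
  is weak or covers > 25% of pixels, i.e. when there is no real red
  foreground to find). Objects below 64 px or touching the image border are
  dropped by default — truncated organoids bias both `A` and `P`.
* Labeling is 8-connected (4-connected labels merged across diagonal
  contacts); the border test for `P` uses the complementary 4-neighbourhood.
  Coordinates are row-major, 0-based at the pixel level.
* Theil–Sen uses the exact median of all pairwise slopes up to 1000 points
  and a deterministic, evenly spaced subsample of 1000 (ordered by the
  regressor) beyond that, so fits are reproducible at any scale.
* `eps = 1e-6` keeps `log r` defined at the anchor without distorting
  ranks. Out-of-sample objects falling below the adjusted line are clamped
  to `eps` and flagged.
* Hole filling is on by default (real organoid interiors are dim); the
  noise-free exact-recovery oracle runs with it off, because a branch
  crossing a rough boundary can enclose single background pixels that
  filling would add to the area.
* All per-well randomness derives deterministically from one master seed,
  so plates are reproducible independent of evaluation order and identical
  seeds give byte-identical CSV outputs end to end.

## Validation problem sizes

The shipped validation suite runs the full chain at desk scale: 96-well
plates on a 512 px canvas with 6 organoids per well (`log_area_mu = 7.6`)
for the anchoring checks; a 384 px canvas, 16 wells and 20 seeds for
planted dose-response recovery (anti-invasive compound: emax 1, EC50
0.3 µM, Hill 2 over 0.03/0.1/0.3/1 µM; cytotoxic comparator; seed-level
scores summarised by per-dose medians across seeds); 12 wells for
segmentation fidelity (>= 95% of ground-truth organoids matched 1:1 at
IoU >= 0.7 at SNR 10, exact area recovery in the noise-free limit); and
planted three-class profile screens for clustering recovery (adjusted Rand
index >= 0.9 over 20 seeds). These sizes are the package's validation
choices; the generator's biological defaults (canvas 1024, organoid scale,
SNR, dose grid) are unchanged by them.

## Known limitations

* Touching organoids are measured as one object (flagged by their IoU
  mismatch in validation, never split).
* The wound-healing module takes wound-area time series, not raw
  phase-contrast images; the effectiveness call uses fixed-horizon
  semantics (RWD at the horizon <= cut, boundary inclusive).
* The dead-cell read-out is the relative red *area* within each organoid; a
  red-object count is not used. Both conventions appear in the screening
  literature; the area ratio is the one that is exactly recoverable from
  ground truth and independent of the complexity model.
* Published cluster memberships of any particular screen depend on
  unreported linkage/cut choices and are not claimed reproducible; the
  package validates clustering on planted classes instead.
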