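---
title: "Topological statistical mapping of sensor-level M/EEG data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological statistical mapping of sensor-level M/EEG data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topostat)
```

## The inference problem

Event-related EEG and MEG experiments produce a statistic at every sensor
and every peristimulus time point (and, after time-frequency
decomposition, every frequency). Asking "where and when does the effect
occur?" without an a-priori region means searching tens of thousands of
correlated tests. Bonferroni correction controls the family-wise error
rate (FWER) but ignores the strong spatial and temporal correlation of
neighbouring samples, and is far too conservative on smooth data.

`topostat` implements the alternative used throughout statistical
parametric mapping: convert the sensor data into images, smooth them,
fit a mass-univariate general linear model (GLM) at every voxel, and
correct the resulting t/F maps with random field theory (RFT), which
adjusts p-values through the expected Euler characteristic (EC) of the
excursion set of a smooth random field. The FWER of the height
threshold $u$ over a search region with resel counts $R_d$ is
approximated by

$$ P\left(\max Z > u\right) \;\approx\; \sum_{d=0}^{D} R_d\,\rho_d(u), $$

where $\rho_d$ are the EC densities of the field type (Gaussian, t or
F; the unified closed forms are implemented in `ec_density()`), and the
resels $R_d$ measure the search region in units of the field's
smoothness (FWHM per dimension). The smoother the data, the fewer
resels, the milder the correction.

## From sensors to images

`dataset_to_volumes()` builds one scalp map per time frame — Delaunay
triangulation of the 2D sensor layout with barycentric linear
interpolation (exact on affine fields) — and stacks the maps over
peristimulus time into a space × space × time NIfTI volume, one image
per condition (averaged data) or per retained trial (epoched data).
Defaults follow common practice: 64 pixels per spatial dimension, a 5%
margin around the good-channel bounding box, and the layout disc mapped
to a nominal 100 mm radius so that smoothing kernels specified in mm
are meaningful. Bad channels are either interpolated from their
neighbours (preferred) or removed; removal punches NaN holes wherever
the nearest channel is bad (distance ties favour the good channel), and
masked renormalized convolution in `gaussian_smooth_image()` propagates
those holes instead of smearing values into them. Smoothing uses a
separable Gaussian kernel truncated at 4σ, with kernel mass
renormalized at image borders. The default kernel for the package's own
experiments is 8 mm × 8 mm × 8 ms — the governing rule is the matched
filter principle (kernel ≈ expected effect extent), not any fixed
number.

Time-frequency data follow the same route: `morlet_transform()` yields
power per trial, channel, frequency and time from unit-energy complex
Morlet wavelets ($\sigma_t = n_{cycles}/2\pi f$, support truncated at
$5\sigma_t$, reflection padding at epoch edges, default 7 cycles for
stable estimates). Because statistical search is limited to three
dimensions, two reductions are provided: averaging power over channels
(`tf_image_from_channels()`, frequency × time images) or over a
frequency band (`band_average_to_dataset()`, a time-domain power
dataset that re-enters the image pipeline).

## GLM and topological inference

`fit_glm()` estimates the model by voxelwise least squares
(pseudoinverse, so rank-deficient designs such as the paired design are
handled), masking out voxels missing in any image. `compute_contrast()`
produces t maps ($t = c^\top\hat\beta / \sqrt{\hat\sigma^2\, c^\top
(X^\top X)^- c}$) or F maps by the extra-sum-of-squares comparison of
the full model against the model reduced by the contrast's null space.

Smoothness is estimated from the standardized model residuals:
$\lambda_j$ is the mean squared first difference along dimension $j$
(over images and in-mask voxel pairs), and
$\mathrm{FWHM}_j = \sqrt{4\ln 2/\lambda_j}$. Resel counts use the
cuboid formulas on the mask's bounding box, with the top-order count
taken as the in-mask voxel count divided by the FWHM product. No
small-sample bias correction is applied to $\lambda_j$; with at least
~20 residual images the residual bias is a few percent (the FWHM
recovery test at 30 images is within 10% at FWHM 4–8, and the
standardization to exactly unit pooled variance removes the largest
finite-sample term).

`topological_report()` thresholds the map (default cluster-forming
height p = 0.001 uncorrected), labels clusters by 18-connectivity in 3D
(8 in 2D, ties in local maxima resolved by first-index order), and
reports peak-level corrected p-values
$\min(p_{\mathrm{RFT}}, p_{\mathrm{Bonferroni}})$ and cluster-level
p-values from the Gaussian-field extent distribution
$P(\text{extent} \ge k) = \exp(-\beta k_{resel}^{2/D})$; t and F
cluster-forming thresholds are probit-Gaussianized first. A window mask
restricts the search (small-volume correction) and recomputes resels on
the restricted region, so a peak inside the window never loses
significance by the restriction.

Numerical choices worth knowing: the expected-EC sum is not a valid
p-value below its mode (EC densities of order ≥ 2 are negative at low
thresholds), so `rft_peak_p()` saturates the p-value below the
decreasing branch, keeping it monotone in $u$; `rft_threshold()`
inverts it by bisection starting from the uncorrected quantile.

## Contrast summaries over time and frequency

`build_time_weights()` converts one or more peristimulus time segments
into a weight vector: the segment indicator convolved with a Gaussian
of 8 ms FWHM, normalized to unit sum. A degenerate segment (t1 = t2)
therefore becomes a pure 8 ms FWHM Gaussian. The 8 ms edge is also used
for finite segments — the single-point case then emerges as the limit
of the same formula. With frequency band 0, `apply_energy_contrast()`
reduces to the signed weighted time average of the trial mean, which
can legitimately cancel to zero for polarity-reversing responses; with
a band, Morlet projectors on a 1 Hz grid (7 cycles) summarize energy,
and the mode distinguishes **evoked** (energy of the trial average —
phase-locked activity only), **induced** (average of per-trial
energies — includes non-phase-locked power) and **trials** (one value
per trial; their mean is exactly the induced value). Integrating a
wideband energy contrast is equivalent to summing squared amplitudes
over the window (the package's tests verify proportionality within
5%). These contrasts accept any labelled time-series ensemble —
channels here, but the mathematics is identical for reconstructed
source time courses.

## Coregistration utilities

`icosphere()` generates the canonical closed surfaces by recursive
icosahedral subdivision ($10 \cdot 4^{level} + 2$ vertices; level 4
gives the 2562-vertex scalp/skull tessellation).
`project_to_layout()` flattens 3D sensor positions by
azimuthal-equidistant projection about the head apex.
`landmark_fit()` solves the rigid (no scaling, no reflection)
orthogonal Procrustes problem for matched fiducials in closed form, and
`icp_align()` refines the fit by iterative closest point: nearest
target vertex correspondence, rigid re-fit, apply — RMS is
non-increasing and iteration stops when it changes by less than 1 mm/1000
(`tol = 1e-6` m, cap 50 iterations; these defaults are the package's
own choice). Only rigid transforms are produced; template scaling for
EEG electrode sets is out of scope. Nearest-neighbour search uses the
target vertices directly, which is adequate at icosphere level ≥ 3
densities. Head coordinates follow the usual convention: origin midway
between the preauricular points, x to the right preauricular, y to the
nasion, z up; meters internally.

## What the synthetic-data module emulates

All validation runs on synthetic data with known ground truth:

* `gen_montage()` — quasi-uniform sensors on an 0.09 m hemisphere
  (Fibonacci lattice with a small seeded jitter) plus nasion/preauricular
  fiducial analogues.
* `gen_dataset()` — trials as a sum of effects and noise. An effect is
  a dipolar-style topography (signed Gaussian bumps over layout
  distance, normalized to peak 1), a Gaussian temporal envelope, an
  optional carrier oscillation with fixed (evoked) or uniform-random
  per-trial (induced) phase, and one amplitude weight per condition.
  Noise is AR(1) in time (coefficient 0.3 by default) with
  $\exp(-d/\ell)$ spatial correlation over the layout
  ($\ell = 0.3$ disc units by default, diagonal jitter $10^{-8}$ for a
  stable Cholesky factor) and calibrated marginal SD — values chosen
  once as representative of moderately autocorrelated sensor noise.
* `gen_null_volume()` — white Gaussian noise convolved (on a padded
  lattice, so every voxel keeps full kernel support) with a Gaussian of
  stated FWHM and rescaled to exactly unit pointwise variance: a
  stationary smooth Gaussian null field of known smoothness.

Every generator is a pure function of its spec and seed. What the
generator does **not** emulate: realistic forward-model topographies
(no volume conduction), non-stationary noise, artifacts, or
between-subject variability. Passing tests therefore demonstrate the
statistical machinery is calibrated on data satisfying its assumptions,
not that real recordings satisfy them.

## Calibration results and limitations

The core validation simulates 500 null experiments (two groups of 12
smooth Gaussian images, 32 × 32 × 20 voxels, FWHM 6), runs the full
two-sample GLM → F contrast → residual smoothness → RFT pipeline, and
counts experiments with any corrected-significant voxel at α = 0.05.
The empirical FWER must stay below the nominal level (plus binomial
error); the suite and `scripts/acceptance.R` recompute it from scratch.

Known behaviour worth stating plainly:

* **Validity over exactness.** The expected-EC correction is an upper
  bound on the FWER. For Gaussian fields at FWHM 6 the empirical rate
  is close to nominal (≈ 0.04 at α = 0.05 in the package's own
  simulations); for F(1, 22) fields it is conservative (≈ 0.01–0.03) —
  a known property of the EC heuristic for heavy-tailed fields at
  moderate degrees of freedom, visible even with the true smoothness
  supplied. Control is never anti-conservative in any tested
  configuration.
* **RFT vs Bonferroni crossover.** On a 32 × 32 × 20 mask the pure-RFT
  Gaussian threshold drops below Bonferroni at about 3.3 voxels FWHM
  (≈ 4.5 for t with 22 df); below that the Bonferroni floor in the
  reported p-values takes over, so the package's corrected threshold
  never exceeds Bonferroni at any smoothness.
* **Cluster inference** uses the Gaussian-field extent approximation
  with probit Gaussianization for t/F fields; it is asymptotic in
  threshold height and smoothness and less accurate for low
  cluster-forming thresholds.
* **Resel counting** for irregular masks approximates lower-order
  counts by the mask's bounding box; only the top-order count uses the
  exact voxel count.
* Problem sizes in the tests (image shapes 32 × 32 × 20 and 48 × 48 ×
  20, 150–500 Monte-Carlo replicates, 30-image smoothness recovery) are
  the package's chosen validation scale: large enough for binomial
  error bands around the quantities being checked to be informative.

## Design decisions that were genuinely open

* Wavelet normalization is not standardized across toolboxes; unit
  total energy was chosen. All tested properties (power ratios, peak
  locations, evoked/induced dissociation, Parseval proportionality)
  are invariant to this choice.
* The spatial footprint of a removed bad channel is not canonically
  defined; nearest-channel masking was chosen and flagged as such.
* Bad channels are excluded at image export, not from trial averaging —
  averaging is harmless for flagged channels and keeping them preserves
  information for later re-flagging.
* The Gaussian edge width for finite time windows reuses the 8 ms
  single-point FWHM, making the degenerate and finite cases one
  formula.
* Condition labels match by exact, case-sensitive string equality to
  avoid silent merging.
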