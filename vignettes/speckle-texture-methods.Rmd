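---
title: "Speckle texture analysis of OCT volumes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speckle texture analysis of OCT volumes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Ultrahigh-resolution optical coherence tomography resolves retinal
microanatomy but not organelles. The speckle of a coherent image, however,
is shaped by sub-resolution scatterer structure: when mitochondria
fragment from a filamentous network into discrete rounded bodies during
early apoptosis, the spatial correlation structure of the image texture
changes even though no individual organelle is resolved. `speckletex`
implements a complete label-free analysis built on this principle:
3D image stacks are parameterized by a 65-dimensional texture feature
vector; classes of images (control vs degenerated, or consecutive
timepoints) are modeled as Gaussian mixtures; new images are classified by
Mahalanobis distance; informative features are selected by sequential
forward search scored by a Bernoulli-error BIC; and progressive texture
change is tracked as a Texture Index (TI) along the maximum-variance axis
of a Sammon embedding.

Because no real OCT recordings ship with the package, every analysis runs
on synthetic speckle phantoms with a controllable degeneration parameter.
The phantom is a first-class, tested module, and the limits of what it
emulates are documented below.

# The phantom

`generate_phantom()` builds a stack in six steps:

1. A Poisson field of scatterer seeds fills a slab below the coverslip
   plane; convolution with a spherical clump kernel gives a scatterer
   strength map. The slab has raised-cosine axial edges (about 3 voxels):
   cell layers do not end in step functions, and razor edges would place
   strong oscillatory structure on exactly the spectral lines used for
   fixed-pattern artifact detection.
2. A circular complex Gaussian phasor field weighted by the square root of
   the scatterer map is blurred with a Gaussian point-spread function and
   magnitude-detected. Where the scatterer map is locally uniform this is
   fully developed speckle: the amplitude is Rayleigh to good
   approximation (Kolmogorov–Smirnov distance about 0.03–0.05 against a
   fitted Rayleigh law at $10^4$ sampled voxels; the residual deviation is
   the clump-scale envelope modulation, which is exactly the texture
   signal the features measure).
3. A bright coverslip plane (Gaussian axial profile, amplitude 92% of the
   dynamic range) is added, tilted by the first two `tilt_deg` components.
   The third component — rotation about the optical axis — leaves a plane
   invariant; it is accepted for interface completeness but has no effect.
4. A fixed-pattern sinusoidal line artifact along depth (identical in
   every A-scan, the classic OCT fixed-pattern noise) is added; the
   default frequency 0.28125 cycles/voxel is bin-aligned for dyadic stack
   sizes so the artifact is spectrally concentrated (a deliberately
   notchable artifact; frequency leakage from non-aligned patterns is a
   documented limitation).
5. Gaussian background noise (default sd 2 quantization levels) is added.
6. The result is quantized to `bit_depth` (default 8).

**Degeneration mapping.** `degeneration` $\in [0,1]$ shrinks the clump
radius linearly to 40% of its control value with the clump count held
fixed — fragmentation in place. We deliberately do not also increase the
clump density: the in-ROI histogram equalization applied before feature
extraction removes amplitude-contrast information, so the features respond
to spatial correlation structure only, and a density increase partially
cancels the radius effect at small degeneration, breaking monotone drift.
With the pure radius mapping the multivariate feature trajectory is
monotone across the whole range (measured per-step standardized shifts of
+4 to +7 on a 6-point schedule at 8 stacks per point).

Defaults: clump radius 3.5 voxels, seed density 0.02 per voxel, PSF sigma
(1.4, 1.1, 1.1) voxels (axial, transverse), voxel pitch 1.46 µm (1024
pixels spanning 1492 µm), stack shape 128 × 64 × 64 — the explant ROI
geometry. No quantitative speckle statistics of the original recordings
are available, so these are design choices, not measurements; they are
configuration, and every analysis records them in its manifest.

**What the phantom does not emulate:** multiple scattering, depth-dependent
signal roll-off, confocal gating, refraction at the coverslip, detector
shot noise statistics, or sample motion. Passing tests on phantoms
demonstrate that the analysis chain recovers known structure from
speckle-like data; they do not certify performance on real recordings.

# Preprocessing

The stage order is fixed: reflection clipping → FFT notch filtering →
coverslip detection → tilt removal → optional cropping.

- **Reflection clipping**: voxels saturated over ≥ 5 consecutive axial
  samples are replaced by their 3×3×3 median.
- **Line-artifact removal**: per B-scan 2D FFT. Fixed-pattern structure is
  coherent across B-scans, so peaks are detected on the slice-averaged
  amplitude spectrum of the two spectral axis lines (kx = 0 and kz = 0): a
  bin is flagged when it exceeds the median + 6·MAD of a 15-bin running
  window along its line *and* carries at least twice the band's power.
  The band is the local neighborhood along the axis line, not a radial
  ring: genuinely planar image structure (the coverslip) occupies the
  same axis lines at all radii and must not be notched. Flagged bins are
  attenuated to the median of their ±2–8 neighbors in every slice, phase
  preserved; DC ± 2 bins are never touched. With no detected peaks the
  stage is exactly the identity.
- **Coverslip detection**: the axial gradient magnitude (the
  high-frequency image component along depth) is smoothed 9×9
  transversely — incoherent speckle gradients average out, the coherent
  interface survives — and 5 samples axially, merging the interface's two
  flank peaks. Per-column peak depths are refined by parabolic
  interpolation and a plane is fitted by least squares with iterated
  3-MAD outlier rejection. Injected tilts of a few degrees are recovered
  to within about 0.05°.
- **Tilt removal**: implemented as sub-voxel axial shear (each transverse
  column is shifted along z by linear interpolation onto the fitted
  plane). For the tilts in scope (< 30°) shear inverts a plane tilt
  exactly and agrees with a rigid rotation to first order; it also
  preserves the stack's dimensions exactly, with out-of-domain voxels set
  to zero. Tilts below 0.05° move the farthest voxel by less than the
  quantization step and are skipped.

The full pipeline is idempotent to within one quantization level RMS.

# ROI masking

Automatic masking thresholds the stack (Otsu by default; the original
protocol used a manually chosen threshold, so an explicit level is
accepted), keeps the largest 26-connected component, closes it with a
discrete ball (default radius 5), fills interior cavities (background
components not touching the volume boundary), erodes (default radius 2,
set empirically to clear background), and keeps the dominant body —
yielding a single homogeneous hole-free 3D mask. Ball morphology is
implemented through an exact Euclidean distance transform, so any radius
costs the same three separable passes. Closing is applied before hole
filling and erosion last; the original order is unstated.

Seeded mode (`mask_roi_manual()`) refines user-supplied boxes (read from
JSON; the original used a Matlab GUI) independently by the same procedure;
masks may overlap and are not deduplicated.

In-ROI histogram equalization maps in-ROI intensities through their
empirical CDF onto the full quantization range (global over the ROI, not
adaptive), leaving out-of-ROI voxels untouched. It removes depth-of-focus
brightness variation — and, with it, absolute-contrast information; all
downstream features therefore measure spatial structure, not brightness.

# The 65 features

Group sizes are 12 + 2 + 12 + 21 + 18 = 65, audited at build time.

- **Local statistics (12)**: per-voxel entropy (5³ window, histogram over
  the full gray range), range and standard deviation (3³ windows),
  computed in 3D over the ROI bounding box; each map is normalized by the
  gray-scale resolution (entropy / bit depth; range / (2^bits − 1);
  sd × 2 / 2^bits) and summarized across in-ROI voxels by mean, median,
  entropy (again / bit depth) and sd (again × 2). The neighborhood sizes
  are unstated in the original description; 3D windows are used since the
  maps are defined for every voxel of the 3D image.
- **Moments (2)**: standardized third and fourth central moments
  (population denominators) of the in-ROI intensities; a zero-variance
  ROI returns (0, 0) with a warning.
- **Co-occurrence (12)**: gray levels quantized to 8 equal-width bins;
  for a +5-voxel offset along each of x, y, z (one cell diameter), pairs
  with both endpoints in the ROI are accumulated, symmetrized and
  normalized; contrast, correlation, energy and homogeneity follow the
  standard definitions, with the correlation of a degenerate single-level
  matrix set to 1.
- **Granulometry (21)**: in-ROI voxels are binarized by Otsu on the
  in-ROI histogram; dark ("black") voxels are labeled by 26-connectivity
  within the ROI; particle sizes fill 12 geometric bins (powers of two
  from 1 to 4096 voxels, the last bin absorbing larger particles), then
  pairwise-summed 6- and 3-bin versions; all normalized by total particle
  count. After equalization roughly half the ROI is below threshold, so a
  percolating giant component plus many small particles is the typical
  configuration; the small-particle spectrum carries the texture signal.
- **Directional wavelets (18)**: each en-face slice is filtered with an
  oriented complex wavelet bank — log-Gabor radial profiles at the three
  smallest dyadic scales (wavelengths 4, 8, 16 voxels; radial bandwidth
  parameter 0.65) times a Gaussian angular window (sigma 22.5°) around
  the x, y and 45° directions, restricted to the analytic half-plane so
  the magnitude is a smooth envelope. In-ROI magnitudes pooled over
  slices give a mean and sd per direction × scale. An analytic filter
  bank was chosen over the dual-tree complex wavelet transform because it
  realizes the stated directions (x, y, 45°) exactly, has a closed-form
  definition (no dependence on published filter-bank coefficient tables),
  and keeps the 90°-rotation covariance exact; the diagonal channel pools
  the 45° and 135° orientations so that a 90° rotation maps the feature
  set onto itself. Slices are cropped to the padded ROI bounding box,
  which makes all features exactly invariant to whole-voxel translations
  away from the stack border.

# Class models and classification

Each class is a full-covariance Gaussian mixture fitted by EM (k-means
initialization, 5 restarts, convergence at 10⁻⁶ relative log-likelihood,
at most 100 iterations). Covariances are regularized by a trace-scaled
ridge (10⁻⁶ of the mean diagonal, with an absolute floor so exactly
degenerate data still yield a scaled-identity covariance), and a restart
is rejected when any component's effective weight falls below d + 1
points — the standard guard against likelihood blow-up through collapsing
components. The component count is chosen by AIC = 2p − 2 ln L among
candidates (default 1–4, matching the biological assumption of up to four
subpopulations per class); p is the full mixture parameter count
k(d + d(d+1)/2) + (k−1) by default, with a `"k"` switch counting only the
number of subpopulations for comparison. AIC with the full parameter
count is known to be liberal for mixtures — on two well-separated
Gaussian components, candidate counts of 3 or 4 win a sizable minority of
fits (in our measurements, and in mclust's reference ML fits) — so
studies that need a sharp 1-vs-2 decision should restrict the candidate
set accordingly.

A new image's distance to a class is the minimum Mahalanobis distance to
any of its mixture components (the aggregation across components is
unstated in the original; minimum is the natural choice for a
nearest-subpopulation reading), and assignment goes to the minimal-distance
class, ties broken lexicographically. Cross-validation is
leave-one-imaging-session-out: subsets are the unit of holdout, per-fold
mixtures are refitted from scratch, and folds whose training data lack a
class are skipped with a warning.

# Feature selection

Sequential forward search adds, at each step, the feature minimizing the
leave-one-subset-out classification error on the training data (inner
mixtures default to a single component, which keeps the inner loop
closed-form), ties broken by registry order. The feature-set size is the
prefix minimizing the Bernoulli-error BIC

$$\mathrm{BIC}(k) = -2\, n\,[\,\hat p\log\hat p + (1-\hat p)\log(1-\hat p)\,] + k\log n,$$

with the error rate clamped to [1/(2n), 1 − 1/(2n)] so the likelihood is
finite at zero observed error. The penalty's n is the number of validated
images; a `"features"` switch implements the literal reading in which n
is the feature count. In the nested procedure each held-out subset never
influences the ranking computed on its training complement, and the union
of per-fold selections — ordered by earliest selection step, then name —
is the working feature set when training data are scarce.

# Projection and the Texture Index

Pairwise distances between images use each class's covariance: within a
class, plain Mahalanobis; across classes, the mean of the two
class-metric distances (the symmetrization of the cross-cluster distance
is unrecoverable from the original text; the arithmetic mean is
implemented and isolated in one function). With few images per class the
per-class covariance is a noisy metric, so each estimate is shrunk toward
the pooled within-class covariance (weight 0.8 by default) — a standard
small-sample stabilization.

The Sammon embedding minimizes
$\sum_{i<j} (D_{ij}-d_{ij})^2/D_{ij} \,/\, \sum_{i<j} D_{ij}$ by gradient
descent with step halving (step grows 1.5× after a successful iteration),
initialized from classical metric MDS; zero off-diagonal distances are
floored at 10⁻¹², convergence at 10⁻⁹ relative stress improvement or 500
iterations. The recorded stress path is non-increasing by construction.
MDS initialization dominates random initialization in the large majority
of trials, and on planar-realizable distances the embedding is exact to
machine precision.

The maximum-variance (MVP) and second-variance (SVP) axes are the
principal axes of the pooled embedded cloud (all classes jointly — the
published projections display one shared axis pair). The Texture Index of
a timepoint is the displacement of its center from the reference
timepoint's center along MVP, sign-oriented so the final timepoint is
nonnegative; confidence intervals are normal-theory
(Z s/√N, Z = 1.96 at 95%), and significance against the reference is a
Welch two-sample t-test on per-image MVP coordinates.

For the time-course analysis the embedding space is the union of per-fold
selected features, enriched to at least 8 features by first-vs-last
effect size while skipping features nearly collinear (|r| > 0.9) with
those already taken. The published analyses projected roughly 15
informative features; a minimal classifying set (often a single feature on
well-separated phantoms) makes the class metric rank-deficient in
exactly the redundant directions and the TI unnecessarily noisy.

# Experiment designs and problem sizes

`experiment_config()` mirrors the three study designs with their full
protocol sizes as defaults (two classes × 120 stacks in 8 subsets; 28
cultures × 6 timepoints every 10 min in 6 subsets; 13 explants × 10 ROIs
of 128 × 64 × 64 voxels in 5 subsets). The explant design generates one
retina volume per acquisition, tiles it along x into seeded ROI boxes and
refines each with the automatic masking — the in-package equivalent of
hand-picking inner-plexiform-layer regions — so each box contributes one
feature row. The degeneration schedule for time
courses, c(0, 0.3, 0.55, 0.75, 0.9, 1), is mildly concave — the
largest texture change occurs in the first half of the hour, as in the
biology being emulated — while keeping consecutive acquisitions separated
by several within-class standard deviations so the TI rise is resolvable
at 10 stacks per timepoint.

The analysis scripts and the acceptance checks run reduced-scale versions
chosen to exercise every stage at meaningful statistical power: 20 stacks
per class of 64³ voxels in 4 subsets for the two-class experiment, and
10 stacks per timepoint of 64 × 48 × 48 voxels for the time course. The
automated quality gate (in-ROI mean intensity and speckle contrast within
configured bounds) stands in for the original visual rejection of
out-of-focus images; on clean phantoms it rejects nothing.

# Numerical choices and degenerate inputs

- Otsu thresholding works on the full-range histogram in double
  precision; constant samples threshold at level 0 (so an all-bright ROI
  has no "black" particles and granulometry returns zeros).
- A constant ROI yields the documented degenerate feature vector: zero
  local statistics, (0, 0) moments with a warning, co-occurrence
  contrast 0 / energy 1 / homogeneity 1 / correlation 1, zero
  granulometry, zero wavelet magnitudes.
- Equalization of a constant ROI maps to the top level; equalization is
  idempotent up to quantization.
- EM on duplicated points returns the point with an ε-identity
  covariance.
- Sammon on fewer than 3 points, or rank-deficient MDS initializations,
  fall back to seeded jitter in the second coordinate.

# Known limitations

- The phantom's artifact model is bin-aligned and purely sinusoidal;
  real fixed-pattern noise has harmonics and drifts, and the notch
  detector's consensus logic has only been validated against the model it
  generates.
- Granulometry with Otsu binarization on equalized speckle operates past
  the 3D percolation threshold; its 21 features are dominated by the
  small-particle spectrum and carry less class information here than the
  local-statistics and wavelet families.
- The AIC component-count selector is liberal by construction (see
  above); the package exposes the candidate set so users can restrict it.
- TI values are in embedding units and comparable only within one
  embedding; across runs, compare shapes and significance, not
  magnitudes.
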