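---
title: "Encoding and decoding naturalistic stimulus complexity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding and decoding naturalistic stimulus complexity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(complexcortex)
```

# The problem

How is the *complexity* of what we see and hear represented in sensory
cortex? The package implements a complete analysis chain for answering that
question with fMRI: objective, computable complexity measures for photographs
and music excerpts; preparation of trial-by-voxel response matrices; fusion of
several subjects' data into a common representational space; per-voxel linear
*encoding* models (predict a voxel response from one complexity value) and
ROI-level ridge *decoding* models (predict the complexity value from all
voxel responses in a region); permutation significance tests; and the summary
statistics — significant-voxel overlap across measures and slope-based
sensitivity profiles — that characterize how complexity coding changes along
the cortical hierarchy. A synthetic-data generator with planted ground truth
makes every stage testable without any scanner data.

# Visual complexity measures

All images are first resized to 256 × 256 with Lanczos-3 resampling and
converted to sRGB; the first two measures then work in CIE L\*a\*b\* (sRGB
primaries, D65 white point), whose channel differences approximate perceived
color differences.

**Mean maximum magnitude gradient.** With $S_c(x,y)$ the Lab channel
$c \in \{L, a, b\}$,

$$\mathrm{mean}_{x,y}\; \max_c \; \lVert \nabla S_c(x, y) \rVert,$$

the per-pixel maximum over channels of the gradient magnitude, averaged over
pixels (units: Lab units/pixel). The gradient operator is a central
difference with replicated borders — the standard discrete $\nabla$; the
definition itself does not pin one, so the choice is recorded here and the
implementation is tested against an independent per-pixel loop.

**PNG size.** The byte count of the losslessly PNG-encoded RGB image (libpng
at its default compression level, via the `png` package) — a practical
stand-in for the raster's Kolmogorov complexity. Codec byte counts are only
comparable under one pinned encoder, so the encoder identity travels with the
feature table, and tests assert orderings (a constant image compresses
smaller than noise) rather than absolute counts.

**Self-similarity.** From a pyramid of histograms of oriented gradients
(PHOG): at level $l$ the image is a $2^l \times 2^l$ grid of regions, each
holding a 16-bin histogram of gradient orientations over $[-\pi, \pi)$,
magnitude-weighted and L1-normalized per region. Per pixel the Lab channel
with the largest gradient magnitude supplies orientation and weight,
mirroring the max-over-channel convention above; there is no block
normalization, and zero-gradient regions keep all-zero histograms so they
contribute nothing. The measure is the median over orientation bins $f$ of
the histogram intersection between level 3 and its level-2 parents:

$$\mathrm{median}_f \sum_{x=1}^{8}\sum_{y=1}^{8}
  \min\!\big(\mathrm{PHOG}^{(2)}_{\lceil x/2\rceil,\lceil y/2\rceil}(f),\;
             \mathrm{PHOG}^{(3)}_{x,y}(f)\big).$$

With 16 bins the median is the mean of the two middle order statistics.
Under per-region normalization the value lies in $[0, 64]$, and a pyramid of
uniform histograms gives exactly $64/16 = 4$ — both used as test anchors. A
prose reading that compares the *whole image* with the level-3 regions also
circulates; the level-2-versus-level-3 form above is the one implemented.

# Auditory complexity measures

Music excerpts are 29 s mono clips at 16 kHz. Each measure is evaluated on
sliding windows of 8.82 s with a 0.735 s hop — twelve and one repetition
times of the intended fMRI sequence — which yields exactly 28 windows per
clip, aligning one-to-one with the response windows below.

**Lossless codec size.** Bytes needed by the package's lossless audio codec:
16-bit PCM quantization, 4096-sample frames, fixed linear predictors of
orders 0–3 chosen per frame, Rice-coded residuals with a per-frame parameter
— the core mechanism of lossless audio coding. **Lossy codec size.** Bytes
under the package's lossy transform codec: 1024-sample DFT frames, uniform
quantization of the one-sided spectrum with a step set by a 0–10 quality
parameter (default 5, mid-scale), DEFLATE entropy coding. Sparse or
predictable signals (silence, a pure tone) compress far smaller than noise,
and both sizes grow with added noise amplitude — the properties the tests
pin. Per-window sizes include each window's own header overhead uniformly; a
config flag controls this since either convention is defensible.

**Event density.** The mean rate (Hz) of musical events: detected onsets
divided by duration. The onset detector is spectral-flux novelty with noise
hardening: 32 ms Hann STFT frames with 8 ms hop; bin magnitudes pooled into
32 frequency bands; each band whitened by its clip-wide median magnitude and
log-compressed; half-wave-rectified frame differences summed over bands and
smoothed over three frames. Peaks must exceed a local median threshold
(±0.3 s window, median + 2 MAD), a global robust noise floor
(median + 4.5 MAD of the whole novelty curve), and 5% of the curve maximum;
a peak must be maximal within the 50 ms minimum-inter-onset radius, and
surviving peaks are pruned strongest-first to that gap. Band pooling and
whitening exist because broadband noise otherwise contributes rectified flux
comparable to a genuine tone onset; the 32 ms frame keeps the novelty rise
shorter than the 50 ms gap so rising-edge shoulders are suppressed rather
than double-counted.

A dead-time counter cannot see events closer together than its minimum gap:
a memoryless (Poisson) train at 8 Hz would lose roughly a quarter of its
events to merging no matter how good the detector is. The generator therefore
emits *refractory* Poisson trains (60 ms minimum separation, as for
non-overlapping click stimuli), and rate-recovery tests compare the detected
density against the realized event rate of the signal; recovery is within a
few percent across 1–8 Hz.

# Response preparation

Run-level time series are linearly detrended and z-scored per voxel along
time. Trials are then reduced in one of two ways. For a 3 s TR design, the
trial window is shifted by one TR, cropped to 3 TRs and averaged — one row
per trial. For a 0.735 s TR design, the trial is shifted by 4 TRs, cropped to
40 TRs and passed through a 12-TR moving average with a 1-TR hop. Counting
all full windows would give 29; the window ending exactly at the crop
boundary is dropped (starts satisfy $s + \mathrm{window} < \mathrm{crop}$
strictly), pinning the count at 28 so response and stimulus-feature series
align index by index. Standardization statistics are always estimated on the
training split and applied to the test split — the test set never informs
any estimate. The population variance convention (divide by $n$) is used
throughout, since the model equations only require "unit variance" and one
convention has to be fixed.

# Hyperalignment

Subjects' voxel spaces are fused by iterative Procrustes alignment. The
common space starts as the training data of the subject with the most voxels
(ties broken by manifest order); other subjects are zero-padded to that
dimensionality, which is why the common dimensionality equals the per-ROI
maximum voxel count. Each iteration (default 2, early-stopped when the mean
residual improves by less than 10⁻⁶) fits each subject's
rotation + uniform-scale + translation map to the common space, averages the
aligned subjects, and reassigns the average as the common space. Finally both
splits of every subject are mapped and averaged, giving the mean hyperaligned
train and test matrices the models are fit on.

Transforms are parameterized in the order *scale, translate, rotate*:
$x \mapsto (s\,x + t)R$. A worked anchor: scaling
$\{(1,2),(3,4),(5,6)\}$ by 10, translating by 5 per coordinate and rotating
by $\pi/2$ gives $\{(-25,15),(-45,35),(-65,55)\}$, at root-sum-square
distance exactly 2 from $\{(-24,16),(-45,35),(-66,54)\}$ — reproduced in the
test suite and the acceptance script. The fit itself is the classical
centered orthogonal-Procrustes solution with scaling, converted to this
parameterization. Orthogonal matrices including reflections are allowed (the
common default in hyperalignment software): with zero-padded columns,
proper-rotation-only fits are strictly worse and the distinction carries no
meaning for abstract voxel bases. Scaling can be disabled by a flag.

# Encoding and decoding models

Both model families assume standardized variables. The encoding model for a
voxel is simple least squares, $\beta = (x^\top x)^{-1} x^\top y$ — the slope
measures how many standard deviations a voxel's response moves per standard
deviation of stimulus complexity. The decoding model for an ROI is ridge
regression, $\beta = (Y^\top Y + \lambda I_q)^{-1} Y^\top x$. (The loss is
squared-error ridge; the closed form above is its unique minimizer.)

The penalty is searched on the scale of *effective degrees of freedom*,
$\mathrm{df}(\lambda) = \sum_j d_j^2/(d_j^2+\lambda)$ over the singular
values $d_j$ of $Y$ — a monotone reparameterization on which a linear grid
is meaningful: 100 targets evenly spaced on $[0.1, \min(n,q) - 0.1]$. Each
target is solved for $\lambda$ by Newton's method, warm-started from the
previous target and safeguarded by bisection so convergence is guaranteed on
ill-conditioned spectra. Standardized data have rank at most $n-1$, so grid
targets at or above the rank are mapped to $\lambda = 0$, the least-squares
limit. Among the candidate penalties, leave-one-out cross-validation on the
training set picks the winner by mean squared LOO error, computed exactly
with the hat-matrix shortcut $e_i/(1-h_{ii})$ (verified against explicit
$n$-fold refitting); ties go to the larger penalty. Validation is the Pearson
correlation $r$ between ground truths and predictions on the held-out test
set; zero-variance predictions score $r = 0$ and are flagged.

# Inference

**Permutation test.** The ground-truth order is shuffled independently
within the training and the test set, the model is refit and rescored, 1000
times by default. The chance level is the mean null $r$; the p-value is the
plain fraction of null $r \ge$ observed $r$, which can be exactly zero — the
$(b+1)/(m+1)$ correction is available behind a flag but off by default.
Whether the penalty is re-optimized inside each permutation is configurable;
re-optimization is the default. Under an independent null the p-values are
approximately uniform (checked by simulation), and the rejection rate at
$\alpha = 0.05$ stays within [0.01, 0.10].

**Bootstrap SEM.** Test trials are resampled with replacement, $r$ is
recomputed per resample (degenerate resamples are redrawn, with a retry
cap), and the SEM is the standard deviation of the resampled distribution;
1000 iterations by default.

**Summaries.** Voxels are marked significant at $p \le 0.05$ and
$p \le 0.001$ (uncorrected, as is conventional for these per-voxel maps; a
Benjamini–Hochberg option exists behind a flag). Overlap summaries partition
the union of significant voxels across the three measures into the seven
Venn cells and report fractions *of the union*. Sensitivity summaries report,
over significant voxels only: mean $|\beta|$, the percentage of positive
slopes, and mean $|\beta/r|$ (voxels with $|r| < 10^{-8}$ excluded and
counted), per ROI and measure.

# The synthetic study

The generator produces data with exactly the structure the analysis assumes,
plus known ground truth:

* **Images** — a smooth low-frequency background with $k$ random antialiased
  discs composited on top, $k$ drawn from 0–50, plus light sensor noise added
  after compositing (adding it before lets flat shapes *cover* incompressible
  noise, making PNG size fall with clutter — the opposite of the intended
  construction). Gradient and PNG measures increase with $k$ by rank
  correlation.
* **Audio** — tone bursts (random carrier 200–2000 Hz, 20 ms decay) at
  refractory-Poisson times with rate 1–8 Hz, plus white noise
  (default SD 0.02).
* **Responses** — $y_v = s_v x + \varepsilon$ per voxel, with slope
  magnitudes drawn ±25% around an ROI-level nominal value, a configurable
  fraction flipped negative, and Gaussian noise (default SD 1, i.e. roughly
  unit-SNR at slope 0.8 and weak signal at slope 0.2 — spanning the
  interesting range).
* **Subjects** — the common response space mapped through random orthogonal
  rotations, uniform scales in [0.5, 2] and translations, optionally
  truncated to fewer voxels, plus independent noise. This is the exact
  generative inverse of the hyperalignment model.
* **Stimulus selection** — binary tag matrices are clustered by complete
  linkage on correlation distance into 16 clusters; per cluster the member
  with the highest within-cluster similarity (mean Pearson correlation with
  the other members, ties broken by stimulus order — one concrete reading of
  "highest within-cluster similarity") goes to the test set and the next
  eight to the training set, giving the 16 + 128 design.

What the synthetic data do **not** emulate: natural image or music corpus
statistics, hemodynamic dynamics or autocorrelated noise, and any spatial
structure among voxels. Passing tests therefore demonstrate the correctness
and calibration of the machinery — oracle equivalence, parameter recovery,
null calibration — not that real cortex behaves this way. One visible
consequence: after random subject rotations, the planted sign mixture of
slopes is only partially recoverable in the common space, because the mean
hyperaligned axes are a rotated basis; sign-structure tests therefore run on
the un-rotated planted responses.

# Problem sizes and runtime choices

The test suite and the analysis scripts run the full machinery at moderate
sizes chosen to exercise every code path while completing quickly on one
CPU: images of 64–128 px (the preprocessing target stays 256 in the
defaults), 20–96 stimuli, ROIs of 8–64 voxels, 2–4 subjects, 30–300
permutations in unit tests and 200 simulations × 200 permutations for the
null-calibration check. The pipeline defaults keep the analysis parameters
at their canonical values (window 8.82 s, hop 0.735 s, df grid of 100, 1000
permutations, 1000 bootstrap iterations, α = 0.05).

# Known limitations

* Codec byte counts are encoder-specific; only orderings, not absolute
  values, transfer across encoders.
* The onset detector is tuned for burst-like events over stationary noise;
  legato or heavily overlapped material will undercount, and parity with any
  other event-density estimator is not claimed.
* Ridge decoding assumes a single scalar target per trial; multi-feature or
  banded designs are out of scope.
* Hyperalignment here is ROI-wise Procrustes only — no searchlight and no
  regularized variants.
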