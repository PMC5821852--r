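# complexcortex

Tools for studying how the **complexity of naturalistic stimuli** — photographs
and music — is represented in sensory cortex, for researchers running fMRI
encoding/decoding analyses. The package covers the whole chain:

* **Objective complexity measures.** For images (after 256×256 Lanczos
  resampling): the mean maximum Lab gradient
  `mean_{x,y} max_c ||∇S_c(x,y)||`, the lossless PNG-encoded byte count (a
  Kolmogorov-complexity surrogate), and PHOG self-similarity
  `median_f Σ_{x,y} min(PHOG²_{⌈x/2⌉,⌈y/2⌉}(f), PHOG³_{x,y}(f))`.
  For 29 s music clips on sliding 8.82 s windows with a 0.735 s hop (28
  windows per clip): lossless and lossy codec byte counts and onset event
  density in Hz.
* **Response preparation.** Linear detrending and z-scoring of run time
  series; trial averaging (shift 1 TR, crop 3 TRs) or 12-TR moving-average
  trial windows emitting 28 points per trial; leak-free train/test
  standardization; TSV round-trips.
* **Hyperalignment.** Iterative Procrustes alignment of subjects into a
  common representational space (dimensionality = the largest subject's
  voxel count; others zero-padded), then mean hyperaligned train/test data.
* **Models.** Per-voxel encoding slopes `β = (xᵀx)⁻¹xᵀy` and ROI-level ridge
  decoders `β = (YᵀY + λI)⁻¹Yᵀx`, with λ searched over 100 effective-degrees-
  of-freedom targets on `[0.1, min(n,q) − 0.1]` (Newton solver, bisection
  safeguard) and selected by exact closed-form leave-one-out error.
* **Inference.** Permutation tests (independent train/test shuffles, chance =
  mean null r, p = fraction of null r ≥ observed), bootstrap SEM, dual
  0.05/0.001 significance masks, three-measure Venn overlap fractions, and
  slope-based sensitivity summaries (mean |β|, % positive β, mean |β/r|).
* **Synthetic data.** Cluttered images, refractory-Poisson tone-burst audio,
  planted linear voxel responses with region-wise slope magnitudes and sign
  mixtures, subjects as rotated/scaled/translated copies of a common space,
  and tag-based stimulus selection via complete-linkage correlation
  clustering — so every stage is testable with known ground truth.

## Worked example

Measure complexity of synthetic images, plant voxel responses driven by the
gradient measure, and decode it back:

```r
library(complexcortex)

gen <- gen_images(3, clutter_range = c(0, 50), size = 128, seed = 42)
visual_complexity_table(gen$images, ids = paste0("img", 1:3), size = 128)
#>   stimulus_id gradient png_bytes self_similarity   (clutter)
#> 1        img1    6.725     27890           2.471        48
#> 2        img2    6.053     27053           2.471        36
#> 3        img3    1.599     22718           3.614         0
```

More shapes mean more edges and less compressible rasters, so the gradient
and PNG measures rise with clutter. Decoding the gradient measure from 24
planted voxels (30 training / 10 test stimuli, response noise SD 1):

```r
dm <- fit_decoding(std$train$Y, std$train$x)   # λ picked by LOO on a df grid
evaluate(dm, std$test$x, std$test$Y)$r
#> decoding r = 0.96 (chance -0.02, p = 0.000, SEM 0.05, lambda = 19.8, df = 10.4)
```

`r` is the Pearson correlation between true and predicted complexity on the
held-out split; `chance` is the mean r of 200 permutation refits, `p` the
fraction of null refits at or above the observed r, and `SEM` a 500-iteration
bootstrap over test trials.

## Analysis workflow

The `analysis/` directory holds the numbered study scripts, each a thin
driver over the package that prints what it found and writes tables under
`results/`:

1. `01_simulate.R` — synthetic images, clips, tag matrix (+ ground truth).
2. `02_features.R` — complexity tables and inter-measure correlations.
3. `03_hyperalign.R` — multi-subject alignment, unequal voxel counts,
   noise sweep.
4. `04_encode_decode.R` — the full pipeline: features → planted responses →
   subjects → hyperalignment → encoding/decoding → permutation tests.
5. `05_summaries.R` — Venn overlap of significant voxels and the
   sensitivity hierarchy.

`run_pipeline(validate_config(list(...)))` runs stage 4 programmatically and
is deterministic given its seed. The methods vignette
(`vignettes/complexity-encoding.Rmd`) documents every model, convention and
design choice.

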