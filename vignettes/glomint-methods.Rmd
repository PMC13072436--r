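---
title: "Mining in-situ lipid markers of glomerular cell types: methods and design"
author: "glomint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining in-situ lipid markers of glomerular cell types: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glomint)
```

# The problem

Kidney glomeruli filter blood through the coordinated action of podocytes,
mesangial cells, fenestrated endothelial cells and the glomerular basement
membrane. High spatial resolution MALDI imaging mass spectrometry (IMS)
maps hundreds of lipid species at a 5 µm pixel pitch, but its pixels are
molecular mixtures with no cell-type identity. Multiplexed
immunofluorescence (MxIF) of the *same* tissue section provides that
identity at ~1 µm through a panel of antibodies with known cellular
targets. `glomint` fuses the two modalities: it segments MxIF pixels into
cell-type-dominated subglomerular clusters, transfers those labels onto
the coregistered IMS grid, and then asks a supervised model which ions
recognize each segment — turning an untargeted lipid image into a ranked,
sign-annotated list of in-situ marker candidates per glomerular cell type.

# Pipeline model

The pipeline is a fixed sequence of stages, each exposed as an exported
function and orchestrated by `runPipeline()`:

1. **Registration.** The two physical frames (µm) are linked by an affine
   transform, either supplied or fit to ≥3 non-collinear landmark pairs by
   least squares (`estimateAffine()`; the residual RMS is reported).
   Affine is deliberate: both rasters come from one rigidly mounted
   section, so a deformable model would add parameters without evidence.
   Each MxIF pixel center is mapped into the IMS frame and assigned to the
   IMS pixel in whose half-open square footprint it lands
   (`associatePixels()`); half-open intervals (left/top inclusive) make
   membership deterministic and enumeration-order-free, and each MxIF
   pixel belongs to at most one footprint.
2. **Segmentation.** In-ROI MxIF pixels are z-scored per channel
   (population SD, in-ROI pixels only — "standardized" intensities remove
   channel gain differences) and clustered with k-means
   (`clusterPixels()`): Lloyd's algorithm, k-means++ initialization, best
   of `nInit` restarts by within-cluster sum of squares, empty clusters
   re-seeded at the farthest point. Labels are renumbered by descending
   cluster size (ties by centroid norm) so segment ids are reproducible —
   raw k-means numbering is arbitrary. Default channels are the six
   glomerular markers (tensin, podocalyxin, fibronectin, CD31,
   synaptopodin, nestin) with `k = 6`; both are configurable.
3. **Cell-type naming.** Each cluster's mean standardized profile is
   compared by cosine similarity against per-type expectation vectors (+1
   on channels whose panel entry marks the type, −1 on the other selected
   channels); assignment requires similarity ≥ 0.3. Two guards matter in
   practice: types with no positive channel among the selected ones are
   not candidates, and a type is only assigned when the cluster is
   actually elevated on that type's marker channels. Without them, any
   uniformly dim cluster (lumen, background rim) matches whichever
   expectation vector has the fewest positive entries — an artifact of
   cosine similarity between mostly-negative vectors. Naming is
   best-effort ("where possible"): several clusters may share a type, and
   unnamed clusters remain "substructure (unassigned)".
4. **Label transfer.** Each IMS pixel takes the modal cluster id of the
   labeled MxIF pixels in its footprint (ties → lowest id). Pixels with
   fewer than `min_count = 5` labeled members (of 25 possible at the 5:1
   pitch ratio) are excluded as `sparse_footprint`: their composition is
   too ambiguous to be a training label.
5. **Spectral summaries.** Unweighted per-segment mean spectra with
   standard errors, and signed difference spectra between segment groups
   (e.g. mesangial vs pooled podocyte segments), on the same intensity
   scale the classifier sees (raw picked intensities by default; per-pixel
   TIC normalization is a config flag, off by default because picked peak
   tables arrive already processed and the choice should be visible, not
   silent).
6. **Classification.** A gradient-boosted tree multiclass model
   (`xgboost`) predicts each labeled IMS pixel's segment from its ion
   intensities. Cross-validation is stratified 5-fold *grouped by
   glomerulus*: all pixels of one glomerulus share a fold, so spatial
   autocorrelation within a glomerulus cannot leak between train and
   test — the conservative choice when the split granularity is otherwise
   unspecified. Per segment we report one-vs-rest balanced accuracy
   ((recall + specificity)/2), F1, precision and recall as fold mean ± SD,
   plus the summed confusion matrix. Class imbalance is handled by the
   metric (balanced accuracy), not by resampling.
7. **Attribution.** The refit model is interpreted with Shapley values
   (`shapleyAttributions()`): exact subset enumeration for ≤ 12 features,
   seeded permutation sampling otherwise. Sampling draws (permutation,
   background row) pairs once and shares them across evaluated pixels;
   background rows are cycled rather than resampled, so local accuracy —
   attributions plus baseline equal the model output — holds exactly for
   the reported baseline, and for linear models the estimate equals the
   closed form whenever the draw count is a multiple of the background
   size. The global score per segment and ion is the mean absolute
   attribution over all evaluated pixels; the direction is the sign of the
   Pearson correlation between ion intensity and its attribution, with a
   dead zone `|r| < 0.1` to suppress sign noise (Spearman available).
   Rankings sort by descending score, ties by ascending m/z.
8. **Depth comparison.** For each segment, a binary deep-vs-superficial
   classifier (glomerulus-grouped CV — depth is a per-glomerulus property)
   is trained and attributed the same way, yielding per-segment signed
   depth-marker rankings.

## Attribution scale and evaluation sampling

Two design points were genuinely open and deserve their rationale:

* **Margin scale by default.** For a softmax model, class probabilities
  are coupled: perturbing an ion that marks segment A changes the
  renormalized probability of every other segment, so on the probability
  scale the dominant segment's marker acquires a large mean |φ| in *every*
  segment's score and can outrank a small segment's own marker. Per-class
  margins (log-odds) depend only on that class's trees and decompose
  cleanly, so `attributeSegments()` attributes margins for tree models by
  default and records the scale in the result metadata; the probability
  scale remains available (`scale = "probability"`).
* **Stratified evaluation set.** The global score averages |φ| over the
  same evaluated pixels for every class. Sampling those pixels uniformly
  makes the average reflect segment size; sampling them stratified by
  segment (equal pixels per segment, the default) makes the scores
  comparable across segments of very different areas. The background set
  stays a uniform sample (200 pixels by default) because it estimates the
  dataset-wide expectation the baseline is defined against.

# The synthetic study design

`simulateGlomeruli()` generates the paired dataset the package is
validated on; its defaults *are* the study conditions (see
`defaultSimConfig()`).

* **Geometry.** 20 glomeruli of radius 60 µm on a jittered grid at 1 µm
  MxIF pitch: a 4 µm basement-membrane ring, a 12 µm peripheral podocyte
  band, and an interior with 4 endothelial capillary annuli around open
  lumina and 3 mesangial lobules; remaining interior is unspecific
  substructure. Measurement ROIs extend 5 µm beyond each tuft, so a rim of
  background is clustered too — six classes in total.
* **Fluorescence.** Mean channel intensities per cell type follow the
  panel's known targets (e.g. podocytes bright in
  podocalyxin/synaptopodin/nestin). Noise is multiplicative lognormal with
  mean 1 and cv 0.2 over an additive floor of 2. The cv was fixed at a
  level where the six classes remain separable in the six marker channels:
  the pipeline's premise — inherited from the tissue it models — is that
  MxIF segments are cell-type-dominated, and a generator whose clusters
  are noise-split would not emulate that system. At cv 0.2 the clustering
  recovers all six classes across seeds with 10 k-means restarts.
* **Lipids.** 40 m/z features with lognormal baselines; each cell type's
  profile varies around them with a 2σ-truncated lognormal spread
  (σ = 0.25), and one planted marker per type is enriched 4-fold.
  m/z 703.575 is planted podocyte-positive and m/z 810.600
  endothelial-positive / podocyte-depleted, so the worked example mirrors
  a sphingomyelin / phosphatidylcholine pair familiar from glomerular
  lipid imaging. IMS pixels are rendered at 5 µm pitch through the true
  (misaligned) transform as partial-volume mixtures of the cell types in
  each footprint, then noised with scaled Poisson counts
  (variance/mean = 2, i.e. ~14% cv at a baseline of 100).
* **Misalignment and depth.** The frames differ by a 1° rotation and a
  (3.2, −2.1) µm offset; corner landmark pairs are exported so
  registration is exercised, not bypassed. Half the glomeruli are "deep"
  and three non-marker features are doubled there, emulating
  acylcarnitine-like depth covariates.

What the generator does **not** emulate: optics (PSF, spectral
bleed-through), staining artifacts, peak-picking errors, mass drift,
within-type biological gradients, and irregular glomerular shapes. Passing
tests therefore demonstrate that the algorithms recover planted structure
under controlled noise and misalignment — not that real tissue will be as
clean. On real data the segment/cell-type correspondence is weaker, and
classifier metrics and marker rankings must be read accordingly.

# Numerical choices

* Coordinates are 0-based (row, col), row-major, with x along columns;
  the physical center of pixel (r, c) is `origin + (c + 1/2, r + 1/2) ·
  pitch`. One formula for both modalities removes a classic off-by-half
  bug source.
* The CSV peak-table dialect is frozen (`row,col,roi_id`, then one column
  per m/z printed with 3 decimals) so round-trips are bit-exact testable;
  imzML support covers processed-mode picked peaks with a shared m/z axis,
  64-bit float, uncompressed. MxIF and ROI rasters travel as TIFF
  (float32 scaled to [0, 1] with a JSON sidecar carrying scale, pitch and
  origin), which bounds TIFF round-trip accuracy at float32 precision
  (~1e-7 relative); CSV/imzML/JSON round-trips are exact to 1e-9.
* k-means convergence: relative WSS change ≤ 1e-8 or 100 iterations;
  k-means++ restarts default to 10 — on ~10^5 standardized pixels the
  split-a-bright-cluster local optimum is common enough that 4 restarts
  occasionally kept it.
* Degenerate inputs fail loudly and early: duplicate grid coordinates,
  non-increasing m/z axes, collinear landmarks, all-constant channels,
  empty segment groups, a missing depth class. Empty IMS footprints are
  flagged, not fatal; zero-variance channels are dropped with a warning.
* Determinism: every stochastic step takes a seed; `runPipeline()`
  expands one global seed into per-stage seeds via
  `stageSeed(seed, stage)` so any stage can be re-run in isolation with
  the stream it saw in the full run. Identical config + seed gives
  byte-identical CSV outputs.

# Problem sizes used in validation

The packaged validation runs desk-scale versions of the design: the full
default dataset (20 glomeruli, ~265k in-ROI MxIF pixels, ~11k labeled IMS
pixels) for the headline classifier check, 8 glomeruli for marker- and
depth-recovery, 2–4 glomeruli for stage-level properties, and toys
(12-point k-means optimum, 20×20 association rasters, d ≤ 4 Shapley
enumerations) wherever an exhaustive oracle is the comparison. These sizes
were chosen so the whole suite exercises every stage at full fidelity
while staying a few minutes of CPU.

# Known limitations

* Cluster naming depends on the panel's `expected_segments` tags over the
  *selected* channels; a type marked only by unselected channels (here the
  basement membrane, whose collagen IV α5 channel is not among the six
  clustering channels) cannot be named and shows up as unassigned or
  under a neighbouring matrix-rich type's name.
* The classifier family is a fixed default (gradient-boosted trees behind
  `predictProba()`/`predictMargin()`); any probabilistic classifier can be
  plugged in, but no tuning or calibration is attempted.
* Exact Shapley enumeration is limited to 12 features; beyond that the
  seeded permutation estimator is used and per-feature values carry Monte
  Carlo error (local accuracy still holds exactly).
* Registration is affine-only, by design; sections with nonlinear
  distortion need external correction before import.
* Merging of same-type segments (e.g. pooling two podocyte clusters for a
  difference spectrum) is always explicit and user-specified — the package
  never merges clusters automatically.
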