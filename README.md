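# glomint

Integrated imaging mass spectrometry + multiplexed immunofluorescence
profiling of kidney glomerular cell types.

## What it does, and for whom

High spatial resolution MALDI imaging mass spectrometry (IMS) maps lipid
ion intensities on a ~5 µm pixel grid, but its pixels carry no cell-type
identity. Multiplexed immunofluorescence (MxIF) of the *same* tissue
section resolves glomerular cell types — podocytes, mesangial cells,
endothelium, the basement membrane — at ~1 µm through a 10-antibody,
3-cycle panel. `glomint` is for spatial-omics researchers who want to fuse
the two: it delivers, per subglomerular segment, a ranked and
sign-annotated list of candidate lipid markers discovered in situ.

The pipeline:

1. **Register** the two physical frames with a landmark least-squares
   affine fit, and associate each IMS pixel with the MxIF pixels inside
   its square footprint (half-open membership, deterministic).
2. **Segment** in-ROI MxIF pixels by k-means (Lloyd + k-means++, best of
   restarts) on z-scored marker channels — default the six glomerular
   channels (tensin, podocalyxin, fibronectin, CD31, synaptopodin,
   nestin), k = 6 — and name clusters by cosine similarity between their
   standardized profiles and panel-derived expectation vectors.
3. **Transfer labels** to IMS pixels by footprint majority vote
   (`min_count` guards against ambiguous boundary footprints), and compute
   per-segment average and difference mass spectra.
4. **Classify** segments from ion intensities with gradient-boosted trees
   under glomerulus-grouped stratified 5-fold CV, reporting one-vs-rest
   balanced accuracy, F1, precision and recall per segment.
5. **Attribute** the model with Shapley values (exact enumeration ≤ 12
   features, seeded permutation sampling otherwise; local accuracy holds
   exactly). The global score of ion *j* for segment *s* is the mean
   absolute attribution `score(s, j) = mean_i |φ_ij^(s)|` over a
   segment-stratified evaluation set; the direction is
   `sign(cor(x_j, φ_j^(s)))` with a ±0.1 dead zone. A bubble table/plot
   (size = score, red/blue = sign) summarizes all segments.
6. Optionally compare **deep vs superficial glomeruli** per segment with
   binary classifiers and the same attribution machinery.

A synthetic-data module (`simulateGlomeruli()`) generates paired datasets
with a known cell map, planted 4-fold lipid markers (including a
703.575-positive / 810.600-negative podocyte pattern), frame misalignment
and a depth covariate, so the whole pipeline is testable without any
download.

## Worked example

```r
library(glomint)

sim <- simulateGlomeruli(list(n_glomeruli = 8, noise_cv = 0.1), seed = 6)
tr  <- estimateAffine(sim$landmarks$mxif, sim$landmarks$ims)
assoc <- associatePixels(sim$mxif, sim$ims, tr)
seg <- segmentMxIF(sim$mxif, sim$roi, seed = 2)
seg
#> SegmentationResult: k = 6 over 106186 in-ROI pixels (WSS 1.06e+04)
#>   segment 1:   38589 px  endothelial
#>   segment 2:   30156 px  podocyte
#>   segment 3:   15710 px  substructure (unassigned)
#>   segment 4:   11664 px  mesangial
#>   segment 5:    5771 px  mesangial
#>   segment 6:    4296 px  endothelial

lab <- labelIMSPixels(assoc, seg, sim$ims, sim$roi)
cls <- trainSegmentClassifier(lab)
head(classMetrics(cls), 4)
#>   segment            metric  mean      sd
#> 1       1 balanced_accuracy 0.992 0.00180
#> 2       1                f1 0.990 0.00242
#> 3       1         precision 0.991 0.00544
#> 4       1            recall 0.989 0.00408
min(classMetrics(cls)$mean)
#> [1] 0.953

att <- attributeSegments(cls, lab, seed = 3)
att@mz[rankings(att)[["2"]][1:3]]
#> [1] 703.575 810.600 642.413
directions(att)["2", match(c(703.575, 810.600), att@mz)]
#> [1]  1 -1
```

Reading the output: the six MxIF clusters are size-ordered segments;
segment 2 is the podocyte band (clusters are named "where possible" — the
large dim lumen cluster here picks up a spurious endothelial tag from its
slightly elevated CD31 z-score, a documented limitation of
expectation-vector naming). Every segment is recognized from its IMS
spectrum with all fold-mean metrics ≥ 0.95. For the podocyte segment the
top-ranked ion is the planted sphingomyelin-like m/z 703.575 with a
positive correlation, and the phosphatidylcholine-like m/z 810.600 ranks
second with a negative correlation — the planted in-situ marker pattern,
recovered end to end. `plotBubble(exportBubbleTable(att))` draws the
summary figure; `runDepthComparison(lab)` adds the per-segment
deep-vs-superficial marker rankings.

The same analysis runs from a shell via the thin CLI:

```sh
Rscript inst/cli/glomint.R run --config pipeline.yaml --out out/ --seed 1
```

with a YAML config holding a `simulate:` block (or `inputs:` paths to
imzML/CSV, TIFF and ROI masks) plus per-stage parameter blocks; every run
writes stage CSV/TIFF/JSON artifacts and a provenance manifest with file
hashes, per-stage seeds and timings.

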