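# endovote

Automated detection of ring-like endosomes in grayscale fluorescence
microscopy images.

Endosomes — membrane-bound transport organelles — appear in widefield
fluorescence images as approximately circular structures with a bright
annular rim. Counting and localizing them is a routine but error-prone
manual task in subcellular-trafficking studies, and generic spot detectors
confuse them with filled vesicles, arc fragments and blob clusters.
`endovote` is for image-analysis practitioners who have a modest set of
hand-annotated example patches and want a reproducible, scriptable detector.

## Method

The detector is a two-stage supervised cascade built on a dense-SIFT
bag-of-words representation (16×16 px grids every 2 px, 128-dimensional
descriptors, K = 400 visual words from K-means).

**Localization.** M query patches *Q*₁…*Q*ₘ of standard endosomes are
compared locally against the test image *D*. A query feature **f** and test
feature **g** quantized to the same visual word *k* cast a vote at the
implied centroid

&nbsp;&nbsp;&nbsp;&nbsp;L(c_D) = L(**g**) − s·(L(**f**) − L(c_Qm)),

weighted by the word's *discriminative capability*
d(k) = α(k)/(δ(k)+ε) — the ratio of its within-class similarity over the
query patches to its between-class similarity against N background
patches. Votes accumulate into one map per scaling factor
s ∈ {0.5, 0.6, …, 1.5}; the final map takes the per-pixel maximum over
scales and records the maximizing scale s\*.

**Identification.** Pixels of the normalized map above γ = 0.2 become
candidate boxes of side s\*·45, pruned by non-maximum suppression. Each
surviving candidate is encoded by locality-constrained linear coding
(affine combination of its C = 5 nearest words, min ‖f − B_f c‖² s.t.
1ᵀc = 1), max-pooled into a K-vector, and classified by a linear SVM
(cost chosen by 5-fold CV over 2⁻⁸…2⁸) that rejects endosome-like
background patterns.

**Evaluation.** A detection is correct when its intersection-over-union
with a ground-truth box exceeds 0.5. The package computes precision,
recall, F₁, miss-rate-vs-FPPI curves and the log-average miss rate.

A seeded synthetic scene generator (Gaussian-annulus rings of radius
8–22 px plus disc/arc/cluster confounders and sensor noise) makes the whole
pipeline testable without microscope data. See the methods vignette
(`vignettes/ring-endosome-detection.Rmd`) for every modeling choice and
its rationale.

## Worked example

Simulate a small annotated dataset, train, detect and evaluate — from R:

```r
library(endovote)

dir <- tempfile()
spec <- scene_spec(size = c(224L, 224L), n_rings = 3L, n_background = 3L,
                   radius_range = c(9, 18), min_sep = 55, seed = 40L)
sim <- cmd_simulate(file.path(dir, "data"), n_images = 4, spec = spec)

cfg <- detector_config(K = 60L, M = 8L, N = 40L, seed = 1L)
cmd_train(sim$images, sim$ground_truth, file.path(dir, "model"), config = cfg)

det_csv <- file.path(dir, "detections.csv")
cmd_detect(sim$images, file.path(dir, "model"), det_csv)
res <- cmd_evaluate(det_csv, sim$ground_truth)
res$metrics
```

which prints (stage counts per image on stderr, then the pooled metrics):

```
extracting dense SIFT from 8 + 40 training patches
clustering 10800 descriptors into K = 60 visual words
training the LLC/SVM identifier (5-fold CV over 17 costs)
chosen SVM cost: 0.5
scene_001.tif: 100 thresholded -> 5 after NMS -> 3 endosomes
scene_002.tif: 119 thresholded -> 5 after NMS -> 3 endosomes
scene_003.tif: 290 thresholded -> 8 after NMS -> 3 endosomes
scene_004.tif: 185 thresholded -> 5 after NMS -> 3 endosomes
precision    recall        f1      lamr
    1e+00     1e+00     1e+00     1e-10
```

Here `precision`/`recall`/`f1` score the SVM-positive detections against
the ring ground truth: on this small noise-free-by-comparison example all
12 rings over the 4 scenes are found with no false alarms. The per-image
counts show the cascade at work — hundreds of above-threshold voting-map
pixels collapse to a handful of candidate boxes after non-maximum
suppression, of which the SVM keeps exactly the three rings per scene.
`lamr` is the log-average miss rate of the score-swept MR-FPPI curve
(lower is better; the 1e-10 floor means every ring is found before the
first false positive). The same commands are available from a shell via
`inst/cli/endovote <simulate|train|detect|evaluate>`.

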