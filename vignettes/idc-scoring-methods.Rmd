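---
title: "Scoring soybean iron deficiency chlorosis from canopy images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring soybean iron deficiency chlorosis from canopy images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idcscore)
```

## The problem

Iron deficiency chlorosis (IDC) strikes soybean on calcareous, high-pH
soils. Iron-starved leaves lose chlorophyll and yellow between the
veins; severe plants brown, die back and stunt. Severity is scored in
the field on a 1–5 visual scale — 1 normal green, 2 modest yellowing,
3 interveinal chlorosis without stunting, 4 chlorosis with stunting,
5 severe chlorosis plus necrosis. Visual rating is slow, and repeated
ratings of the same plot drift with the rater. The premise of this
package is that the rating is, to a very good approximation, a function
of two quantities visible in an RGB photograph: the fraction of canopy
area that has yellowed (Y%) and the fraction that has browned (B%).
Everything else — camera color cast, soil, debris — is nuisance, removed
by calibration and segmentation before those two numbers are measured.

## Pipeline and assumptions

**Calibration.** A color chart photographed alongside the plots anchors
color constancy. White balance is a von-Kries diagonal correction from
the neutral grey patch: each channel gain is `mean(grey) / grey_c`, so a
neutral grey reads equal channels afterwards. Hue drift is measured at
three chromatic patches (green, brown, yellow — the hues that matter for
this trait) as the circular difference between the observed patch hue
(after white balance) and its defined reference hue. Correction
subtracts from each pixel's hue a drift value interpolated
piecewise-linearly between the three anchors around the hue circle
(wraparound-aware). Piecewise-linear interpolation is the weakest
assumption that preserves hue ordering; whether a camera's cast is truly
global or hue-dependent is scene-specific, and with three anchors both
are handled. A profile estimated from a clipped (blown-out) grey patch
is refused outright — there is no recovering white balance from
saturated pixels. Reference patch hues (green 110°, brown 35°, yellow
65°) and the patch geometry are configurable; the defaults match the
bundled synthetic chart.

**Segmentation** assumes the standard imaging protocol: one plant,
centered, filling the frame, weeds removed. Soil background is far less
saturated than foliage and its hues fall outside the brown-to-green arc,
so foreground is `S >= sat_min` AND hue in `fg_hue_window`. The defaults
— `sat_min = 0.15`, window `[21°, 140°]` — are data-dependent
placeholders: the saturation floor should be tuned to local soil (it was
derived here from the synthetic soil model), and the window's lower edge
is the brown band's published lower bound while the green upper edge is
a convention of this package. Thresholding is deliberately generous;
what guarantees a clean canopy is the connected-components step, which
keeps only the largest blob (ties broken toward the image center, since
the protocol centers the plant). Debris and chart patches survive
thresholding but lose to the canopy on size. An image with no foreground
raises a distinct `no-canopy-found` condition so batch scoring can
record the failure and continue.

**Features.** Canopy pixels are labeled by hue band: brown 21–50°,
yellow 51–80° (closed bounds, integer degrees after rounding half-up, so
50 is brown and 51 is yellow), green 81–140° by default. The rare canopy
pixel whose hue survives segmentation but sits outside every band is
assigned to the nearest band by circular distance, ties to the more
severe class; this makes the three-way labeling total, so
green + yellow + brown percentages partition 100 exactly and `Area_total`
is unambiguous. The feature vector is the pair
`(Y%, B%) = 100 · (n_yellow, n_brown) / n_canopy`.

**Classification.** Eight flat algorithms map (Y%, B%) to a rating:
classification tree, random forest, naive Bayes, LDA, QDA, multi-class
RBF SVM on standardized features, k-nearest neighbors, and per-class
Gaussian mixtures combined through the Bayes rule with empirical priors
(GMMB). The hierarchical classifier encodes rater logic: Step A assigns
low ({1,2}) / medium ({3}) / high ({4,5}) susceptibility with SVM or
LDA; Step B resolves the binary splits 1 vs 2 and 4 vs 5 with SVMs;
medium maps directly to 3. Since no kernel or hyperparameter settings
are canonical for this trait, defaults are the field-standard ones (RBF
kernel, k = 5, 100 trees, 2 mixture components per class), all
configurable. Posterior, vote and distance ties resolve to the **lowest**
rating — a deliberate, conservative severity call. KNN prediction is
implemented in-package so that tie-breaking is deterministic (library
implementations break ties at random). Class imbalance is left
uncorrected by default, matching the realistic imbalanced training
population; optional class weights are exposed.

**Evaluation.** Accuracy alone overstates performance when most plants
are healthy, so the primary metric is mean per-class accuracy (MPCA),
the mean of the row-normalized confusion-matrix diagonal. A class absent
from a fold has undefined per-class accuracy; it is excluded from the
MPCA mean with a warning rather than silently imputed. The cost metric
weights each confusion count by `w_ij = |i − j|` and averages over
observations — zero exactly at 100% accuracy, and an error of four
rating steps costs four times an error of one. The train/test split is
75–25 by simple random sampling (train size rounded half-up; an optional
stratified mode preserves class proportions with largest-remainder
rounding). Cross-validation is 10-fold repeated 10 times; repeat *r*
re-shuffles under seed `seed + r` and partitions contiguously, making
every fold assignment reproducible. Both the cross-validated MPCA and
the cross-validated misclassification error are reported, since either
may be wanted as the generalization summary.

**Population canopy graph.** A trained model queried on a uniform grid
over the feasible simplex {Y ≥ 0, B ≥ 0, Y + B ≤ 100} (the two features
are area fractions of the same canopy; a full-square domain is available
for comparison) yields the PCG. The default step of 0.5% localizes
boundaries to sub-percent resolution at negligible cost. Instead of a
subjective low/medium/high interpretability grade, the package reports
an objective checklist: (a) the fraction of rating-1–3 area at low B,
(b) the lowest B level above which everything is rated 5 (vacuous only
for a constant map), and (c) contiguity of each rating's region — the
three properties a rater recognizes as "physically sensible" decision
boundaries — plus a free-text annotation field for the human judgment.

## The synthetic data model

The generator exists so that every stage has exact, planted ground
truth. It emulates:

- **Canopy geometry** — a union of eight overlapping ellipses, each
  containing the image center, so the truth mask is guaranteed to be one
  connected component (the protocol's key assumption made literal).
- **Soil** — mostly gray-brown low-saturation noise (below the
  saturation floor), with a minority of more saturated off-window hues,
  so both arms of the threshold do real work.
- **Discoloration** — exact pixel counts: `floor(p/100 · n_canopy + 0.5)`
  pixels get hues drawn from inside the brown or yellow band with a 4°
  guard against 8-bit quantization, the rest green. Recovery of the
  planted fractions is therefore exact up to one pixel (±100/n_canopy).
  Canopy saturation × value is kept ≥ 0.525 so a planted hue survives
  the render → calibrate → re-render chain with under 1° of drift.
- **Debris and chart** — small saturated blobs away from the canopy, and
  a four-patch chart (grey, green, brown, yellow) whose chromatic
  patches carry a controllable extra hue offset; a separate global
  `hue_shift` rotates all chromatic content, emulating the illumination
  cast that chart-based correction must undo.
- **Feature distributions** — per-rating bivariate normals truncated to
  the simplex. Defaults: rating 1 at (6, 2), 2 at (25, 2), 3 at (48, 4),
  4 at (48, 12), 5 at (48, 28) with spreads (2, 0.8), (3, 0.8), (4, 1.2),
  (10, 2), (10, 4); priors 0.40/0.15/0.15/0.15/0.15. Ratings 1–3 sit at
  low brown; ratings 3–5 share a comparable chlorosis level and are
  separated chiefly by necrosis, so a trained classifier's rating-5
  boundary runs nearly horizontally — the qualitative shape expert
  logic produces ("beyond a certain necrosis, it is a 5"). Means sit
  ≥ ~2.2 standard deviations inside the simplex so truncation bias is
  negligible relative to Monte-Carlo error. The dominant rating-1 prior
  reflects that most of a screening population stays healthy. All of
  these numbers are this package's invention — the published record
  describes the shapes only qualitatively — and all are overridable.
- **Experiment structure** — a plots × replications × time-points
  catalog in which each plot's severity is non-decreasing over time
  (symptoms progress; the per-step advance probability, 0.35, is a
  chosen convention). The catalog carries planted features and ratings;
  rasters are rendered on demand rather than materialized 5916 at a
  time.
- **Ground-truth rating rule** — `bayes_rating()` is piecewise-linear
  and monotone in both features: rating 5 whenever B > 15; otherwise 4,
  3, 2, 1 by decreasing thresholds on weighted sums of Y and B
  (Y + 2.5B > 60, Y + 2B > 35, Y + 1.5B > 15). No published boundary
  values exist; these are the package's own convention, chosen to
  satisfy the qualitative constraints (necrosis cap, low ratings only at
  low B, graceful linear transitions) and used as planted truth, not as
  a claim about any field dataset.

What the generator does **not** emulate: leaf venation and interveinal
patterning (the rating here uses area fractions only, so pattern is
irrelevant by construction), stunting (a 3-vs-4 cue visible to raters
but not to a color pipeline — a genuine, shared limitation), shadows,
multi-plant scenes, weeds, and photorealistic texture. Tests passing on
synthetic data therefore certify the pipeline's internal contracts —
exact feature recovery, calibration round trips, classifier behavior on
cluster-structured features — not performance on any real field imagery.

## Numerical choices

- Hue is stored in degrees [0, 360) everywhere, red at 0°, regardless of
  any backend's half-range convention; all configs take degrees.
- Images are 8-bit quantized arrays in [0, 1]; an "intensity level" in
  tolerance statements is 1/255.
- Band membership is decided on integer degrees after rounding half-up,
  eliminating boundary ambiguity at 50/51 and 80/81.
- Component labeling is a BFS in compiled code, deterministic in
  raster-scan order, with 4- and 8-connectivity (8 is the default for
  blob isolation; 4 exists for oracle cross-checks). Equal-size largest
  components tie-break to the centroid nearest the image center.
- The train-size rounding rule is floor(fraction · N + 0.5) (round
  half-up), documented because N · fraction is routinely half-integral.
- Feature percentages are ratios of exact integer pixel counts; the
  green percentage is the exact complement, so the three always sum
  to 100.
- Degenerate inputs have defined behavior: empty masks raise
  `no-canopy-found`; single-class training data are refused; a missing
  susceptibility group degrades that hierarchical branch to the group's
  most conservative rating with a warning; zero confusion-matrix rows
  yield NA per-class accuracy, excluded from MPCA with a warning.

## Problem sizes used in the checks

The bundled suites run at deliberately modest scale: 100 random 16×16
masks against a flood-fill oracle; 50 images at 512×512 for the
end-to-end feature round trip; n = 10 000 feature draws for the
distribution checks; n = 2000 with a 75–25 split for the hierarchical
classifier's held-out MPCA (≥ 95% on the default well-separated spec — a
property of the synthetic conditions, not a field-accuracy claim); and
10×10-fold cross-validation on a 150-row separable fixture. These sizes
were chosen as the smallest that exercise each contract convincingly.

## Known limitations

- The saturation floor and green band edge are protocol-dependent
  constants; transferring to a new camera/soil combination requires
  re-tuning them on background samples.
- The pipeline is color-only: it cannot use stunting, so ratings 3 and 4
  are distinguishable only insofar as their color signatures differ.
- JPEG input is refused rather than accepted-with-warning: lossy
  compression shifts exactly the hues this trait depends on, and no
  lossless-roundtrip JPEG path is bundled.
- The hierarchical Step-B SVMs inherit SVM extrapolation behavior far
  from training support; PCG regions in data-free corners of the simplex
  (e.g. very high Y with near-zero B) can be arbitrary, which is why the
  interpretability checklist and the boundary-flatness check are
  evaluated where data support exists.
- Calibration assumes the chart shares the scene's illumination; a
  profile is metadata-tagged but the library applies whichever profile
  it is given — staleness control (the re-capture cadence) is the
  operator's job.
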