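---
title: "Plantar-pressure gait recognition: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plantar-pressure gait recognition: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gaitpress` implements a complete pressure-mat gait-identification system:
raw frame streams from a floor-mat sensor array are condensed into
per-gait-cycle *average bilateral pressure maps*, a convolutional
classifier identifies enrolled walkers (closed set), and an autoencoder
embedding with cosine-similarity thresholding rejects walkers that were
never enrolled (open set). Because mats of this kind are bespoke hardware,
the package ships a synthetic walk simulator with the same statistical
structure, so every stage is testable end to end. This vignette records
the scientific choices behind each stage.

## The sensing model

The simulated mat is a chain of `n_units` identical units (default three
64 cm x 40 cm units at 1 cm sensor pitch), i.e. a 192 x 40 grid of 7680
piezoresistive cells sampled at 40 Hz, each frame an 8-bit matrix
(values 0-255, saturation by clipping, never wrap-around). Rows run along
the walking direction, columns across the mat; grids are row-major in the
walking sense (row 1 is the mat start).

## The synthetic cohort

`generate_cohort()` draws, per subject:

* **shoe size** from the four discrete sizes worn by the study cohort
  (US 3/4/7/10; default histogram 2/15/19/24 for 60 subjects). Size fixes
  the footprint extent in cells (22x8 up to 28x11, always inside the
  32 x 16 segmentation mask);
* **body weight** ~ N(66, 12) kg truncated to [42, 100]; the per-frame
  peak pressure is `40 + 1.6 * weight_kg` (8-bit units), so pressure
  magnitude is strictly monotone in weight;
* **step angle** ~ N(6, 3) degrees outward, truncated at the largest
  rotation that keeps the rotated footprint inside the 32 x 16 mask
  (size-dependent, at most 14 degrees);
* **step length** ~ N(45, 3) cells, **cadence** ~ N(44, 3) frames per
  gait cycle (about 1.1 s per stride at 40 Hz), and a mild left/right
  magnitude **asymmetry** ~ N(1, 0.03);
* a **footprint template** per foot: two rasterized Gaussian lobes (heel
  and forefoot) whose centers, widths and amplitude ratio are per-subject
  random. Bimodal heel/forefoot pressure is the minimal realistic
  structure of a plantar pressure image; the per-subject lobe geometry is
  what makes subjects separable.

`identical_templates = TRUE` clones one parameter set across the cohort —
a negative control in which the only per-subject signal is sensor noise,
used to verify that the pipeline cannot learn identities that are not
there.

`simulate_walk()` renders alternating left/right contacts along the mat
(left foot in the left half-width lane), each active for 60% of the gait
cycle; stance frames crossfade linearly from the heel lobe to the
forefoot lobe, which reproduces heel-strike-to-toe-off progression and
makes the stance-averaged image equal the mid-stance template. Consecutive
contacts overlap in time (double support). Walking with a carried load
(`walk_condition(500)`) shifts the center of pressure forward by a whole
number of cells (default 2) and scales magnitude (default 1.06); the
integer shift makes the load effect exactly verifiable. Sensor noise is
additive integer-rounded Gaussian on active cells (default sd 2), and
isolated full-scale (255) single-cell spikes are injected at a small rate
to exercise anomaly replacement. The first frame is always silent — the
subject starts a meter before the mat.

What the generator does *not* emulate: ground-reaction-force dynamics,
sole-tread patterns (the study standardized shoes precisely to remove
them), fatigue or speed drift across trials, cross-talk between sensors,
and long-tailed sensor noise. Passing tests on this cohort therefore
demonstrate that the pipeline's machinery is correct and that it can
separate subjects whose footprint geometry differs — not that real human
cohorts are separable at any particular accuracy.

## Preprocessing

1. **Anomaly replacement** (`replace_anomalies`): a cell is anomalous
   when its value exceeds the mean of its 8-neighborhood by more than
   `z_threshold` (default 4) neighborhood standard deviations (population
   convention, with a 1-unit floor on the sd so flat neighborhoods still
   flag full-scale spikes). Flagged cells are replaced by the mean of
   their unflagged neighbors. The detector is one-sided (high outliers):
   sensor spikes are positive, and a two-sided rule would erode footprint
   boundaries.
2. **Aggregation** (`accumulate_pressure`): cellwise sum of all frames of
   a traversal, in double precision.
3. **ROI extraction** (`extract_rois`): the summed map is thresholded at
   2% of its maximum (suppressing faint single-frame residues that
   anomaly replacement can leave at footprint borders) and segmented by
   connected-component labeling; each component is covered by a 32 x 16
   window centered symmetrically on its center of mass (symmetric
   centering makes mirroring the mat mirror the windows exactly). A
   mask-correlation variant (repeatedly taking the 32 x 16 window with
   the largest summed pressure) is available behind the same interface
   via `method = "mask"`; the component method is the default because its
   failure mode (an oversized component) is detected and reported rather
   than silently splitting a footprint. Side is assigned from the
   window's lateral position relative to the mat midline. The onset frame
   is the first frame with nonzero pressure among the component's cells.
4. **Gait cycles** (`detect_gait_cycles`): a cycle spans one contact's
   onset to the onset two contacts later (a full stride); the final
   cycle, lacking a closing onset, is capped at the last frame with
   nonzero pressure. N contacts give N-1 cycles.
5. **Average maps** (`compute_average_map`): each participating foot's
   windowed pressure is summed over the cycle and divided by the cycle
   duration; the left foot fills columns 1-16 and the right foot columns
   17-32 of the 32 x 32 image. Maps are non-negative reals; no
   renormalization is applied beyond the global [0, 1] input scaling at
   training time (per-map renormalization would discard the weight
   signal).
6. **Augmentation** (`augment_flip`): horizontally mirrored copies are
   appended to *training* partitions only, to avoid leakage into test
   statistics.

A "unit step" is one foot contact; the scheduler
(`schedule_cohort_trials`) sizes each round's traversals so that the
average maps per round — one fewer than the contacts of each traversal —
total exactly `unit_steps_per_round` (default 40). Dataset partitions
follow the study protocol (`build_datasets`): unloaded rounds 1-2 train;
the held-out unloaded round and the loaded round test; for the open-set
task only known subjects' training rounds are enrolled and everything
else is test data.

## Models

The classifier (`gait_cnn`) is the smallest standard architecture
consistent with three convolution/pooling blocks and a 256-unit
penultimate layer: 3 x 3 kernels, filter progression 32-64-128, 2 x 2 max
pooling, rectified-linear activations, softmax cross-entropy, Adam with
learning rate 0.001, 50 epochs, batch 16, validation split 0.1 taken
subject-stratified with the run seed. Early stopping is not used; at desk
scale the loss converges well before the fixed epoch budget. Inputs are
scaled by the global training-set maximum into [0, 1]. The training loop
is implemented in compiled code (Rcpp/Armadillo, im2col + GEMM) and is
bit-reproducible given the seed. The 256-unit post-ReLU activations are
the identity embeddings.

The autoencoder (`gait_ae`) is a single hidden mirror 256 -> 64 -> 256
with linear code and output, trained with Adam on mean squared
reconstruction error. With only the dimensions prescribed, the linear
map is the most parsimonious choice; it preserves the geometry that the
cosine similarity relies on, trains stably at small sample sizes, and its
reconstruction loss is provably non-increasing at convergence.

## Open-set decision rule

Enrolled 64-dimensional codes are standardized per dimension
((x - mean) / sd, population sd over all enrolled vectors, variance floor
1e-8 so zero-variance dimensions map to zero). Queries are standardized
with the *enrollment-time* parameters — refitting on queries would leak
test statistics into the gallery. Each query is scored against every
subject's gallery summary, by default the subject's mean standardized
vector (a per-vector maximum is available via `feature_db(gallery =
"max")`); the best cosine similarity is compared with the acceptance
threshold (default 0.85): below it the walker is declared unknown. Ties
break toward the lowest subject id and are flagged. Decisions are per
unit step; no multi-step voting is applied, so reported accuracies are at
unit-step granularity.

## Evaluation conventions

With acceptance defined as score >= threshold: FAR(t) is the fraction of
impostor scores at or above t, FRR(t) the fraction of genuine scores
below t. Both are step functions; the equal error rate is the common
value of the two curves linearly interpolated between the adjacent grid
thresholds where FAR - FRR changes sign (the default grid is the sorted
unique scores plus an upper sentinel, so the crossing is always
bracketed). The interpolated EER value depends only on the bracketing
curve values, not the grid spacing, which the tests exploit by comparing
against a dense brute-force grid. ROC AUC is the trapezoidal integral of
the empirical ROC and equals the pairwise (Mann-Whitney) estimator with
ties counted one half. Undefined ratios (zero denominators) are returned
as `NA` with a warning, never silently zero. Multiclass closed-set
precision/recall/F1 are macro averages over one-vs-rest counts. Open-set
"known accuracy" is reported both ways: acceptance only, and acceptance
with correct identity (`acc_known_accept` vs `acc_known`); the stricter
variant is the headline number.

Misclassification attribution aggregates closed-set errors by
(actual, predicted) pair and marks shared attributes: equal shoe size,
and weights within 5 kg (a tolerance consistent with treating 63 vs 66 kg
as similar but 60 vs 73 kg as different).

## Problem sizes used by tests and the acceptance script

Full-protocol partition arithmetic (60 subjects x 4 rounds x 40 unit
steps) is checked on the scheduler's plan without rasterizing frames.
The learning experiments run a 12-subject cohort (shoe-size mix 1/3/4/4),
3 + 1 rounds of 16 unit steps, 12 training epochs — sizes chosen so the
distinct-template cohort is comfortably separable while a cloned-template
control collapses to chance, which is the property being asserted; the
default configuration retains the full-scale values.

## Known limitations

* The simulator's subjects differ in template geometry by construction;
  nothing is claimed about the separability of real human cohorts.
* Side assignment relies on lane-separated walking; a walk straddling
  the midline would need the mask-correlation ROI variant and external
  side cues.
* Footprints larger than the 32 x 16 mask (or rotated beyond its
  diagonal) are rejected rather than resized.
* The open-set database is static: enrollment does not retrain the CNN
  or the autoencoder, and template aging or spoofing are out of scope.
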