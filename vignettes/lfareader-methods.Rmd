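---
title: "Reading lateral flow test cards from photographs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reading lateral flow test cards from photographs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A lateral flow assay (LFA) strip reports the presence of an analyte through
colored transverse lines: a **control line (C)** that confirms the sample
migrated correctly, and a **test line (T)** whose *absence* indicates an
above-cutoff (positive) drug result. Saliva drug panels carry several such
strips side by side in one plastic card, sometimes together with an alcohol
strip whose reactive pad turns blue in proportion to the alcohol
concentration. Visual interpretation of faint lines is notoriously
inconsistent between human operators; `lfareader` automates it from a single
photograph of the card.

The pipeline has four stages, each exposed as package functions so every
stage can be validated in isolation:

1. **Registration** — locate the strip region in the photograph by matching
   ORB binary features against a stored template and estimating a RANSAC
   homography; the image is warped into the template frame so all
   downstream geometry is pose-invariant.
2. **Segmentation** — find the colored strip-label regions by per-channel
   Otsu thresholding, morphological closing, a column-occupancy filter and
   contour position/area filters; each label anchors a histogram-extraction
   window below it.
3. **Histogram preprocessing** — reduce each window to a 1-D lateral
   intensity profile, resample it to a fixed bin count, remove the linear
   illumination baseline robustly, and align the two line dips into a
   fixed 62-bin layout (control signal in bins 1–31, test signal in bins
   32–62). Alcohol strips instead resample to 62 bins and subtract the
   mean of the leading 15 bins.
4. **Classification** — three small multilayer perceptrons with
   hyperbolic-tangent (tansig) neurons decide, per strip, whether the
   control line is valid, which of five darkness classes the test line
   falls in, and whether the alcohol pad is positive; every classifier can
   refuse to answer (reject option, "undetermined").

## Registration

The template is processed once, off-line: oriented FAST-9 corners
(segment test of 9 contiguous pixels on the radius-3 Bresenham circle,
contrast threshold 20/255), an intensity-centroid orientation per corner,
and steered 256-bit BRIEF descriptors sampled from a box-smoothed patch.
Detection runs over an 8-level image pyramid with scale factor 1.2, keeping
the 500 strongest corners. Two details are deliberate simplifications of
the classical ORB recipe and are worth knowing about:

* keypoints are ranked by their FAST corner score (the sum of thresholded
  absolute circle-pixel differences) rather than a separate Harris
  response;
* the BRIEF test pattern is a fixed, seeded isotropic Gaussian pattern
  (sd = patch/5, clipped to radius 13 so any rotation stays inside the
  31×31 patch), steered by the continuous keypoint orientation. The
  "learned, decorrelated" pattern of the original recipe requires a
  training corpus that is not part of this package.

Matching is brute-force minimum Hamming distance with a mutual-consistency
filter: a pair survives only if the two descriptors are each other's
nearest neighbor, with distance ties broken toward the lowest index so
matching is deterministic. The homography is estimated by RANSAC over
4-point minimal samples (normalized DLT), reprojection-error threshold
3 px, at most 2000 adaptive iterations, seeded, followed by a least-squares
refit on the inlier set. Registration is declared failed below 10 inliers —
the reader reports "could not locate test" rather than guessing.

The rectified region of interest (ROI) is produced by warping the captured
image into the template frame and cropping the template's strip
quadrilateral. The alternative — analyzing in the captured frame — would
make "the lower half of the ROI" (used by the segmentation position
filter) ill-defined under rotation, which is why the warp-then-crop order
was chosen.

## Segmentation

Each RGB channel of the ROI is binarized at its own Otsu threshold
(between-class variance maximization over 256 levels, ties to the lowest
threshold, foreground = the darker class, since labels and lines are
darker than the white card). With an alcohol strip present the two
conjunctions (G∧B) and (G∧R) are merged by union — the union is
recall-preserving, and the intersection variant remains available through
the configuration; without one, the union of the R and B masks is taken.
A 3×3 closing fills small gaps, then any column whose foreground fraction
is below 10% is zeroed.

Connected components are filtered in two stages: centroids in the lower
half of the ROI are dropped (this removes the alcohol pad, line fragments
and reflections), then components smaller than half the **largest
surviving** area are dropped. Computing the reference area after the
position filter means a huge lower-half artifact cannot suppress the true
labels. Survivors must match the configured panel size exactly — any other
count is a segmentation mismatch, reported as an invalid capture — and are
assigned strip identities left to right (the physical card's strip order is
known from the panel configuration, as the batch number identifies it in
the field).

The histogram window hangs below each label: width 0.6 × label width
(narrower than the strip so edge shadows stay outside), vertical gap
0.2 × label height, length 2.5 × label height, clipped to the ROI. The
multipliers are package defaults, exposed in `panel_config()`.

## Histogram preprocessing

The lateral histogram is the mean intensity of each pixel row of the
window (luminance by default), the index running along the strip's flow
axis. Line dips then appear as local minima. The chain for line strips is:

* **Resampling to 100 bins** by piecewise 3-point Lagrange (quadratic)
  interpolation over normalized position; exact on globally quadratic
  inputs and endpoint-preserving. "Quadratic interpolation" admits several
  schemes; the local Lagrange triple was chosen for locality and
  exactness on its own model class.
* **Baseline removal**: a linear model `y = a·i + b` is fitted by RANSAC
  (2-point samples, 500 seeded iterations, inlier threshold 5% of the
  profile's dynamic range, least-squares refit on inliers) and
  subtracted. The narrow dips are outliers to the fit, so the baseline
  tracks the illuminated background. The synthetic generator applies a
  *linear* illumination ramp precisely because this stage assumes one;
  nonlinear contamination can be added for robustness experiments.
* **Peak alignment**: the profile is split into halves 1–50 and 50–100
  (bin 50 shared, as the halves are defined); the minimum of each half
  locates the control and test line, ties breaking toward the lowest
  index. Fifteen bins on each side of each minimum (31 + 31 = 62 values,
  control half first) form the final histogram; windows near a segment
  border are shifted inward so exactly 31 bins are always taken.

Alcohol strips resample directly to 62 bins and subtract the mean of the
first 15 bins (the pre-pad region, which tracks illumination but carries
no signal). No baseline correction is applied on this path by default —
the alcohol preprocessing is defined as resampling plus leading-bin
normalization — but a configuration switch can enable it.

## Classification

All three classifiers share one processing chain, with all statistics
taken from the training split only:

1. per-bin z-score normalization;
2. per-bin affine mapping of the training range onto [−1, 1] (no
   clipping of out-of-range inputs);
3. a tansig MLP — every neuron, hidden and output, applies tanh to its
   weighted sum plus bias;
4. reverse mapping of outputs onto the raw training-target scale
   (one-per-class 0/1 targets, so reverse-mapped outputs live on [0, 1]);
5. argmax with a per-class confidence threshold: the candidate label is
   emitted only if its reverse-mapped score reaches the threshold,
   otherwise "undetermined". Argmax ties break toward the lowest class
   index.

The fixed structures are 62–5–2 (alcohol: positive/negative), 31–1–2
(control: valid/invalid) and 31–7–7–5 (test line: very positive, positive,
doubtful, negative, very negative), operating on bins 1–62, 1–31 and 32–62
of the preprocessed histogram respectively. An optional grid search over
hidden sizes exists but is off by default; the fixed structures are the
ones the method was designed around.

**Training.** Stratified seeded 70/15/15 split; one-hot targets mapped to
±1; full-batch iRprop⁻ on squared error with early stopping on validation
success. Three trainer details matter:

* a small L2 weight decay (10⁻⁴) keeps the network off bins that carry no
  class signal — the z-score normalization amplifies signal-free bins to
  unit scale, and without the penalty the net can lock onto their noise;
* among checkpoints of equal validation success the one with the larger
  validation margin (lower validation MSE) is kept. Keeping the *first*
  such checkpoint — a natural implementation — retains an under-trained
  network whose correct answers sit below the confidence threshold;
* training restarts from three independent initializations and keeps the
  restart with the best validation score, removing sensitivity to an
  unlucky starting point.

The binary classifiers train for up to 3000 epochs (patience 30); the
test-line classifier for up to 4000 (patience 40), since sharp decision
boundaries between its deliberately overlapping classes need the extra
convergence.

**Confidence thresholds.** All classifiers default to 0.5 on the
reverse-mapped [0, 1] scale: the candidate output must be at least
halfway to its +1 target, so a rejection marks genuine ambiguity rather
than imperfect output saturation. A stricter cut such as 0.9 turns out to
reject a non-negligible fraction of *correct*, shallow-signal answers
(faint but clearly present lines), which contradicts the intended
behavior of the reject option — a rare refusal, not a common answer — and
does not match how the reference evaluations behave (no rejected samples
in any split). Thresholds are per-class configurable — they are exactly
the knob for trading false positives against false negatives.

**Outcome rules.** Following the standard interpretation of line-based
tests: an
invalid control makes the strip invalid regardless of the test line; an
undetermined control dominates a determined test line; otherwise the five
test-line classes collapse to three outcomes — very positive/positive →
positive, negative/very negative → negative (any shade of test-line color
counts as a line), and doubtful follows a configurable policy defaulting
to "undetermined". The alcohol strip reports its classifier label
directly: the pad's five-level color chart is deliberately not quantified,
binary-plus-undetermined being the use case for saliva alcohol screens.

## The synthetic generators

No public dataset of photographed cards exists for this assay, so the
package ships seeded generators in place of one; they define the
conditions under which the package validates itself.

`generate_template_image()` + `generate_card_image()` render a 640×480
frame: a white card (intensity 0.92) on a dark light-box background,
seeded high-contrast fiducial squares in the card margins (so ORB has
structure to lock onto; template and cards of one panel share the same
fiducial layout — matching would be meaningless otherwise), colored strip
labels (every palette entry keeps all channels ≤ 0.55 so each Otsu channel
mask catches it), 3-px control/test lines whose color interpolates between
card white and a dark line color by the line's darkness, an optional
alcohol pad interpolating toward blue, a linear illumination ramp along
the strip axis, a pose (rotation about the card center plus translation,
applied as a homography; frame margins accommodate ±10° plus ±15 px), and
clipped additive Gaussian pixel noise (sd 0.01 by default). Ground truth
records every rendered quantity, including the applied homography.

The five test-line classes map to five equal darkness sub-intervals of
[0, 1], lightest (absent line) to darkest, widened by ±0.02 at shared
boundaries so adjacent classes deliberately overlap — the test-line
dataset is *supposed* to be confusable at class boundaries, which is the
documented reason the classifier keeps five internal classes plus a
reject. Card renders sample from the central half of the class interval
("unambiguous" conditions); dataset generation samples the full widened
interval.

`generate_histogram_dataset()` does **not** draw preprocessed bins
directly: it synthesizes raw profiles (background level U(0.84, 0.94),
slope U(−3·10⁻⁴, 3·10⁻⁴) per px, 3-px line dips with ±4 px position
jitter, or an alcohol pad step) and pushes them through the package's own
preprocessing chain. Training data therefore have exactly the structure
the image pipeline produces at inference time — the alternative
(hand-drawn "preprocessed-looking" templates) risks a silent train/deploy
distribution gap.

Profile noise deserves its own note. The per-profile noise sd follows
from the card physics — per-pixel noise (sd 0.01) averaged across a
window of roughly 28 columns gives about 0.002, and warping plus
resampling attenuate it further — but its exact value depends on window
width, pose and resampling, so the generator draws the noise scale per
profile from U(0.0008, 0.004), the way capture noise varies across
devices and exposures. Heterogeneous noise has a second, deliberate
effect: no classifier can treat the background noise *level* as a class
feature, which makes the trained networks robust to the exact noise
scale of the deployment images. Training on a single fixed noise scale
measurably was not: a model trained that way misread card-derived
histograms whose flat bins were quieter than its training data.

Class-conditional parameters: alcohol positives draw pad levels
U(0.3, 0.95) and negatives U(0, 0.02) — the 0.3 floor reflects that the
pad is *visibly* light blue at the minimum detection level, and keeps the
two classes linearly separable at the ≥ 99% level the alcohol dataset is
specified to have (a first draft with a 0.15 floor measurably violated
that contract). Control "valid" draws line darkness U(0.3, 0.95),
"invalid" renders no line. Default class mixes mirror the reference
datasets: alcohol 74/264 positive/negative of 338; control 1982/376
valid/invalid of 2358; test-line 459/122/200/258/330 across the five
classes.

**What the generators do not emulate**: lens distortion and perspective
foreshortening beyond the in-plane pose, motion blur, specular
reflections, saliva stains and reagent remains on strips, non-linear
illumination fields, sensor vignetting, and the color chemistry of real
membranes. Tests passing on synthetic cards demonstrate that the
*algorithmic chain* is correct and self-consistent under its stated
assumptions; they do not certify field accuracy on photographs of
physical tests, which would require a captured, labeled image set.

## Numerical choices and degenerate inputs

* Otsu on a constant sample has no split; the mask is defined empty.
* All RNG consumption is wrapped: every generator, RANSAC and trainer
  takes a `seed` and restores the caller's RNG state, so identical calls
  are bitwise reproducible and package calls never perturb user code.
* Minimum-of-half and argmax ties break toward the lowest index;
  descriptor-distance ties toward the lowest descriptor index.
* Zero-variance training bins are guarded with an epsilon (10⁻⁹) and a
  degenerate mapping range is a training error, not a silent NaN.
* The ±15-bin alignment windows shift inward at segment borders rather
  than shrinking, so the 62-bin layout is unconditional.
* Profiles shorter than 3 samples cannot be quadratically resampled and
  are rejected.

## Problem sizes used in the validation suite

The package's own test suite validates registration robustness on 100
rendered cards (rotations to ±10°), segmentation on 200 rendered cards,
the depth-vs-intensity monotonicity on a 200-card sweep, classifier
reproduction on datasets of 338 (alcohol), 2358 (control) and 1955
(test line) samples, and the full pipeline on 200 cards with unambiguous
classes. These sizes mirror the reference datasets where sizes are
reported and are otherwise chosen large enough for the rates being
asserted (e.g. ≥ 95% agreement on 800 strips).

## Known limitations

* Single card per image; multi-card frames are out of scope.
* Strips are assumed vertical in the rectified ROI; multi-row panels are
  not handled.
* The reader is qualitative: line depth is not converted to analyte
  concentration, and the alcohol pad's five-level chart is collapsed to
  positive/negative/undetermined.
* Timing rules of the physical assay (read windows in minutes) are not
  modeled; the reader interprets one image.
* The classifiers are only as good as their training distribution;
  models trained on the synthetic datasets should be retrained before
  use on any real capture hardware.
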