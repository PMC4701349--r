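# lfareader

Automated reading of lateral flow immunoassay (LFA) test cards from
photographs, in R.

Rapid saliva drug screens report results as colored transverse lines on
membrane strips: a **control line (C)** confirms valid sample migration,
and the **absence** of a **test line (T)** signals an above-cutoff
(positive) result; an optional alcohol strip carries a reactive pad that
turns blue with alcohol. Reading faint lines by eye is subjective —
trained operators disagree on a substantial fraction of near-cutoff
strips. `lfareader` replaces the eyeball with a deterministic pipeline:

1. **Registration** — ORB binary features (oriented FAST-9 corners +
   steered 256-bit BRIEF descriptors) matched by Hamming distance with a
   mutual-consistency filter against a stored template; a RANSAC
   homography rectifies the photographed card into the template frame and
   crops the strip region.
2. **Segmentation** — per-channel Otsu thresholding (with alcohol-specific
   channel logic), morphological closing, a 10% column-occupancy filter,
   and contour position/area filters isolate each strip's colored label,
   which anchors a histogram window below it.
3. **Lateral histograms** — each window is reduced to a row-mean intensity
   profile `x(i) = (1/n) Σ_j s(i, j)`, resampled to 100 bins by quadratic
   interpolation, baseline-corrected by a robust linear fit
   `x(i) − (a·i + b)`, and aligned into 62 bins: ±15 bins around the
   minimum of each profile half, control signal in bins 1–31, test signal
   in bins 32–62. Alcohol strips resample to 62 bins and subtract the mean
   of the first 15 bins.
4. **Classification** — three tansig multilayer perceptrons
   (62–5–2 alcohol, 31–1–2 control, 31–7–7–5 test line) with z-score
   normalization, [−1, 1] input mapping, reverse-mapped [0, 1] outputs and
   a per-class confidence threshold; below threshold the classifier
   answers "undetermined" rather than guessing. Strip outcomes follow the
   standard rules: no control line → invalid; any test-line shade →
   negative; no test line → positive.

Because the photographed dataset behind this class of reader is not
public, the package ships **seeded synthetic generators** for template
images, test-card renders (labels, lines, alcohol pad, illumination
gradient, noise, pose) with full ground truth, and labeled histogram
datasets produced by pushing class-conditional raw profiles through the
package's own preprocessing chain. All validation runs against these
generators; see the methods vignette (`vignettes/lfareader-methods.Rmd`)
for what they do and do not emulate.

## Worked example

```r
library(lfareader)

panel    <- panel_config(c("AMP", "KET", "COC", "MET"))
tmpl     <- generate_template_image(panel, seed = 7)
template <- build_template(tmpl$image, tmpl$strip_quad)
template
#> <template_model> 267 keypoints, 640x480 px, strip quad [(190,80) (450,80) (450,400) (190,400)]

models <- list(
  control  = train_classifier(generate_histogram_dataset("control", 2358, seed = 42),
                              "control",  seed = 1)$model,
  testline = train_classifier(generate_histogram_dataset("testline", 1955, seed = 42),
                              "testline", seed = 1)$model)

# a posed, noisy card: dark test line / absent test line / dark line /
# missing control line on the four strips
spec <- card_spec(panel,
                  control_line_intensity = c(0.8, 0.8, 0.8, 0),
                  test_line_class = c("very_negative", "very_positive",
                                      "negative", "negative"),
                  pose = list(tx = 10, ty = -5, rot_deg = 4),
                  seed = 11)
card   <- generate_card_image(spec, tmpl)
result <- read_test(card$image, template, panel, models)
result
#> <test_result> in-memory: ok
#>   AMP  -> negative
#>   KET  -> positive
#>   COC  -> negative
#>   MET  -> invalid
```

Reading the output: AMP and COC show both lines (negative), KET shows a
control line but no test line (positive, i.e. analyte above cutoff), and
MET formed no control line, so its result is invalid regardless of the
test region. The result object carries provenance — registration quality
(here 106/150 inlier matches), each strip's 62-bin histogram and the
classifier confidence scores (AMP: control 0.997, test line 1.000 on the
[0, 1] reverse-mapped scale).

Training a classifier prints per-split evaluation reports; for the
alcohol model (62–5–2) on its 338-sample synthetic dataset:

```r
fit <- train_classifier(generate_histogram_dataset("alcohol", 338, seed = 42),
                        "alcohol", seed = 1)
fit$reports$test
#> <evaluation_report> test (50 samples): success 100.000%
#>           predicted
#> true       positive negative undetermined
#>   positive       11        0            0
#>   negative        0       39            0
```

The confusion matrix has an extra `undetermined` column: inputs are never
labeled undetermined, but the classifier may answer it, and such answers
count against the success rate.

## Command line

A thin wrapper over the same functions lives at `inst/cli/lfa.R`
(`system.file("cli/lfa.R", package = "lfareader")`):

```sh
Rscript lfa.R simulate card   --panel AMP,KET,COC,MET --seed 7 --out sim/
Rscript lfa.R simulate histos --kind testline --n 2000 --seed 7 --out tl.csv
Rscript lfa.R train --kind testline --data tl.csv --seed 7 --out models/testline.json
Rscript lfa.R read  --image sim/card.png --template sim/template.json \
    --panel AMP,KET,COC,MET --models models/ --out result.json
Rscript lfa.R batch --dir images/ --template sim/template.json \
    --panel AMP,KET,COC,MET --models models/ --out summary.json
```

Exit codes: 0 ok, 2 registration failure, 3 segmentation mismatch.

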