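# Labeled histogram datasets for classifier training. Each sample is
# synthesized as a RAW lateral profile — background level, linear
# illumination ramp, additive noise, and class-conditional line dips or an
# alcohol pad step — and then pushed through the package's own
# preprocessing chain to the stage the classifiers consume. Training data
# therefore have exactly the structure the image pipeline produces.

# luminance of the rendered line / pad colors (card-frame physics shared
# with the card generator)
.line_lum <- function() {
  g <- card_geometry()
  sum(c(0.299, 0.587, 0.114) * g$line_base)
}
.pad_lum <- function() {
  g <- card_geometry()
  sum(c(0.299, 0.587, 0.114) * g$pad_blue)
}

# One raw 125-px profile with optional control/test box dips (3 px) at
# jittered positions, or an alcohol pad step over the trailing region.
# The default profile noise follows the card physics: per-pixel noise
# (sd 0.01) averaged across a ~28-column histogram window gives
# 0.01/sqrt(28) ~= 0.002 per profile value.
raw_profile <- function(control_dark = 0, test_dark = 0, alcohol_level = 0,
                        base = 0.9, slope = 0, noise_sd = 0.002,
                        jitter = c(0, 0), len = 125L) {
  v <- base + slope * (seq_len(len) - len / 2) + stats::rnorm(len, sd = noise_sd)
  dip <- function(v, center, depth) {
    ys <- clamp((center - 1L):(center + 1L), 1L, len)
    v[ys] <- v[ys] - depth
    v
  }
  if (control_dark > 0) {
    v <- dip(v, 26L + jitter[1], control_dark * (base - .line_lum()))
  }
  if (test_dark > 0) {
    v <- dip(v, 89L + jitter[2], test_dark * (base - .line_lum()))
  }
  if (alcohol_level > 0) {
    pad <- 60L:len
    v[pad] <- v[pad] - alcohol_level * (base - .pad_lum())
  }
  v
}

default_class_mix <- function(kind) {
  switch(kind,
    alcohol = c(positive = 74, negative = 264) / 338,
    control = c(valid = 1982, invalid = 376) / 2358,
    testline = c(very_positive = 459, positive = 122, doubtful = 200,
                 negative = 258, very_negative = 330) / 1369,
    stop("configuration error: unknown dataset kind: ", kind, call. = FALSE)
  )
}

#' Generate a labeled synthetic histogram dataset
#'
#' Draws `n` class-labeled raw strip profiles and preprocesses each with
#' the package chain: line-strip kinds are resampled to 100 bins, baseline
#' corrected and aligned to 62 bins (control signal in bins 1-31, test
#' signal in bins 32-62); the alcohol kind is resampled to 62 bins and
#' normalized by its first 15 bins. Alcohol and control classes are well
#' separated; adjacent test-line classes deliberately overlap in darkness.
#'
#' @param kind `"alcohol"`, `"control"` or `"testline"`.
#' @param n number of samples (>= 10).
#' @param class_mix named vector of class proportions summing to 1;
#'   defaults mirror the class frequencies of the corresponding training
#'   datasets.
#' @param seed integer seed; the same call is fully reproducible.
#' @return data.frame with columns `bin_001` ... `bin_062` and `label`.
#' @export
generate_histogram_dataset <- function(kind = c("alcohol", "control", "testline"),
                                       n, class_mix = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (n < 10L) stop("n must be at least 10", call. = FALSE)
  if (is.null(class_mix)) class_mix <- default_class_mix(kind)
  if (abs(sum(class_mix) - 1) > 1e-6) {
    stop("class_mix proportions must sum to 1", call. = FALSE)
  }
  classes <- names(class_mix)
  counts <- floor(class_mix * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    top <- order(class_mix * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[top] <- counts[top] + 1L
  }
  labels <- rep(classes, counts)

  with_seed(seed, {
    labels <- sample(labels)
    row_seeds <- sample.int(.Machine$integer.max - 1L, n)
    rows <- matrix(NA_real_, n, 62L)
    for (r in seq_len(n)) {
      lab <- labels[r]
      base <- stats::runif(1, 0.84, 0.94)
      slope <- stats::runif(1, -3e-4, 3e-4)
      # capture noise varies between devices and exposures; sampling its
      # scale per profile keeps the classifiers from treating the
      # background noise level itself as a class feature
      nsd <- stats::runif(1, 0.0008, 0.004)
      jit <- sample(-4:4, 2L, replace = TRUE)
      raw <- switch(kind,
        alcohol = raw_profile(
          alcohol_level = if (lab == "positive") stats::runif(1, 0.3, 0.95)
                          else stats::runif(1, 0, 0.02),
          base = base, slope = slope, noise_sd = nsd, jitter = jit),
        control = raw_profile(
          control_dark = if (lab == "valid") stats::runif(1, 0.3, 0.95) else 0,
          test_dark = stats::runif(1, 0, 1),
          base = base, slope = slope, noise_sd = nsd, jitter = jit),
        testline = {
          iv <- testline_darkness_interval(lab)
          raw_profile(control_dark = stats::runif(1, 0.5, 0.95),
                      test_dark = stats::runif(1, iv[1], iv[2]),
                      base = base, slope = slope, noise_sd = nsd, jitter = jit)
        })
      h <- new_lateral_histogram(raw, "raw")
      rows[r, ] <- if (kind == "alcohol") {
        alcohol_normalize(resample_bins(h, 62L))$values
      } else {
        align_peaks(baseline_correct(resample_bins(h, 100L),
                                     seed = row_seeds[r]))$values
      }
    }
    out <- as.data.frame(rows)
    names(out) <- sprintf("bin_%03d", 1:62)
    out$label <- labels
    out
  })
}
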