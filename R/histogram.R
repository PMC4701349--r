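# Lateral intensity histograms: the 1-D mean-intensity profile along a
# strip's flow axis, and its preprocessing chain. Non-alcohol strips:
# raw -> 100-bin quadratic resampling -> RANSAC linear baseline removal ->
# two-half minima alignment to 62 bins (control half first). Alcohol
# strips: raw -> 62-bin resampling -> subtraction of the mean of the first
# 15 bins.

new_lateral_histogram <- function(values, stage, strip_id = NA_character_,
                                  metadata = list()) {
  structure(list(values = as.numeric(values), stage = stage,
                 strip_id = strip_id, metadata = metadata),
            class = "lateral_histogram")
}

#' @export
print.lateral_histogram <- function(x, ...) {
  cat("<lateral_histogram> stage=", x$stage, ", ", length(x$values),
      " bins", if (!is.na(x$strip_id)) paste0(", strip ", x$strip_id), "\n",
      sep = "")
  invisible(x)
}

#' Extract the raw lateral histogram of a strip window
#'
#' Each profile value is the mean pixel intensity of one image row of the
#' window, the index running along the strip's flow axis and the mean taken
#' across the strip width. RGB windows are first reduced to luminance.
#'
#' @param window_image grayscale matrix or RGB array (the histogram
#'   window).
#' @param strip_id optional strip identifier carried in the result.
#' @return `lateral_histogram` at stage `"raw"`, length = window height.
#' @export
extract_profile <- function(window_image, strip_id = NA_character_) {
  g <- rgb_to_gray(window_image)
  if (ncol(g) < 1L || nrow(g) < 1L) {
    stop("zero-size histogram window", call. = FALSE)
  }
  new_lateral_histogram(rowMeans(g), "raw", strip_id)
}

# Piecewise quadratic (3-point Lagrange) interpolation of (xs, ys) at xq.
# Each query uses the nearest run of three consecutive nodes; exact on
# globally quadratic data.
quadratic_interp <- function(xs, ys, xq) {
  n <- length(xs)
  j <- findInterval(xq, xs, all.inside = TRUE)  # xs[j] <= xq < xs[j+1]
  j <- clamp(j, 2L, n - 1L)                      # center node of the triple
  x0 <- xs[j - 1L]; x1 <- xs[j]; x2 <- xs[j + 1L]
  y0 <- ys[j - 1L]; y1 <- ys[j]; y2 <- ys[j + 1L]
  l0 <- (xq - x1) * (xq - x2) / ((x0 - x1) * (x0 - x2))
  l1 <- (xq - x0) * (xq - x2) / ((x1 - x0) * (x1 - x2))
  l2 <- (xq - x0) * (xq - x1) / ((x2 - x0) * (x2 - x1))
  y0 * l0 + y1 * l1 + y2 * l2
}

#' Resample a raw histogram to a fixed bin count
#'
#' Quadratic interpolation over normalized position, evaluated at `n_bin`
#' equispaced nodes; the first and last values are preserved exactly.
#' Different captures thus yield profiles of identical length regardless of
#' window height.
#'
#' @param hist a `lateral_histogram` at stage `"raw"`.
#' @param n_bin target bin count (100 for line strips, 62 for the alcohol
#'   path).
#' @return `lateral_histogram` at stage `"resampled100"` (or
#'   `"resampled62"` when `n_bin = 62`).
#' @export
resample_bins <- function(hist, n_bin = 100L) {
  stopifnot(inherits(hist, "lateral_histogram"))
  if (hist$stage != "raw") stop("resample_bins expects a raw histogram", call. = FALSE)
  m <- length(hist$values)
  if (m < 3L) stop("need at least 3 raw bins for quadratic interpolation", call. = FALSE)
  xs <- seq(0, 1, length.out = m)
  xq <- seq(0, 1, length.out = n_bin)
  v <- quadratic_interp(xs, hist$values, xq)
  v[1] <- hist$values[1]; v[n_bin] <- hist$values[m]
  new_lateral_histogram(v, paste0("resampled", n_bin), hist$strip_id,
                        hist$metadata)
}

# Robust linear fit y = a*i + b by RANSAC over 2-point samples, refit on
# the inlier set by least squares. Vectorized over iterations.
ransac_line <- function(i, y, threshold, max_iters = 500L, seed = 1L) {
  n <- length(i)
  if (n < 2L) stop("fewer than 2 points for baseline fit", call. = FALSE)
  pick <- with_seed(seed, {
    cbind(sample.int(n, max_iters, replace = TRUE),
          sample.int(n, max_iters, replace = TRUE))
  })
  ok <- pick[, 1] != pick[, 2] & i[pick[, 1]] != i[pick[, 2]]
  pick <- pick[ok, , drop = FALSE]
  a <- (y[pick[, 2]] - y[pick[, 1]]) / (i[pick[, 2]] - i[pick[, 1]])
  b <- y[pick[, 1]] - a * i[pick[, 1]]
  # residual matrix: candidate models x points
  resid <- abs(outer(a, i) + b - matrix(y, nrow(pick), n, byrow = TRUE))
  support <- rowSums(resid <= threshold)
  best <- which.max(support)
  inl <- which(resid[best, ] <= threshold)
  if (length(inl) < 2L) inl <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, i[inl]), y[inl])
  c(b = unname(fit$coefficients[1]), a = unname(fit$coefficients[2]))
}

#' Remove the linear illumination baseline of a profile
#'
#' Fits `y = a * i + b` robustly (RANSAC: the narrow line dips are
#' outliers, the illuminated background is the inlier set) and subtracts
#' it, leaving dips on a near-zero baseline. The fitted `(a, b)` is stored
#' in the result metadata.
#'
#' @param hist a `lateral_histogram` at stage `"resampled100"`.
#' @param threshold inlier residual bound; by default 5% of the profile's
#'   dynamic range (floored at 1e-6 for flat profiles).
#' @param max_iters RANSAC sample count.
#' @param seed integer RNG seed.
#' @return `lateral_histogram` at stage `"baseline_corrected"`.
#' @export
baseline_correct <- function(hist, threshold = NULL, max_iters = 500L,
                             seed = 1L) {
  stopifnot(inherits(hist, "lateral_histogram"))
  if (hist$stage != "resampled100") {
    stop("baseline_correct expects a 100-bin resampled histogram", call. = FALSE)
  }
  v <- hist$values
  idx <- seq_along(v)
  if (is.null(threshold)) {
    threshold <- max(0.05 * diff(range(v)), 1e-6)
  }
  ab <- ransac_line(idx, v, threshold, max_iters, seed)
  out <- v - (ab["a"] * idx + ab["b"])
  md <- hist$metadata
  md$baseline_a <- unname(ab["a"]); md$baseline_b <- unname(ab["b"])
  new_lateral_histogram(unname(out), "baseline_corrected", hist$strip_id, md)
}

#' Align the control and test line dips into a fixed 62-bin histogram
#'
#' The 100-bin profile is split into two halves (bins 1-50 and 50-100, bin
#' 50 shared); the minimum of each half locates the control and test line.
#' A window of 15 bins on each side of each minimum (31 + 31 = 62 values,
#' control half first) forms the final histogram. Minima ties break toward
#' the lowest index; windows near a segment border are shifted inward so
#' 31 bins are always taken.
#'
#' @param hist a `lateral_histogram` at stage `"baseline_corrected"`.
#' @return `lateral_histogram` at stage `"aligned62"` with minima positions
#'   `h_min1`, `h_min2` in the metadata.
#' @export
align_peaks <- function(hist) {
  stopifnot(inherits(hist, "lateral_histogram"))
  if (hist$stage != "baseline_corrected" || length(hist$values) != 100L) {
    stop("align_peaks expects a 100-bin baseline-corrected histogram",
         call. = FALSE)
  }
  v <- hist$values
  take <- function(lo, hi) {
    m <- (lo:hi)[which.min(v[lo:hi])]
    start <- clamp(m - 15L, lo, hi - 30L)
    list(min = m, window = v[start:(start + 30L)])
  }
  first <- take(1L, 50L)
  second <- take(50L, 100L)
  md <- hist$metadata
  md$h_min1 <- first$min; md$h_min2 <- second$min
  new_lateral_histogram(c(first$window, second$window), "aligned62",
                        hist$strip_id, md)
}

#' Normalize an alcohol-strip histogram by its leading bins
#'
#' The mean of the first 15 values — the pre-pad region of the strip,
#' which tracks illumination but carries no signal — is subtracted from
#' the whole 62-bin profile, removing the illumination offset between
#' captures. The first 15 output bins average exactly zero.
#'
#' @param hist a `lateral_histogram` of length 62 (stage `"resampled62"`).
#' @param n_av number of leading bins averaged (default 15).
#' @return `lateral_histogram` at stage `"alcohol62"`.
#' @export
alcohol_normalize <- function(hist, n_av = 15L) {
  stopifnot(inherits(hist, "lateral_histogram"))
  if (length(hist$values) != 62L) {
    stop("alcohol_normalize expects a 62-bin histogram", call. = FALSE)
  }
  v <- hist$values - mean(hist$values[seq_len(n_av)])
  new_lateral_histogram(v, "alcohol62", hist$strip_id, hist$metadata)
}

#' Full preprocessing chain for one strip window
#'
#' Convenience wrapper running the stage sequence appropriate to the strip
#' type: line strips `raw -> resampled100 -> baseline_corrected ->
#' aligned62`, alcohol strips `raw -> resampled62 -> alcohol62`.
#'
#' @param window_image the histogram window (gray or RGB).
#' @param alcohol logical: alcohol-strip path?
#' @param strip_id carried through to the result.
#' @param seed RANSAC seed for the baseline fit.
#' @return the final `lateral_histogram` (`aligned62` or `alcohol62`).
#' @export
preprocess_strip <- function(window_image, alcohol = FALSE,
                             strip_id = NA_character_, seed = 1L) {
  h <- extract_profile(window_image, strip_id)
  if (alcohol) {
    alcohol_normalize(resample_bins(h, 62L))
  } else {
    align_peaks(baseline_correct(resample_bins(h, 100L), seed = seed))
  }
}

#' Export a histogram as a data frame
#'
#' @param x a `lateral_histogram`.
#' @param ... unused.
#' @return data.frame with `position`, `value`, `stage`, `strip_id`.
#' @export
as.data.frame.lateral_histogram <- function(x, ...) {
  data.frame(position = seq_along(x$values), value = x$values,
             stage = x$stage, strip_id = x$strip_id)
}
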