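# Strip-label segmentation in the rectified ROI: per-channel Otsu
# thresholding with alcohol-specific channel logic, morphological closing,
# a column occupancy filter, and contour position/area filters. Survivors
# are matched left-to-right to the configured panel and turned into
# per-strip histogram-extraction windows.

#' Otsu threshold of an intensity sample
#'
#' Maximizes between-class variance over a 256-level quantization of
#' `[0, 1]`, using the standard cumulative-moment recurrence. Ties break
#' toward the lowest threshold; among all maximizing levels the lowest is
#' returned, as a value on the `[0, 1]` scale. Pixels `<= threshold` form
#' the dark class.
#'
#' @param v numeric vector (or matrix) of intensities in `[0, 1]`.
#' @return scalar threshold in `[0, 1]`, or `NA` when the sample is
#'   constant (degenerate, no split exists).
#' @export
otsu_threshold <- function(v) {
  v <- as.numeric(v)
  lev <- clamp(floor(v * 255), 0, 255)
  counts <- tabulate(lev + 1L, nbins = 256L)
  n <- sum(counts)
  if (n == 0L || sum(counts > 0) < 2L) return(NA_real_)
  p <- counts / n
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, -Inf)
  k <- which.max(sigma_b)  # first maximum = lowest threshold
  (k - 1) / 255
}

#' Segment colored (non-white) pixels of the strip ROI
#'
#' Each RGB channel is binarized at its own Otsu threshold, foreground
#' being the darker (colored) class. With an alcohol strip present the two
#' conjunctions (G and B) and (G and R) are formed and merged; without one,
#' the union of the R and B masks is taken. A morphological closing then
#' fills small gaps.
#'
#' @param roi_image RGB array in `[0, 1]` (the rectified strip region).
#' @param alcohol_present logical; selects the channel combination.
#' @param combine how the two alcohol-case conjunctions merge: `"union"`
#'   (default, recall-preserving) or `"intersection"`.
#' @param closing_size side of the square closing structuring element.
#' @return binary mask matrix (0/1) of the ROI size.
#' @export
threshold_strips <- function(roi_image, alcohol_present = FALSE,
                             combine = c("union", "intersection"),
                             closing_size = 3L) {
  combine <- match.arg(combine)
  if (!is_rgb(roi_image)) {
    stop("format error: threshold_strips needs an RGB image", call. = FALSE)
  }
  ch_mask <- function(k) {
    thr <- otsu_threshold(roi_image[, , k])
    if (is.na(thr)) return(matrix(0L, dim(roi_image)[1], dim(roi_image)[2]))
    (roi_image[, , k] <= thr) * 1L
  }
  R <- ch_mask(1L); G <- ch_mask(2L); B <- ch_mask(3L)
  mask <- if (alcohol_present) {
    gb <- G * B; gr <- G * R
    if (combine == "union") pmax(gb, gr) else gb * gr
  } else {
    pmax(R, B)
  }
  if (sum(mask) == 0L) return(mask)
  kern <- EBImage::makeBrush(closing_size, shape = "box")
  closed <- EBImage::closing(mask, kern)
  matrix(as.integer(closed > 0), nrow(mask), ncol(mask))
}

#' Zero out sparsely occupied mask columns
#'
#' Columns whose foreground fraction falls below `min_fraction` are set to
#' zero, removing isolated pixels; columns at or above the fraction are
#' untouched. Idempotent.
#'
#' @param mask binary matrix.
#' @param min_fraction minimum fraction of foreground pixels a column must
#'   hold to survive (default 0.10).
#' @return filtered binary mask.
#' @export
column_filter <- function(mask, min_fraction = 0.10) {
  frac <- colSums(mask != 0) / nrow(mask)
  mask[, frac < min_fraction] <- 0L
  mask
}

#' Extract strip-label regions from the segmentation mask
#'
#' Connected components of the mask are filtered in two stages: contours
#' whose centroid lies in the lower half of the ROI are removed (spurious
#' reflections, lines, pads), then contours with area below half the
#' largest remaining area are removed. Survivors, sorted left to right,
#' must match the panel strip count one-to-one.
#'
#' @param mask binary matrix from [threshold_strips()] +
#'   [column_filter()].
#' @param panel a [panel_config()]; strip identities are assigned in
#'   left-to-right order.
#' @param area_ratio contours below `area_ratio` x the largest surviving
#'   area are dropped (default 0.5).
#' @return list of `labeled_region` objects, one per panel strip, each with
#'   `strip_id`, `bbox` (x, y, w, h), `centroid`, `area` and
#'   `bottom_middle`.
#' @export
extract_label_regions <- function(mask, panel, area_ratio = 0.5) {
  stopifnot(inherits(panel, "panel_config"))
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n_obj <- max(lab)
  if (n_obj == 0L) {
    stop("segmentation mismatch: found 0 label regions, expected ",
         length(panel$strips), call. = FALSE)
  }
  rows <- row(lab)[lab > 0]; cols <- col(lab)[lab > 0]; ids <- lab[lab > 0]
  regions <- lapply(seq_len(n_obj), function(i) {
    sel <- ids == i
    r <- rows[sel]; cc <- cols[sel]
    list(area = sum(sel),
         centroid = c(x = mean(cc), y = mean(r)),
         bbox = c(x = min(cc), y = min(r),
                  w = max(cc) - min(cc) + 1L, h = max(r) - min(r) + 1L))
  })
  # position filter: centroid must lie in the upper half of the ROI
  half <- nrow(mask) / 2
  regions <- Filter(function(rg) rg$centroid["y"] <= half, regions)
  if (length(regions) == 0L) {
    stop("segmentation mismatch: found 0 label regions, expected ",
         length(panel$strips), call. = FALSE)
  }
  # area filter relative to the largest surviving contour
  a_max <- max(vapply(regions, `[[`, numeric(1), "area"))
  regions <- Filter(function(rg) rg$area >= area_ratio * a_max, regions)
  if (length(regions) != length(panel$strips)) {
    stop("segmentation mismatch: found ", length(regions),
         " label regions, expected ", length(panel$strips), call. = FALSE)
  }
  ord <- order(vapply(regions, function(rg) rg$centroid["x"], numeric(1)))
  regions <- regions[ord]
  mapply(function(rg, id) {
    rg$strip_id <- id
    # continuous box convention: midpoint of the bottom edge
    rg$bottom_middle <- c(x = rg$bbox[["x"]] + rg$bbox[["w"]] / 2,
                          y = rg$bbox[["y"]] + rg$bbox[["h"]])
    structure(rg, class = "labeled_region")
  }, regions, panel$strips, SIMPLIFY = FALSE)
}

#' Histogram-extraction window under a label region
#'
#' A rectangle centered horizontally on the label's bottom-middle point,
#' narrower than the label (`width_factor`) so strip-edge shadows stay
#' outside, starting `gap_factor` x label height below the label and
#' extending `length_factor` x label height downward, clipped to the ROI.
#'
#' @param region a `labeled_region`.
#' @param roi_size `c(height, width)` of the ROI in px.
#' @param width_factor,gap_factor,length_factor geometry multipliers (see
#'   [panel_config()]).
#' @return named numeric `c(x, y, w, h)` of the window.
#' @export
histogram_window <- function(region, roi_size, width_factor = 0.6,
                             gap_factor = 0.2, length_factor = 2.5) {
  bw <- region$bbox[["w"]]; bh <- region$bbox[["h"]]
  cx <- region$bottom_middle[["x"]]
  ww <- round(width_factor * bw)
  hh <- round(length_factor * bh)
  x0 <- max(1, round(cx - ww / 2))
  y0 <- max(1, round(region$bottom_middle[["y"]] + gap_factor * bh))
  x1 <- min(roi_size[2], x0 + ww - 1)
  y1 <- min(roi_size[1], y0 + hh - 1)
  if (x1 <= x0 || y1 <= y0 + 2) {
    stop("segmentation error: degenerate histogram window after clipping",
         call. = FALSE)
  }
  c(x = x0, y = y0, w = x1 - x0 + 1, h = y1 - y0 + 1)
}
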