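# ORB binary features: FAST-9 corners with intensity-centroid orientation
# (oFAST) and steered 256-bit BRIEF descriptors (rBRIEF), detected over a
# scale pyramid. All routines are deterministic; the BRIEF test pattern is
# generated once per session from a fixed seed.

# Bresenham circle of radius 3: the 16 segment-test pixels, clockwise from
# 12 o'clock. dy is the row offset (negative = up).
.fast_circle <- cbind(
  dx = c(0L, 1L, 2L, 3L, 3L, 3L, 2L, 1L, 0L, -1L, -2L, -3L, -3L, -3L, -2L, -1L),
  dy = c(-3L, -3L, -2L, -1L, 0L, 1L, 2L, 3L, 3L, 3L, 2L, 1L, 0L, -1L, -2L, -3L)
)

#' ORB detector/descriptor parameters
#'
#' @param n_keypoints maximum keypoints kept (best corner scores first).
#' @param n_levels number of pyramid levels.
#' @param scale_factor geometric downscaling factor between levels.
#' @param fast_threshold segment-test contrast threshold on the `[0, 1]`
#'   intensity scale (default 20/255, the customary FAST setting).
#' @param edge_margin border (px) in which keypoints are discarded so the
#'   31x31 descriptor patch stays inside the image.
#' @param patch_size side of the (odd) square patch used for orientation and
#'   descriptor tests.
#' @return a list of class `orb_params`.
#' @export
orb_params <- function(n_keypoints = 500L, n_levels = 8L, scale_factor = 1.2,
                       fast_threshold = 20 / 255, edge_margin = 16L,
                       patch_size = 31L) {
  stopifnot(n_keypoints >= 1, n_levels >= 1, scale_factor > 1,
            fast_threshold > 0, patch_size %% 2 == 1)
  structure(list(n_keypoints = as.integer(n_keypoints),
                 n_levels = as.integer(n_levels),
                 scale_factor = scale_factor,
                 fast_threshold = fast_threshold,
                 edge_margin = as.integer(edge_margin),
                 patch_size = as.integer(patch_size)),
            class = "orb_params")
}

# FAST-9 segment test on a grayscale matrix. Returns data.frame(x, y, score).
# A cardinal-point prefilter (a 9-long arc must contain >= 3 of the 4
# compass pixels on its side) discards most of the image cheaply; the full
# 16-start arc test runs only on the survivors.
fast_detect <- function(img, threshold = 20 / 255, margin = 16L) {
  h <- nrow(img); w <- ncol(img)
  if (h <= 2L * margin + 6L || w <= 2L * margin + 6L) {
    return(data.frame(x = numeric(0), y = numeric(0), score = numeric(0)))
  }
  rows <- (margin + 1L):(h - margin)
  cols <- (margin + 1L):(w - margin)
  idx <- as.vector(outer(rows, (cols - 1L) * h, `+`))
  p <- img[idx]
  off <- .fast_circle[, "dx"] * h + .fast_circle[, "dy"]

  cardinal <- c(1L, 5L, 9L, 13L)
  nb <- 0L; nd <- 0L
  for (k in cardinal) {
    v <- img[idx + off[k]]
    nb <- nb + (v > p + threshold)
    nd <- nd + (v < p - threshold)
  }
  cand <- which(nb >= 3L | nd >= 3L)
  if (length(cand) == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0), score = numeric(0)))
  }
  ci <- idx[cand]; cp <- p[cand]
  B <- matrix(FALSE, length(ci), 16L)
  D <- matrix(FALSE, length(ci), 16L)
  score <- numeric(length(ci))
  for (k in 1:16) {
    v <- img[ci + off[k]]
    B[, k] <- v > cp + threshold
    D[, k] <- v < cp - threshold
    score <- score + pmax(abs(v - cp) - threshold, 0)
  }
  okB <- logical(length(ci)); okD <- okB
  for (s in 1:16) {
    arc <- ((s - 1L):(s + 7L)) %% 16L + 1L
    aB <- B[, arc[1]]; aD <- D[, arc[1]]
    for (k in arc[-1]) { aB <- aB & B[, k]; aD <- aD & D[, k] }
    okB <- okB | aB; okD <- okD | aD
  }
  keep <- okB | okD
  if (!any(keep)) {
    return(data.frame(x = numeric(0), y = numeric(0), score = numeric(0)))
  }
  # 3x3 non-maximum suppression on the sparse score surface
  sc <- matrix(0, h, w)
  sc[ci[keep]] <- score[keep]
  mx <- sc
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0L && dy == 0L) next
    sh <- matrix(0, h, w)
    ys <- max(1L, 1L + dy):min(h, h + dy)
    xs <- max(1L, 1L + dx):min(w, w + dx)
    sh[ys, xs] <- sc[ys - dy, xs - dx]
    mx <- pmax(mx, sh)
  }
  win <- ci[keep][sc[ci[keep]] >= mx[ci[keep]]]
  data.frame(x = ((win - 1L) %/% h) + 1L,
             y = ((win - 1L) %% h) + 1L,
             score = sc[win])
}

# Orientation by intensity centroid over a disc of radius (patch-1)/2:
# theta = atan2(m01, m10) with moments about the keypoint.
keypoint_orientation <- function(img, x, y, patch_size = 31L) {
  r <- (patch_size - 1L) %/% 2L
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g <- g[g$dx^2 + g$dy^2 <= r^2, ]
  h <- nrow(img)
  base <- (x - 1L) * h + y
  m10 <- numeric(length(x)); m01 <- numeric(length(x))
  for (i in seq_len(nrow(g))) {
    v <- img[base + g$dx[i] * h + g$dy[i]]
    m10 <- m10 + g$dx[i] * v
    m01 <- m01 + g$dy[i] * v
  }
  atan2(m01, m10)
}

# The 256 BRIEF point pairs: isotropic Gaussian with sd = patch/5, clipped
# to radius 13 so any rotation keeps samples inside a 31x31 patch.
brief_pattern <- function(patch_size = 31L) {
  if (!is.null(.lfa_cache$brief) && .lfa_cache$brief_patch == patch_size) {
    return(.lfa_cache$brief)
  }
  pat <- with_seed(90210L, {
    draw <- function(n) {
      p <- matrix(stats::rnorm(2L * n, sd = patch_size / 5), ncol = 2L)
      rad <- sqrt(rowSums(p^2))
      bad <- rad > 13
      p[bad, ] <- p[bad, ] * (13 / rad[bad])
      p
    }
    list(p1 = draw(256L), p2 = draw(256L))
  })
  .lfa_cache$brief <- pat
  .lfa_cache$brief_patch <- patch_size
  pat
}

.lfa_cache <- new.env(parent = emptyenv())

# Steered BRIEF descriptors for keypoints (x, y, angle) on a box-smoothed
# image. Returns an n x 256 integer 0/1 matrix.
brief_describe <- function(smoothed, x, y, angle, patch_size = 31L) {
  pat <- brief_pattern(patch_size)
  n <- length(x)
  desc <- matrix(0L, n, 256L)
  ca <- cos(angle); sa <- sin(angle)
  h <- nrow(smoothed)
  for (t in 1:256) {
    x1 <- round(x + ca * pat$p1[t, 1] - sa * pat$p1[t, 2])
    y1 <- round(y + sa * pat$p1[t, 1] + ca * pat$p1[t, 2])
    x2 <- round(x + ca * pat$p2[t, 1] - sa * pat$p2[t, 2])
    y2 <- round(y + sa * pat$p2[t, 1] + ca * pat$p2[t, 2])
    v1 <- smoothed[(x1 - 1L) * h + y1]
    v2 <- smoothed[(x2 - 1L) * h + y2]
    desc[, t] <- as.integer(v1 < v2)
  }
  desc
}

#' Detect ORB keypoints and descriptors
#'
#' Runs FAST-9 with non-maximum suppression on each level of a scale
#' pyramid, assigns each corner an intensity-centroid orientation, and
#' extracts a steered 256-bit BRIEF descriptor from the box-smoothed level
#' image. Keypoint coordinates are reported in the full-resolution frame.
#'
#' @param img grayscale matrix or RGB array in `[0, 1]`.
#' @param params an [orb_params()] list.
#' @return list with `keypoints` (data.frame x, y, angle, score, level) and
#'   `descriptors` (n x 256 integer 0/1 matrix), ordered by decreasing
#'   corner score and truncated to `params$n_keypoints`.
#' @export
orb_detect <- function(img, params = orb_params()) {
  g <- rgb_to_gray(img)
  kps <- list(); descs <- list()
  level_img <- g
  for (lev in seq_len(params$n_levels)) {
    scale <- params$scale_factor^(lev - 1L)
    if (lev > 1L) level_img <- resize_gray(g, scale)
    if (nrow(level_img) <= 2L * params$edge_margin + 6L ||
        ncol(level_img) <= 2L * params$edge_margin + 6L) break
    kp <- fast_detect(level_img, params$fast_threshold, params$edge_margin)
    if (nrow(kp) == 0L) next
    sm <- box_blur(level_img, 5L)
    ang <- keypoint_orientation(level_img, kp$x, kp$y, params$patch_size)
    d <- brief_describe(sm, kp$x, kp$y, ang, params$patch_size)
    sx <- ncol(g) / ncol(level_img); sy <- nrow(g) / nrow(level_img)
    kps[[lev]] <- data.frame(x = (kp$x - 0.5) * sx + 0.5,
                             y = (kp$y - 0.5) * sy + 0.5,
                             angle = ang, score = kp$score, level = lev)
    descs[[lev]] <- d
  }
  if (length(kps) == 0L) {
    return(list(keypoints = data.frame(x = numeric(0), y = numeric(0),
                                       angle = numeric(0), score = numeric(0),
                                       level = integer(0)),
                descriptors = matrix(0L, 0L, 256L)))
  }
  keypoints <- do.call(rbind, kps)
  descriptors <- do.call(rbind, descs)
  ord <- order(-keypoints$score, keypoints$x, keypoints$y)
  if (length(ord) > params$n_keypoints) ord <- ord[seq_len(params$n_keypoints)]
  keypoints <- keypoints[ord, , drop = FALSE]
  rownames(keypoints) <- NULL
  list(keypoints = keypoints,
       descriptors = descriptors[ord, , drop = FALSE])
}

#' Hamming distance matrix between binary descriptor sets
#'
#' @param a,b integer 0/1 matrices with one descriptor per row and equal
#'   column counts.
#' @return `nrow(a)` x `nrow(b)` matrix of Hamming distances.
#' @export
hamming_distance <- function(a, b) {
  a <- matrix(as.numeric(a), nrow = nrow(a))
  b <- matrix(as.numeric(b), nrow = nrow(b))
  if (ncol(a) != ncol(b)) stop("descriptor lengths differ", call. = FALSE)
  a %*% t(1 - b) + (1 - a) %*% t(b)
}
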