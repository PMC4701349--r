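# Internal helpers shared across modules.
#
# Image convention: a grayscale image is a numeric matrix [row, col], an RGB
# image a numeric array [row, col, 3], intensities in [0, 1]. A point is
# (x, y) with x = column and y = row, 1-based pixel centers. A homography is
# a 3x3 matrix mapping template-frame (x, y, 1) to image-frame homogeneous
# coordinates.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. Keeps every generator a pure function of its
# arguments without clobbering the user's random stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_gray <- function(img) is.matrix(img) && is.numeric(img)

is_rgb <- function(img) is.array(img) && length(dim(img)) == 3L && dim(img)[3] >= 3L

#' Convert an RGB image to luminance
#'
#' Standard Rec. 601 weighting (0.299 R + 0.587 G + 0.114 B). Grayscale
#' input is returned unchanged.
#'
#' @param img numeric matrix (grayscale) or `[h, w, 3]` array in `[0, 1]`.
#' @return numeric matrix of luminance values.
#' @export
rgb_to_gray <- function(img) {
  if (is_gray(img)) return(img)
  if (!is_rgb(img)) stop("expected a grayscale matrix or an RGB array", call. = FALSE)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# Bilinear sampling of a grayscale matrix at fractional (x, y); coordinates
# outside the image are clamped to the border pixel.
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- clamp(x, 1, w); y <- clamp(y, 1, h)
  x0 <- clamp(floor(x), 1, w - 1L); y0 <- clamp(floor(y), 1, h - 1L)
  if (w == 1L) x0 <- rep(1, length(x))
  if (h == 1L) y0 <- rep(1, length(y))
  fx <- x - x0; fy <- y - y0
  x1 <- pmin(x0 + 1L, w); y1 <- pmin(y0 + 1L, h)
  i00 <- (x0 - 1) * h + y0; i10 <- (x1 - 1) * h + y0
  i01 <- (x0 - 1) * h + y1; i11 <- (x1 - 1) * h + y1
  img[i00] * (1 - fx) * (1 - fy) + img[i10] * fx * (1 - fy) +
    img[i01] * (1 - fx) * fy + img[i11] * fx * fy
}

# Apply a homography to an n x 2 matrix of (x, y) points.
apply_homography <- function(H, pts) {
  pts <- matrix(pts, ncol = 2L)
  p <- H %*% rbind(t(pts), 1)
  cbind(x = p[1, ] / p[3, ], y = p[2, ] / p[3, ])
}

# Warp `img` so that output pixel (x, y) takes the value of `img` at H(x, y).
# With H mapping template -> image this rectifies a captured image into the
# template frame. `fill` is used where H maps outside the source.
warp_homography <- function(img, H, out_width, out_height, fill = 0) {
  grid_x <- rep(seq_len(out_width), each = out_height)
  grid_y <- rep(seq_len(out_height), times = out_width)
  src <- apply_homography(H, cbind(grid_x, grid_y))
  inside <- src[, 1] >= 1 & src[, 1] <= ncol_any(img) &
    src[, 2] >= 1 & src[, 2] <= nrow_any(img)
  warp_one <- function(m) {
    v <- bilinear_sample(m, src[, 1], src[, 2])
    v[!inside] <- fill
    matrix(v, out_height, out_width)
  }
  if (is_gray(img)) return(warp_one(img))
  out <- array(0, dim = c(out_height, out_width, dim(img)[3]))
  for (k in seq_len(dim(img)[3])) out[, , k] <- warp_one(img[, , k])
  out
}

nrow_any <- function(img) if (is_gray(img)) nrow(img) else dim(img)[1]
ncol_any <- function(img) if (is_gray(img)) ncol(img) else dim(img)[2]

# Downscale a grayscale image by `factor` (> 1) with bilinear sampling.
resize_gray <- function(img, factor) {
  h2 <- max(2L, floor(nrow(img) / factor))
  w2 <- max(2L, floor(ncol(img) / factor))
  sx <- ncol(img) / w2; sy <- nrow(img) / h2
  gx <- rep((seq_len(w2) - 0.5) * sx + 0.5, each = h2)
  gy <- rep((seq_len(h2) - 0.5) * sy + 0.5, times = w2)
  matrix(bilinear_sample(img, gx, gy), h2, w2)
}

# Box blur of side `k` (odd) via integral image; border handled by
# normalizing with the actual window area.
box_blur <- function(img, k = 5L) {
  r <- (k - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  ii <- rbind(0, cbind(0, apply(apply(img, 2, cumsum), 1, cumsum)))
  # after the double apply the matrix is transposed: ii is (w+1) x (h+1)
  y0 <- pmax(seq_len(h) - r - 1L, 0L); y1 <- pmin(seq_len(h) + r, h)
  x0 <- pmax(seq_len(w) - r - 1L, 0L); x1 <- pmin(seq_len(w) + r, w)
  S <- ii[x1 + 1L, y1 + 1L] - ii[x0 + 1L, y1 + 1L] -
    ii[x1 + 1L, y0 + 1L] + ii[x0 + 1L, y0 + 1L]
  area <- outer(x1 - x0, y1 - y0)
  t(S / area)
}

# Read an image file (PNG) as an RGB array in [0, 1].
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  img <- png::readPNG(path)
  if (is.matrix(img)) {
    img <- array(rep(img, 3L), dim = c(nrow(img), ncol(img), 3L))
  } else if (dim(img)[3] > 3L) {
    img <- img[, , 1:3, drop = FALSE]
  }
  img
}

write_image <- function(img, path) {
  png::writePNG(clamp(img, 0, 1), path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
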