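# Registration of a captured card photograph against a stored template:
# ORB keypoints are matched by Hamming distance with a mutual-consistency
# filter, a homography is estimated by RANSAC, and the strip region defined
# once in the template is rectified out of the captured frame.

#' Build a template model from a template image
#'
#' Computed once, off-line: ORB keypoints and descriptors of the template
#' image are extracted and stored together with the manually defined
#' quadrilateral bounding the strips.
#'
#' @param image grayscale matrix or RGB array in `[0, 1]`.
#' @param strip_quad 4x2 matrix of (x, y) corners of the strip region,
#'   ordered (top-left, top-right, bottom-right, bottom-left).
#' @param params an [orb_params()] list.
#' @return an object of class `template_model` with fields `keypoints`,
#'   `descriptors`, `strip_quad`, `image_size` and `image`.
#' @export
build_template <- function(image, strip_quad, params = orb_params()) {
  strip_quad <- matrix(as.numeric(strip_quad), ncol = 2L)
  if (nrow(strip_quad) != 4L) stop("strip_quad must have 4 corners", call. = FALSE)
  w <- ncol_any(image); h <- nrow_any(image)
  if (any(strip_quad[, 1] < 1 | strip_quad[, 1] > w |
          strip_quad[, 2] < 1 | strip_quad[, 2] > h)) {
    stop("strip_quad must lie inside the template image", call. = FALSE)
  }
  feats <- orb_detect(image, params)
  if (nrow(feats$keypoints) < 4L) {
    stop("template error: fewer than 4 keypoints found (untextured template)",
         call. = FALSE)
  }
  structure(list(keypoints = feats$keypoints,
                 descriptors = feats$descriptors,
                 strip_quad = strip_quad,
                 image_size = c(width = w, height = h),
                 orb = params,
                 image = rgb_to_gray(image)),
            class = "template_model")
}

#' @export
print.template_model <- function(x, ...) {
  cat("<template_model> ", nrow(x$keypoints), " keypoints, ",
      x$image_size["width"], "x", x$image_size["height"],
      " px, strip quad [",
      paste(sprintf("(%g,%g)", x$strip_quad[, 1], x$strip_quad[, 2]),
            collapse = " "), "]\n", sep = "")
  invisible(x)
}

#' Match binary descriptors by Hamming distance with mutual consistency
#'
#' For every template descriptor the image descriptor at minimum Hamming
#' distance is selected (brute force); a pair survives only if the two
#' descriptors are each other's nearest neighbor. Distance ties break
#' toward the lowest index, so matching is deterministic.
#'
#' @param d_template,d_image integer 0/1 descriptor matrices (rows =
#'   descriptors).
#' @return data.frame with columns `template`, `image`, `distance`; possibly
#'   zero rows.
#' @export
match_descriptors <- function(d_template, d_image) {
  if (nrow(d_template) == 0L || nrow(d_image) == 0L) {
    stop("descriptor sets must be non-empty", call. = FALSE)
  }
  D <- hamming_distance(d_template, d_image)
  fwd <- apply(D, 1, which.min)          # template -> image
  bwd <- apply(D, 2, which.min)          # image -> template
  keep <- bwd[fwd] == seq_len(nrow(D))
  data.frame(template = which(keep),
             image = fwd[keep],
             distance = D[cbind(which(keep), fwd[keep])])
}

# Direct linear transform for a homography from >= 4 correspondences, with
# Hartley normalization. Returns NULL when the system is degenerate.
homography_dlt <- function(src, dst) {
  normalise <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
    s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
    T <- matrix(c(s, 0, -s * ctr[1], 0, s, -s * ctr[2], 0, 0, 1), 3, 3, byrow = TRUE)
    list(p = sweep(p, 2, ctr) * s, T = T)
  }
  ns <- normalise(src); nd <- normalise(dst)
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- ns$p[i, 1]; y <- ns$p[i, 2]; u <- nd$p[i, 1]; v <- nd$p[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ] <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  sv <- svd(A, nu = 0, nv = 9)
  hvec <- sv$v[, 9]
  H <- matrix(hvec, 3, 3, byrow = TRUE)
  if (abs(det(H)) < 1e-12) return(NULL)
  H <- solve(nd$T) %*% H %*% ns$T
  if (abs(H[3, 3]) < 1e-12) return(NULL)
  H / H[3, 3]
}

#' Estimate a homography from matched keypoints with RANSAC
#'
#' Repeated minimal (4-point) samples vote by reprojection-error inlier
#' count; the winning model is refit by least squares on all its inliers.
#' Iteration count adapts to the observed inlier ratio (0.999 confidence)
#' up to `max_iters`. Deterministic for a fixed `seed`.
#'
#' @param pairs data.frame from [match_descriptors()].
#' @param kp_template,kp_image keypoint data.frames with `x`, `y` columns.
#' @param ransac_threshold_px inlier reprojection error bound (px).
#' @param max_iters RANSAC iteration cap.
#' @param min_inliers minimum supporting correspondences.
#' @param seed integer RNG seed.
#' @return object of class `homography_result`: fields `H` (3x3, template to
#'   image), `inlier_count`, `match_count`, `inliers` (row indices into
#'   `pairs`).
#' @export
estimate_homography <- function(pairs, kp_template, kp_image,
                                ransac_threshold_px = 3, max_iters = 2000L,
                                min_inliers = 10L, seed = 1L) {
  if (nrow(pairs) < 4L) {
    stop("registration failure: fewer than 4 matched pairs", call. = FALSE)
  }
  src <- cbind(kp_template$x[pairs$template], kp_template$y[pairs$template])
  dst <- cbind(kp_image$x[pairs$image], kp_image$y[pairs$image])
  n <- nrow(src)
  best <- list(count = -1L, inl = NULL)
  with_seed(seed, {
    needed <- max_iters
    it <- 0L
    while (it < needed && it < max_iters) {
      it <- it + 1L
      s <- sample.int(n, 4L)
      if (any(duplicated(src[s, , drop = FALSE])) ||
          any(duplicated(dst[s, , drop = FALSE]))) next
      H <- homography_dlt(src[s, , drop = FALSE], dst[s, , drop = FALSE])
      if (is.null(H)) next
      proj <- apply_homography(H, src)
      err <- sqrt(rowSums((proj - dst)^2))
      inl <- which(err < ransac_threshold_px)
      if (length(inl) > best$count) {
        best <- list(count = length(inl), inl = inl)
        w <- length(inl) / n
        if (w > 0) {
          needed <- min(max_iters,
                        ceiling(log(1e-3) / log(pmax(1 - w^4, 1e-12))))
        }
      }
    }
  })
  if (best$count < max(4L, min_inliers)) {
    stop("registration failure: only ", max(best$count, 0L),
         " inliers (need ", max(4L, min_inliers), ")", call. = FALSE)
  }
  H <- homography_dlt(src[best$inl, , drop = FALSE], dst[best$inl, , drop = FALSE])
  if (is.null(H)) stop("registration failure: degenerate refit", call. = FALSE)
  structure(list(H = H, inlier_count = best$count, match_count = n,
                 inliers = best$inl),
            class = "homography_result")
}

#' @export
print.homography_result <- function(x, ...) {
  cat("<homography_result> inliers ", x$inlier_count, "/", x$match_count, "\n",
      sep = "")
  invisible(x)
}

#' Locate and rectify the strip region of a captured image
#'
#' Detects ORB features in the captured image, matches them against the
#' template, estimates the template-to-image homography, then warps the
#' captured image into the template frame and crops the strip
#' quadrilateral. Downstream geometry is therefore pose-invariant.
#'
#' @param image captured RGB array (or grayscale matrix) in `[0, 1]`.
#' @param template a [build_template()] model.
#' @param ransac_threshold_px,max_iters,min_inliers,seed passed to
#'   [estimate_homography()].
#' @return list with `roi` (rectified RGB/gray crop of the strip region),
#'   `homography` (the `homography_result`), and `projected_quad` (strip
#'   quad corners in the captured frame).
#' @export
locate_strip_region <- function(image, template, ransac_threshold_px = 3,
                                max_iters = 2000L, min_inliers = 10L,
                                seed = 1L) {
  feats <- orb_detect(image, template$orb)
  if (nrow(feats$keypoints) < 4L) {
    stop("registration failure: too few keypoints in captured image",
         call. = FALSE)
  }
  pairs <- match_descriptors(template$descriptors, feats$descriptors)
  hom <- estimate_homography(pairs, template$keypoints, feats$keypoints,
                             ransac_threshold_px, max_iters, min_inliers, seed)
  quad <- template$strip_quad
  x0 <- floor(min(quad[, 1])); x1 <- ceiling(max(quad[, 1]))
  y0 <- floor(min(quad[, 2])); y1 <- ceiling(max(quad[, 2]))
  # warp output pixel (x, y) of the template frame samples image at H(x, y);
  # restrict the warp to the quad's bounding box by translating H.
  Tr <- matrix(c(1, 0, x0 - 1, 0, 1, y0 - 1, 0, 0, 1), 3, 3, byrow = TRUE)
  Hcrop <- hom$H %*% Tr
  roi <- warp_homography(image, Hcrop, x1 - x0 + 1L, y1 - y0 + 1L)
  list(roi = roi, homography = hom,
       projected_quad = apply_homography(hom$H, quad))
}

#' Serialize / restore a template model as JSON
#'
#' Descriptors are stored hex-encoded (64 hex characters per 256-bit
#' descriptor); the template image itself is stored as a PNG next to the
#' JSON file and referenced by name.
#'
#' @param template a `template_model`.
#' @param path JSON file path; the image is written alongside with the same
#'   basename and extension `.png`.
#' @return `save_template` returns `path` invisibly; `load_template`
#'   returns the restored `template_model`.
#' @export
save_template <- function(template, path) {
  img_path <- sub("\\.json$", ".png", path)
  if (identical(img_path, path)) img_path <- paste0(path, ".png")
  write_image(template$image, img_path)
  obj <- list(
    keypoints = template$keypoints,
    descriptors = apply(template$descriptors, 1, bits_to_hex),
    strip_quad = template$strip_quad,
    image_size = as.list(template$image_size),
    orb = unclass(template$orb),
    image_file = basename(img_path)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_template
#' @export
load_template <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  img <- read_image(file.path(dirname(path), obj$image_file))
  desc <- t(vapply(obj$descriptors, hex_to_bits, integer(256L)))
  dimnames(desc) <- NULL
  structure(list(
    keypoints = as.data.frame(obj$keypoints),
    descriptors = desc,
    strip_quad = matrix(as.numeric(obj$strip_quad), ncol = 2L),
    image_size = c(width = obj$image_size$width, height = obj$image_size$height),
    orb = do.call(orb_params, obj$orb),
    image = rgb_to_gray(img)
  ), class = "template_model")
}

bits_to_hex <- function(bits) {
  nib <- matrix(bits, nrow = 4L)
  vals <- as.integer(8 * nib[1, ] + 4 * nib[2, ] + 2 * nib[3, ] + nib[4, ])
  paste(c("0", "1", "2", "3", "4", "5", "6", "7", "8", "9",
          "a", "b", "c", "d", "e", "f")[vals + 1L], collapse = "")
}

hex_to_bits <- function(hex) {
  vals <- strtoi(strsplit(hex, "")[[1]], base = 16L)
  as.integer(rbind(vals %/% 8 %% 2, vals %/% 4 %% 2, vals %/% 2 %% 2, vals %% 2))
}
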