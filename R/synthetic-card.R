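# Seeded synthetic test-card rendering. The generator stands in for the
# photographed dataset: it draws a white card with colored strip-label
# regions, transverse control/test lines of controlled darkness, an
# optional alcohol reactive pad, fiducial texture for feature matching, a
# linear illumination ramp, additive Gaussian noise and a small pose
# (translation + rotation) of the card within the frame. Ground truth for
# every rendered quantity is returned alongside the image.

#' Panel configuration
#'
#' Ordered strip identities of one card side plus geometry multipliers used
#' to place the histogram-extraction window under each strip label.
#'
#' @param strips character vector of strip identifiers, left to right
#'   (e.g. `c("AMP", "KET", "COC", "MET")`). The alcohol strip is named
#'   `"ALC"`.
#' @param width_factor histogram window width as a fraction of the label
#'   width.
#' @param gap_factor vertical gap between label bottom and window top, as a
#'   fraction of label height.
#' @param length_factor window height as a multiple of label height.
#' @return object of class `panel_config`.
#' @export
panel_config <- function(strips, width_factor = 0.6, gap_factor = 0.2,
                         length_factor = 2.5) {
  strips <- as.character(strips)
  if (length(strips) < 1L) stop("configuration error: empty panel", call. = FALSE)
  if (anyDuplicated(strips)) stop("duplicate strip identifiers", call. = FALSE)
  structure(list(strips = strips,
                 alcohol_present = "ALC" %in% strips,
                 width_factor = width_factor,
                 gap_factor = gap_factor,
                 length_factor = length_factor),
            class = "panel_config")
}

# Internal names of the five test-line classes, lightest (absent line,
# analyte above cutoff) to darkest.
testline_classes <- function() {
  c("very_positive", "positive", "doubtful", "negative", "very_negative")
}

# Line-darkness interval per class: five equal sub-intervals of [0, 1],
# widened by `overlap` on each shared boundary so adjacent classes are
# deliberately confusable, as real near-cutoff test lines are.
# `core = TRUE` returns the unambiguous central band.
testline_darkness_interval <- function(class, overlap = 0.02, core = FALSE) {
  k <- match(class, testline_classes())
  if (is.na(k)) stop("unknown test-line class: ", class, call. = FALSE)
  lo <- (k - 1) / 5; hi <- k / 5
  if (core) {
    pad <- (hi - lo) / 4
    c(lo + pad, hi - pad)
  } else {
    c(max(0, lo - overlap), min(1, hi + overlap))
  }
}

# Fixed card geometry (px) in a 640x480 frame. The physical card's pixel
# geometry is a generator choice; nothing downstream depends on these
# numbers except through detected label regions. The frame margins leave
# room for card rotations up to about +/-10 degrees plus +/-15 px
# translation without clipping.
card_geometry <- function() {
  list(frame_w = 640L, frame_h = 480L,
       card = c(x0 = 90, y0 = 70, x1 = 550, y1 = 410),
       quad = c(x0 = 190, y0 = 80, x1 = 450, y1 = 400),
       card_white = 0.92, bg_gray = 0.35,
       label_top = 10, label_h = 50, strip_frac = 0.72,
       control_y = 95, test_y = 158, line_h = 3,
       pad_y0 = 130, pad_y1 = 220,
       line_base = c(0.30, 0.20, 0.35),
       pad_blue = c(0.15, 0.25, 0.65))
}

# Distinct label colors, all channels <= 0.55 so every Otsu channel mask
# catches them against the white card.
label_color <- function(strip_id, index) {
  palette <- list(AMP = c(0.55, 0.15, 0.20), KET = c(0.15, 0.30, 0.55),
                  COC = c(0.50, 0.28, 0.10), MET = c(0.38, 0.12, 0.45),
                  OPI = c(0.12, 0.38, 0.22), THC = c(0.42, 0.38, 0.10),
                  OXY = c(0.30, 0.40, 0.15), BZO = c(0.55, 0.35, 0.10),
                  ALC = c(0.16, 0.22, 0.50))
  if (!is.null(palette[[strip_id]])) return(palette[[strip_id]])
  palette[[(index - 1L) %% length(palette) + 1L]]
}

# Per-strip horizontal layout inside the strip-region quad.
strip_layout <- function(geom, n_strips) {
  qw <- geom$quad["x1"] - geom$quad["x0"]
  pitch <- qw / n_strips
  width <- geom$strip_frac * pitch
  centers <- geom$quad["x0"] + (seq_len(n_strips) - 0.5) * pitch
  data.frame(center = as.numeric(centers), width = as.numeric(width))
}

draw_rect <- function(img, x0, y0, x1, y1, color) {
  ys <- max(1L, round(y0)):min(dim(img)[1], round(y1))
  xs <- max(1L, round(x0)):min(dim(img)[2], round(x1))
  for (k in 1:3) img[ys, xs, k] <- color[k]
  img
}

# Base card: background, white card, fiducial texture, strip labels.
# Identical for the template and for every card of the same panel/seed, so
# feature matching has stable structure to lock onto.
render_base_card <- function(panel, seed) {
  geom <- card_geometry()
  img <- array(geom$bg_gray, dim = c(geom$frame_h, geom$frame_w, 3L))
  cd <- geom$card
  img <- draw_rect(img, cd["x0"], cd["y0"], cd["x1"], cd["y1"],
                   rep(geom$card_white, 3L))
  # fiducial squares in the card margins, outside the strip quad
  q <- geom$quad
  zones <- rbind(c(cd["x0"] + 6, cd["y0"] + 6, q["x0"] - 12, cd["y1"] - 6),   # left
                 c(q["x1"] + 12, cd["y0"] + 6, cd["x1"] - 6, cd["y1"] - 6),   # right
                 c(q["x0"], cd["y0"] + 6, q["x1"], q["y0"] - 12))             # top
  zones <- zones[zones[, 3] - zones[, 1] > 24 & zones[, 4] - zones[, 2] > 24,
                 , drop = FALSE]
  img <- with_seed(seed, {
    for (z in seq_len(nrow(zones))) {
      zn <- zones[z, ]
      n_fid <- 20L
      for (i in seq_len(n_fid)) {
        side <- stats::runif(1, 6, 18)
        fx <- stats::runif(1, zn[1], max(zn[1] + 1, zn[3] - side))
        fy <- stats::runif(1, zn[2], max(zn[2] + 1, zn[4] - side))
        col <- stats::runif(3, 0.05, 0.45)
        img <- draw_rect(img, fx, fy, fx + side, fy + side, col)
      }
    }
    img
  })
  lay <- strip_layout(geom, length(panel$strips))
  for (s in seq_along(panel$strips)) {
    x0 <- lay$center[s] - lay$width[s] / 2
    x1 <- lay$center[s] + lay$width[s] / 2
    y0 <- q["y0"] + geom$label_top
    img <- draw_rect(img, x0, y0, x1, y0 + geom$label_h,
                     label_color(panel$strips[s], s))
  }
  img
}

#' Generate a synthetic template image
#'
#' A clean, axis-aligned card with textured fiducial content outside the
#' strip window (so ORB keypoints exist), colored strip labels, and no
#' lines, pad color, noise or pose. Deterministic given `seed`.
#'
#' @param panel a [panel_config()].
#' @param seed integer; fixes the fiducial layout.
#' @return list with `image` (RGB array), `strip_quad` (4x2 corner matrix),
#'   `panel`, `seed` and `geometry`.
#' @export
generate_template_image <- function(panel, seed = 1L) {
  if (!inherits(panel, "panel_config")) panel <- panel_config(panel)
  geom <- card_geometry()
  img <- render_base_card(panel, seed)
  q <- geom$quad
  quad <- rbind(c(q["x0"], q["y0"]), c(q["x1"], q["y0"]),
                c(q["x1"], q["y1"]), c(q["x0"], q["y1"]))
  dimnames(quad) <- NULL
  list(image = img, strip_quad = quad, panel = panel, seed = seed,
       geometry = geom)
}

#' Specification of one synthetic card
#'
#' @param panel a [panel_config()] (or character vector of strip ids).
#' @param control_line_intensity numeric in `[0, 1]` per non-alcohol strip
#'   (0 = control line absent, i.e. an invalid strip); recycled.
#' @param test_line_class test-line class name per non-alcohol strip (one
#'   of `r paste(testline_classes(), collapse = ", ")`); recycled.
#' @param alcohol_level pad blueness in `[0, 1]` for the `ALC` strip.
#' @param illumination_gradient slope of the linear brightness ramp along
#'   the strip axis (intensity units per px).
#' @param noise_sd additive Gaussian noise standard deviation (intensity
#'   units).
#' @param pose list with `tx`, `ty` (px) and `rot_deg` applied to the card
#'   within the frame.
#' @param seed integer RNG seed for line-darkness sampling and noise.
#' @return object of class `card_spec`.
#' @export
card_spec <- function(panel, control_line_intensity = 0.8,
                      test_line_class = "very_negative",
                      alcohol_level = 0, illumination_gradient = 0,
                      noise_sd = 0.01,
                      pose = list(tx = 0, ty = 0, rot_deg = 0), seed = 1L) {
  if (!inherits(panel, "panel_config")) panel <- panel_config(panel)
  n_line <- sum(panel$strips != "ALC")
  control_line_intensity <- rep_len(control_line_intensity, n_line)
  test_line_class <- rep_len(test_line_class, n_line)
  if (any(control_line_intensity < 0 | control_line_intensity > 1)) {
    stop("control_line_intensity must lie in [0, 1]", call. = FALSE)
  }
  if (!all(test_line_class %in% testline_classes())) {
    stop("unknown test-line class", call. = FALSE)
  }
  if (alcohol_level < 0 || alcohol_level > 1) {
    stop("alcohol_level must lie in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(panel = panel,
                 control_line_intensity = control_line_intensity,
                 test_line_class = test_line_class,
                 alcohol_level = alcohol_level,
                 illumination_gradient = illumination_gradient,
                 noise_sd = noise_sd, pose = pose, seed = as.integer(seed)),
            class = "card_spec")
}

# Pose homography: rotation about the card center followed by translation,
# mapping zero-pose frame coordinates to posed-frame coordinates.
pose_homography <- function(pose, geom) {
  th <- pose$rot_deg * pi / 180
  cx <- (geom$card["x0"] + geom$card["x1"]) / 2
  cy <- (geom$card["y0"] + geom$card["y1"]) / 2
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  T1 <- matrix(c(1, 0, -cx, 0, 1, -cy, 0, 0, 1), 3, 3, byrow = TRUE)
  T2 <- matrix(c(1, 0, cx + pose$tx, 0, 1, cy + pose$ty, 0, 0, 1),
               3, 3, byrow = TRUE)
  T2 %*% R %*% T1
}

#' Render a synthetic card image with ground truth
#'
#' Renders the strips of `spec` onto the shared base card of `template`
#' (same fiducials and labels), adds control/test lines at class-consistent
#' darkness and the optional blue alcohol pad, applies the illumination
#' ramp, the pose homography and additive noise.
#'
#' @param spec a [card_spec()].
#' @param template the list returned by [generate_template_image()] for the
#'   same panel; carries the strip quadrilateral and fiducial layout.
#' @return list with `image` (RGB array) and `truth`, a list holding
#'   per-strip expected results, line positions and label boxes in the
#'   zero-pose card frame, the applied 3x3 pose homography, and the
#'   sampled line darkness values.
#' @export
generate_card_image <- function(spec, template) {
  stopifnot(inherits(spec, "card_spec"))
  if (!identical(spec$panel$strips, template$panel$strips)) {
    stop("card panel does not match template panel", call. = FALSE)
  }
  geom <- template$geometry
  H <- pose_homography(spec$pose, geom)
  corners <- rbind(c(geom$card["x0"], geom$card["y0"]),
                   c(geom$card["x1"], geom$card["y0"]),
                   c(geom$card["x1"], geom$card["y1"]),
                   c(geom$card["x0"], geom$card["y1"]))
  posed <- apply_homography(H, corners)
  if (any(posed[, 1] < 1 | posed[, 1] > geom$frame_w |
          posed[, 2] < 1 | posed[, 2] > geom$frame_h)) {
    stop("generation error: pose pushes the card outside the frame",
         call. = FALSE)
  }
  img <- render_base_card(spec$panel, template$seed)
  lay <- strip_layout(geom, length(spec$panel$strips))
  q <- geom$quad
  label_y0 <- unname(q["y0"]) + geom$label_top
  label_y1 <- label_y0 + geom$label_h
  white <- geom$card_white

  truth <- list(strips = list(), homography = H)
  darkness <- with_seed(spec$seed, {
    vapply(seq_along(spec$test_line_class), function(j) {
      iv <- testline_darkness_interval(spec$test_line_class[j], core = TRUE)
      stats::runif(1, iv[1], iv[2])
    }, numeric(1))
  })
  li <- 0L
  for (s in seq_along(spec$panel$strips)) {
    id <- spec$panel$strips[s]
    x0 <- lay$center[s] - lay$width[s] / 2
    x1 <- lay$center[s] + lay$width[s] / 2
    entry <- list(strip_id = id,
                  label_box = c(x = x0, y = label_y0,
                                w = lay$width[s], h = geom$label_h))
    if (id == "ALC") {
      mixv <- spec$alcohol_level
      col <- (1 - mixv) * rep(white, 3L) + mixv * geom$pad_blue
      img <- draw_rect(img, x0 + 2, q["y0"] + geom$pad_y0,
                       x1 - 2, q["y0"] + geom$pad_y1, col)
      entry$expected <- if (mixv >= 0.1) "positive" else "negative"
      entry$alcohol_level <- mixv
    } else {
      li <- li + 1L
      cint <- spec$control_line_intensity[li]
      tdark <- darkness[li]
      cy <- q["y0"] + geom$control_y
      ty <- q["y0"] + geom$test_y
      line_col <- function(d) (1 - d) * rep(white, 3L) + d * geom$line_base
      if (cint > 0) {
        img <- draw_rect(img, x0 + 2, cy - geom$line_h %/% 2,
                         x1 - 2, cy + geom$line_h %/% 2, line_col(cint))
      }
      if (tdark > 0) {
        img <- draw_rect(img, x0 + 2, ty - geom$line_h %/% 2,
                         x1 - 2, ty + geom$line_h %/% 2, line_col(tdark))
      }
      cls <- spec$test_line_class[li]
      entry$expected <- if (cint == 0) "invalid"
        else if (cls %in% c("very_positive", "positive")) "positive"
        else if (cls == "doubtful") "undetermined"
        else "negative"
      entry$control_intensity <- cint
      entry$test_class <- cls
      entry$test_darkness <- tdark
      entry$control_line_y <- as.numeric(cy)
      entry$test_line_y <- as.numeric(ty)
    }
    truth$strips[[id]] <- entry
  }

  # illumination ramp along the strip (vertical) axis, centered on the quad
  ramp <- spec$illumination_gradient *
    (seq_len(geom$frame_h) - (q["y0"] + q["y1"]) / 2)
  for (k in 1:3) img[, , k] <- img[, , k] + ramp

  if (spec$pose$tx != 0 || spec$pose$ty != 0 || spec$pose$rot_deg != 0) {
    # warp: output pixel p gets the zero-pose image at H^{-1}(p)
    img <- warp_homography(img, solve(H), geom$frame_w, geom$frame_h,
                           fill = geom$bg_gray)
  }
  if (spec$noise_sd > 0) {
    img <- with_seed(spec$seed + 1L, {
      img + array(stats::rnorm(length(img), sd = spec$noise_sd), dim = dim(img))
    })
  }
  list(image = clamp(img, 0, 1), truth = truth)
}

#' Draw a random card specification
#'
#' Convenience sampler for simulation suites: unambiguous test-line classes
#' (the `doubtful` band is excluded), control lines present, moderate
#' illumination gradient and pose.
#'
#' @param panel a [panel_config()] or character vector.
#' @param seed integer seed.
#' @param rot_range rotation range (deg) for the sampled pose.
#' @param invalid_rate probability that a strip is rendered without its
#'   control line.
#' @return a [card_spec()].
#' @export
random_card_spec <- function(panel, seed, rot_range = 5, invalid_rate = 0) {
  if (!inherits(panel, "panel_config")) panel <- panel_config(panel)
  n_line <- sum(panel$strips != "ALC")
  with_seed(seed, {
    classes <- sample(c("very_positive", "positive", "negative", "very_negative"),
                      n_line, replace = TRUE)
    cint <- stats::runif(n_line, 0.5, 0.95)
    cint[stats::runif(n_line) < invalid_rate] <- 0
    card_spec(panel,
              control_line_intensity = cint,
              test_line_class = classes,
              alcohol_level = if (panel$alcohol_present)
                sample(c(stats::runif(1, 0, 0.02), stats::runif(1, 0.3, 0.9)), 1)
                else 0,
              illumination_gradient = stats::runif(1, -2e-4, 2e-4),
              noise_sd = 0.01,
              pose = list(tx = stats::runif(1, -15, 15),
                          ty = stats::runif(1, -15, 15),
                          rot_deg = stats::runif(1, -rot_range, rot_range)),
              seed = seed)
  })
}
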