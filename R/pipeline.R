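# End-to-end orchestration: captured image -> registration -> label
# segmentation -> per-strip histogram preprocessing -> classification ->
# per-strip and per-test outcomes, plus a batch mode with a repeatability
# summary. Every early exit sets a machine-readable failure flag.

#' Default pipeline configuration
#'
#' One list with a section per stage; every tunable default of the reader
#' lives here and can be overridden (or loaded from YAML with
#' [load_config()]).
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    registration = list(ransac_threshold_px = 3, max_iters = 2000L,
                        min_inliers = 10L, seed = 1L),
    segmentation = list(combine = "union", closing_size = 3L,
                        column_min_fraction = 0.10, area_ratio = 0.5),
    histogram = list(baseline_iters = 500L, baseline_seed = 1L,
                     alcohol_baseline = FALSE),
    classifier = list(threshold = 0.5),
    pipeline = list(doubtful_policy = "undetermined")
  )
}

#' Load / save a pipeline configuration as YAML
#'
#' Values present in the file override [default_config()]; everything else
#' keeps its default.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
load_config <- function(path) {
  cfg <- default_config()
  user <- yaml::read_yaml(path)
  for (sec in names(user)) {
    for (key in names(user[[sec]])) cfg[[sec]][[key]] <- user[[sec]][[key]]
  }
  cfg
}

#' @rdname load_config
#' @param config configuration list to write.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# Map a test-line class to the reported outcome. Faint lines count as
# lines: the two negative-side classes are negative, the two
# positive-side classes positive; the doubtful band follows the policy.
testline_to_result <- function(class, policy = "undetermined") {
  switch(class,
    very_positive = , positive = "positive",
    negative = , very_negative = "negative",
    doubtful = policy,
    undetermined = "undetermined",
    stop("unknown test-line class: ", class, call. = FALSE))
}

#' Read one lateral-flow test card image
#'
#' Runs the full chain. Per non-alcohol strip: an invalid control makes
#' the strip invalid regardless of the test line; an undetermined
#' classifier output makes it undetermined (undetermined dominates a
#' determined test line); otherwise the test-line class decides. The
#' alcohol strip reports its classifier label directly.
#'
#' @param image RGB array, or path to a PNG file.
#' @param template a `template_model` from [build_template()] (or path to
#'   its JSON file).
#' @param panel a [panel_config()].
#' @param models named list of `mlp_classifier` objects: `control` and
#'   `testline` (always), `alcohol` when the panel has an ALC strip.
#' @param config configuration list, see [default_config()].
#' @return object of class `test_result`: fields `image_id`, `panel`,
#'   `ok`, `failure` (NA, `"registration"` or `"segmentation"`), `strips`
#'   (list of per-strip results with provenance), `timestamp`.
#' @export
read_test <- function(image, template, panel, models,
                      config = default_config()) {
  image_id <- if (is.character(image)) basename(image) else "in-memory"
  if (is.character(image)) image <- read_image(image)
  if (is.character(template)) template <- load_template(template)
  stopifnot(inherits(panel, "panel_config"))
  needed <- c("control", "testline", if (panel$alcohol_present) "alcohol")
  missing <- setdiff(needed, names(models))
  if (length(missing) > 0L) {
    stop("missing classifier model(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  result <- list(image_id = image_id, panel = panel$strips, ok = FALSE,
                 failure = NA_character_, strips = list(),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  class(result) <- "test_result"

  reg <- tryCatch(
    locate_strip_region(image, template,
                        config$registration$ransac_threshold_px,
                        config$registration$max_iters,
                        config$registration$min_inliers,
                        config$registration$seed),
    error = function(e) e)
  if (inherits(reg, "error")) {
    result$failure <- "registration"
    result$message <- conditionMessage(reg)
    return(result)
  }
  roi <- reg$roi
  result$registration <- list(inliers = reg$homography$inlier_count,
                              matches = reg$homography$match_count)

  seg <- tryCatch({
    mask <- threshold_strips(roi, panel$alcohol_present,
                             config$segmentation$combine,
                             config$segmentation$closing_size)
    mask <- column_filter(mask, config$segmentation$column_min_fraction)
    extract_label_regions(mask, panel, config$segmentation$area_ratio)
  }, error = function(e) e)
  if (inherits(seg, "error")) {
    result$failure <- "segmentation"
    result$message <- conditionMessage(seg)
    return(result)
  }

  roi_size <- c(nrow_any(roi), ncol_any(roi))
  for (region in seg) {
    id <- region$strip_id
    win <- histogram_window(region, roi_size, panel$width_factor,
                            panel$gap_factor, panel$length_factor)
    wimg <- roi[win["y"]:(win["y"] + win["h"] - 1),
                win["x"]:(win["x"] + win["w"] - 1), , drop = FALSE]
    strip <- list(strip_id = id, window = win)
    if (id == "ALC") {
      h <- preprocess_strip(wimg, alcohol = TRUE, strip_id = id)
      det <- classify_histogram(matrix(h$values, 1L), models$alcohol,
                                detail = TRUE)
      strip$alcohol_class <- det$label
      strip$final_result <- det$label
      strip$scores <- list(alcohol = det$score)
    } else {
      h <- preprocess_strip(wimg, alcohol = FALSE, strip_id = id,
                            seed = config$histogram$baseline_seed)
      cdet <- classify_histogram(matrix(h$values[1:31], 1L), models$control,
                                 detail = TRUE)
      tdet <- classify_histogram(matrix(h$values[32:62], 1L), models$testline,
                                 detail = TRUE)
      strip$control_status <- switch(cdet$label, valid = "valid",
                                     invalid = "invalid", "undetermined")
      strip$testline_class <- tdet$label
      strip$final_result <- if (strip$control_status == "invalid") {
        "invalid"
      } else if (strip$control_status == "undetermined") {
        "undetermined"
      } else {
        testline_to_result(tdet$label, config$pipeline$doubtful_policy)
      }
      strip$scores <- list(control = cdet$score, testline = tdet$score)
    }
    strip$histogram <- h$values
    result$strips[[id]] <- strip
  }
  result$ok <- TRUE
  result
}

#' @export
print.test_result <- function(x, ...) {
  cat("<test_result> ", x$image_id, ": ",
      if (!x$ok) paste0("FAILED (", x$failure, ")") else "ok", "\n", sep = "")
  for (s in x$strips) {
    cat(sprintf("  %-4s -> %s\n", s$strip_id, s$final_result))
  }
  invisible(x)
}

#' Write a test result as JSON
#'
#' @param result a `test_result`.
#' @param path output file.
#' @export
write_test_result <- function(result, path) {
  jsonlite::write_json(unclass(result), path, digits = NA, auto_unbox = TRUE,
                       force = TRUE)
  invisible(path)
}

#' Read a directory of card images
#'
#' Processes every PNG in `dir` with a shared template/panel/models.
#' Unreadable or unprocessable files are logged, skipped and counted.
#' Repeated captures of one physical card are recognized by stripping a
#' trailing `_rep<N>` from the file name; the summary reports, per card
#' and strip, the modal result and its frequency across repeats.
#'
#' @inheritParams read_test
#' @param dir directory of PNG images.
#' @return list with `results` (per readable image), `skipped` (count),
#'   `summary` (data.frame card_id, strip_id, modal_result, repeats,
#'   agreement).
#' @export
read_batch <- function(dir, template, panel, models,
                       config = default_config()) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (is.character(template)) template <- load_template(template)
  results <- list(); skipped <- 0L
  for (f in files) {
    r <- tryCatch(read_test(f, template, panel, models, config),
                  error = function(e) e)
    if (inherits(r, "error")) {
      warning("skipping unreadable file ", basename(f), ": ",
              conditionMessage(r), call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    results[[basename(f)]] <- r
  }
  rows <- list()
  for (nm in names(results)) {
    r <- results[[nm]]
    card <- sub("_rep[0-9]+$", "", sub("\\.png$", "", nm))
    for (s in r$strips) {
      rows[[length(rows) + 1L]] <- data.frame(card_id = card,
                                              strip_id = s$strip_id,
                                              result = s$final_result)
    }
  }
  summary <- if (length(rows) > 0L) {
    tab <- do.call(rbind, rows)
    agg <- lapply(split(tab, list(tab$card_id, tab$strip_id), drop = TRUE),
                  function(d) {
                    tt <- sort(table(d$result), decreasing = TRUE)
                    data.frame(card_id = d$card_id[1], strip_id = d$strip_id[1],
                               modal_result = names(tt)[1],
                               repeats = nrow(d),
                               agreement = as.numeric(tt[1]) / nrow(d))
                  })
    out <- do.call(rbind, agg)
    rownames(out) <- NULL
    out
  } else {
    data.frame(card_id = character(0), strip_id = character(0),
               modal_result = character(0), repeats = integer(0),
               agreement = numeric(0))
  }
  list(results = results, skipped = skipped, summary = summary)
}
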