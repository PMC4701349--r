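# Shared fixtures, built lazily and cached for the whole test run. The
# expensive pieces (template feature extraction, classifier training) are
# computed once and reused across test files.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_panel4 <- function() fixture("panel4", function() {
  panel_config(c("AMP", "KET", "COC", "MET"))
})

fx_panel_alc <- function() fixture("panel_alc", function() {
  panel_config(c("OPI", "THC", "ALC"))
})

fx_template4 <- function() fixture("template4", function() {
  generate_template_image(fx_panel4(), seed = 7)
})

fx_template_alc <- function() fixture("template_alc", function() {
  generate_template_image(fx_panel_alc(), seed = 7)
})

fx_template_model4 <- function() fixture("template_model4", function() {
  t <- fx_template4()
  build_template(t$image, t$strip_quad)
})

fx_template_model_alc <- function() fixture("template_model_alc", function() {
  t <- fx_template_alc()
  build_template(t$image, t$strip_quad)
})

fx_models <- function() fixture("models", function() {
  list(
    control = train_classifier(
      generate_histogram_dataset("control", 2358, seed = 42),
      "control", seed = 1)$model,
    testline = train_classifier(
      generate_histogram_dataset("testline", 1955, seed = 42),
      "testline", seed = 1)$model,
    alcohol = train_classifier(
      generate_histogram_dataset("alcohol", 338, seed = 42),
      "alcohol", seed = 1)$model
  )
})

# crop the rectified strip region straight out of a zero-pose render,
# bypassing registration (for segmentation/histogram tests)
crop_roi <- function(image, template) {
  q <- template$strip_quad
  image[q[1, 2]:q[3, 2], q[1, 1]:q[2, 1], , drop = FALSE]
}

# a flat-gray degenerate image
blank_image <- function(h = 120, w = 160, value = 1) {
  array(value, dim = c(h, w, 3))
}
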