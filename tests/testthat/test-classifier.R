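# The normalization/mapping/forward/reverse-mapping/thresholding chain,
# the trainer's bookkeeping, and the evaluation report.

# a hand-built two-class toy model working directly on 2-bin inputs
toy_model <- function(weights, biases, thresholds = c(0.5, 0.5),
                      labels = c("a", "b")) {
  structure(list(kind = "toy", input_dim = nrow(weights[[1]]),
                 layer_sizes = c(vapply(weights, ncol, integer(1))),
                 norm_stats = list(mean = rep(0, nrow(weights[[1]])),
                                   sd = rep(1, nrow(weights[[1]]))),
                 map_bounds = list(min = rep(-1, nrow(weights[[1]])),
                                   max = rep(1, nrow(weights[[1]]))),
                 reverse_bounds = list(min = rep(0, length(labels)),
                                       max = rep(1, length(labels))),
                 thresholds = thresholds, labels = labels,
                 input_bins = seq_len(nrow(weights[[1]])),
                 weights = weights, biases = biases),
            class = "mlp_classifier")
}

test_that("normalization and mapping hit their closed-form endpoints", {
  ns <- list(mean = c(1, 2), sd = c(1, 2))
  expect_equal(normalize_input(c(1, 2), ns), c(0, 0))
  expect_equal(normalize_input(c(1, 4), list(mean = c(1, 0), sd = c(1, 2))),
               c(0, 2))

  mb <- list(min = c(-2, 0), max = c(2, 4))
  expect_equal(map_input(c(-2, 0), mb), c(-1, -1))
  expect_equal(map_input(c(2, 4), mb), c(1, 1))
  expect_equal(map_input(c(0, 2), mb), c(0, 0))
  expect_error(map_input(c(0, 0), list(min = c(0, 0), max = c(0, 1))),
               "degenerate")

  rb <- list(min = c(0, 0), max = c(1, 1))
  expect_equal(reverse_map(c(-1, -1), rb), c(0, 0))
  expect_equal(reverse_map(c(1, 1), rb), c(1, 1))
  expect_equal(reverse_map(0, list(min = 0, max = 1)), 0.5)

  # normalized training table: per-bin mean 0, sd 1
  set.seed(7)
  x <- matrix(rnorm(200 * 10, mean = 3, sd = 2), 200, 10)
  ns2 <- list(mean = colMeans(x), sd = apply(x, 2, sd))
  xn <- normalize_input(x, ns2)
  expect_lt(max(abs(colMeans(xn))), 1e-9)
  expect_lt(max(abs(apply(xn, 2, sd) - 1)), 1e-9)
})

test_that("the tansig forward pass matches hand computation", {
  w0 <- list(matrix(0, 3, 2)); b0 <- list(c(0, 0))
  expect_equal(mlp_forward(c(1, 2, 3), w0, b0), matrix(0, 1, 2))

  w1 <- list(matrix(1, 1, 1)); b1 <- list(0)
  expect_equal(mlp_forward(0.5, w1, b1)[1, 1], tanh(0.5), tolerance = 1e-12)
  expect_equal(tanh(0.5), 0.462117, tolerance = 1e-6)

  # 2 -> 2 -> 1 network traced by hand
  W1 <- matrix(c(0.5, -0.3, 0.2, 0.8), 2, 2)   # columns = hidden neurons
  b1v <- c(0.1, -0.2)
  W2 <- matrix(c(1.5, -0.7), 2, 1)
  b2v <- 0.05
  x <- c(0.4, -0.6)
  h1 <- tanh(0.5 * 0.4 + (-0.3) * (-0.6) + 0.1)
  h2 <- tanh(0.2 * 0.4 + 0.8 * (-0.6) - 0.2)
  y <- tanh(1.5 * h1 - 0.7 * h2 + 0.05)
  got <- mlp_forward(x, list(W1, W2), list(b1v, b2v))
  expect_equal(got[1, 1], y, tolerance = 1e-12)

  expect_error(mlp_forward(c(1, 2), list(W1[1, , drop = FALSE]), list(b1v)),
               "input length")
})

test_that("classification applies the confidence threshold and tie-breaks", {
  # one linear-ish layer steering two outputs apart
  m <- toy_model(list(matrix(c(5, -5, -5, 5), 2, 2)), list(c(0, 0)),
                 thresholds = c(0.9, 0.9))
  expect_equal(classify_histogram(c(1, -1), m), "a")
  expect_equal(classify_histogram(c(-1, 1), m), "b")
  # below every threshold: undetermined
  expect_equal(classify_histogram(c(0.05, 0), m), "undetermined")
  # thresholds at +Inf reject everything
  m_inf <- toy_model(list(matrix(c(5, -5, -5, 5), 2, 2)), list(c(0, 0)),
                     thresholds = c(Inf, Inf))
  expect_equal(classify_histogram(c(1, -1), m_inf), "undetermined")
  # exact tie: lowest class index wins
  m_tie <- toy_model(list(matrix(0, 2, 2)), list(c(5, 5)),
                     thresholds = c(0.5, 0.5))
  expect_equal(classify_histogram(c(0.3, 0.4), m_tie), "a")

  # the emitted label's score is never below its threshold
  set.seed(8)
  for (i in 1:50) {
    W <- matrix(rnorm(4), 2, 2)
    mm <- toy_model(list(W), list(rnorm(2)), thresholds = runif(2, 0.3, 0.95))
    det <- classify_histogram(matrix(rnorm(20), 10, 2), mm, detail = TRUE)
    lab <- det$label != "undetermined"
    if (any(lab)) {
      k <- match(det$candidate[lab], mm$labels)
      expect_true(all(det$score[lab] >= mm$thresholds[k]))
    }
  }
})

test_that("training is seeded, bounded by the training split, and structured", {
  ds <- generate_histogram_dataset("alcohol", 120,
                                   class_mix = c(positive = 0.5,
                                                 negative = 0.5), seed = 3)
  f1 <- train_classifier(ds, "alcohol", trainer = list(epochs = 200L), seed = 9)
  f2 <- train_classifier(ds, "alcohol", trainer = list(epochs = 200L), seed = 9)
  expect_identical(f1$model$weights, f2$model$weights)
  expect_identical(lapply(f1$reports, `[[`, "success"),
                   lapply(f2$reports, `[[`, "success"))

  m <- f1$model
  expect_equal(m$input_dim, 62L)
  expect_equal(m$layer_sizes, c(5L, 2L))
  expect_true(all(m$norm_stats$sd > 0))
  expect_true(all(m$map_bounds$max > m$map_bounds$min))

  # normalization/mapping bounds derive from the training split only:
  # recomputing them from the training rows reproduces the model's, and
  # the mapped training split attains both endpoints
  x <- as.matrix(ds[, sprintf("bin_%03d", 1:62)])
  x_tr <- x[f1$split$train, ]
  expect_equal(m$norm_stats$mean, colMeans(x_tr))
  expect_equal(m$norm_stats$sd, pmax(apply(x_tr, 2, sd), 1e-9))
  xn <- normalize_input(x_tr, m$norm_stats)
  xm <- map_input(xn, m$map_bounds)
  expect_equal(unname(apply(xm, 2, min)), rep(-1, 62))
  expect_equal(unname(apply(xm, 2, max)), rep(1, 62))
  # one-hot targets across the training split span [0, 1] per output
  expect_equal(m$reverse_bounds$min, c(0, 0))
  expect_equal(m$reverse_bounds$max, c(1, 1))

  expect_error(train_classifier(ds[1:3, ], "alcohol", seed = 1), "data error")
})

test_that("network structures follow the per-kind specification", {
  dsc <- generate_histogram_dataset("control", 150, seed = 4)
  mc <- train_classifier(dsc, "control", trainer = list(epochs = 150L),
                         seed = 1)$model
  expect_equal(mc$input_dim, 31L)
  expect_equal(mc$layer_sizes, c(1L, 2L))
  expect_equal(dim(mc$weights[[1]]), c(31L, 1L))

  dst <- generate_histogram_dataset("testline", 150, seed = 4)
  mt <- train_classifier(dst, "testline", trainer = list(epochs = 150L),
                         seed = 1)$model
  expect_equal(mt$input_dim, 31L)
  expect_equal(mt$layer_sizes, c(7L, 7L, 5L))
  expect_equal(dim(mt$weights[[2]]), c(7L, 7L))
  expect_equal(dim(mt$weights[[3]]), c(7L, 5L))
})

test_that("evaluation reports match a manual tally", {
  m <- toy_model(list(matrix(c(5, -5, -5, 5), 2, 2)), list(c(0, 0)),
                 thresholds = c(0.9, 0.9))
  x <- rbind(c(1, -1), c(1, -1), c(-1, 1), c(0.02, 0), c(-1, 1))
  labels <- c("a", "a", "b", "a", "a")
  rep5 <- evaluate_classifier(m, x, labels, split = "test")
  # manual: rows 1,2 -> a (correct); 3 -> b (correct); 4 -> undetermined;
  # 5 -> b (wrong). success = 3/5
  expect_equal(rep5$success, 60)
  expect_equal(unname(rep5$confusion["a", "a"]), 2)
  expect_equal(unname(rep5$confusion["a", "b"]), 1)
  expect_equal(unname(rep5$confusion["a", "undetermined"]), 1)
  expect_equal(unname(rep5$confusion["b", "b"]), 1)
  expect_equal(sum(rep5$confusion), 5)
  # row sums equal per-class counts
  expect_equal(unname(rowSums(rep5$confusion)), c(4, 1))

  expect_error(evaluate_classifier(m, x, c("a", "a", "c", "a", "a")),
               "unknown label")
})

test_that("classifier models round-trip through JSON", {
  ds <- generate_histogram_dataset("alcohol", 60,
                                   class_mix = c(positive = 0.5,
                                                 negative = 0.5), seed = 5)
  m <- train_classifier(ds, "alcohol", trainer = list(epochs = 100L),
                        seed = 2)$model
  path <- withr::local_tempfile(fileext = ".json")
  save_classifier(m, path)
  m2 <- load_classifier(path)
  expect_equal(m2$weights, m$weights)
  expect_equal(m2$biases, m$biases)
  expect_equal(m2$norm_stats$mean, unname(m$norm_stats$mean))
  expect_equal(m2$labels, m$labels)
  x <- as.matrix(ds[, sprintf("bin_%03d", 1:62)])
  expect_identical(classify_histogram(x, m2), classify_histogram(x, m))
})
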