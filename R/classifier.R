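# The three tansig multilayer-perceptron classifiers and their shared
# processing chain: per-bin z-score normalization against training
# statistics, affine mapping of each bin onto [-1, 1] by its training
# range, layered tanh network evaluation, reverse mapping of outputs onto
# the training-target [0, 1] scale, and a confidence threshold with an
# "undetermined" reject option.

classifier_kinds <- function() c("alcohol", "control", "testline")

# Fixed network structures (input dim, hidden sizes, output dim) and class
# labels per classifier kind.
classifier_structure <- function(kind) {
  switch(kind,
    alcohol = list(input_dim = 62L, hidden = 5L,
                   labels = c("positive", "negative")),
    control = list(input_dim = 31L, hidden = 1L,
                   labels = c("valid", "invalid")),
    testline = list(input_dim = 31L, hidden = c(7L, 7L),
                    labels = testline_classes()),
    stop("unknown classifier kind: ", kind, call. = FALSE)
  )
}

#' Per-bin z-score normalization against training statistics
#'
#' @param x numeric vector (one histogram) or matrix (rows = histograms).
#' @param norm_stats list with `mean` and `sd` vectors computed on the
#'   training split.
#' @return normalized vector/matrix.
#' @export
normalize_input <- function(x, norm_stats) {
  if (is.matrix(x)) {
    sweep(sweep(x, 2, norm_stats$mean), 2, norm_stats$sd, `/`)
  } else {
    (x - norm_stats$mean) / norm_stats$sd
  }
}

#' Affine mapping of normalized bins onto the training [-1, 1] range
#'
#' Sends the training minimum of each bin to -1 and its maximum to +1;
#' inputs outside the training range may exceed `[-1, 1]` (no clipping).
#'
#' @param x_normalized vector or matrix of normalized bins.
#' @param map_bounds list with `min` and `max` vectors from the training
#'   split.
#' @return mapped vector/matrix.
#' @export
map_input <- function(x_normalized, map_bounds) {
  rng <- map_bounds$max - map_bounds$min
  if (any(rng <= 0)) stop("degenerate mapping bounds (min >= max)", call. = FALSE)
  if (is.matrix(x_normalized)) {
    sweep(sweep(x_normalized, 2, map_bounds$min), 2, rng, `/`) * 2 - 1
  } else {
    2 * (x_normalized - map_bounds$min) / rng - 1
  }
}

#' Evaluate a tansig multilayer perceptron
#'
#' Every neuron, hidden and output alike, applies the hyperbolic-tangent
#' sigmoid to its weighted input sum plus bias, so all activations lie in
#' (-1, 1).
#'
#' @param x_mapped input vector or matrix (rows = samples).
#' @param weights list of weight matrices (inputs x neurons per layer).
#' @param biases list of bias vectors per layer.
#' @return output activation matrix (samples x output neurons).
#' @export
mlp_forward <- function(x_mapped, weights, biases) {
  a <- if (is.matrix(x_mapped)) x_mapped else matrix(x_mapped, nrow = 1L)
  if (ncol(a) != nrow(weights[[1]])) {
    stop("input length does not match network input dimension", call. = FALSE)
  }
  for (l in seq_along(weights)) {
    a <- tanh(sweep(a %*% weights[[l]], 2, biases[[l]], `+`))
  }
  a
}

#' Reverse mapping of network outputs onto the training-target scale
#'
#' The inverse of the [-1, 1] mapping, using per-output bounds of the raw
#' training targets: -1 maps to `min`, +1 to `max`.
#'
#' @param y_nn network output vector or matrix.
#' @param reverse_bounds list with `min` and `max` per output.
#' @return reverse-mapped vector/matrix.
#' @export
reverse_map <- function(y_nn, reverse_bounds) {
  rng <- reverse_bounds$max - reverse_bounds$min
  if (is.matrix(y_nn)) {
    sweep(sweep((y_nn + 1) / 2, 2, rng, `*`), 2, reverse_bounds$min, `+`)
  } else {
    (y_nn + 1) / 2 * rng + reverse_bounds$min
  }
}

#' Classify preprocessed histograms with a reject option
#'
#' Runs the full chain (normalize, map, forward pass, reverse map); the
#' candidate class is the argmax of the reverse-mapped outputs (ties break
#' toward the lowest class index) and its label is returned only when the
#' candidate score reaches that class's confidence threshold — otherwise
#' `"undetermined"`.
#'
#' @param h_x numeric vector of the preprocessed histogram (or matrix,
#'   rows = histograms), already cut to the model's input bins.
#' @param model an `mlp_classifier` from [train_classifier()].
#' @param detail if `TRUE` return a data.frame with the candidate scores.
#' @return character vector of labels (or the detail data.frame).
#' @export
classify_histogram <- function(h_x, model, detail = FALSE) {
  x <- if (is.matrix(h_x)) h_x else matrix(h_x, nrow = 1L)
  if (ncol(x) != model$input_dim) {
    stop("histogram length ", ncol(x), " does not match model input dim ",
         model$input_dim, call. = FALSE)
  }
  y <- mlp_forward(map_input(normalize_input(x, model$norm_stats),
                             model$map_bounds),
                   model$weights, model$biases)
  yr <- reverse_map(y, model$reverse_bounds)
  k <- apply(yr, 1, which.max)          # which.max: lowest index on ties
  score <- yr[cbind(seq_len(nrow(yr)), k)]
  label <- ifelse(score >= model$thresholds[k], model$labels[k], "undetermined")
  if (!detail) return(label)
  data.frame(label = label, candidate = model$labels[k], score = score)
}

# ---- training ---------------------------------------------------------------

# iRprop- full-batch training of a tansig MLP on +/-1 targets (squared
# error plus a small L2 penalty). Sign-based individual step sizes make
# the trainer insensitive to gradient scale and deterministic for a fixed
# initialization. The weight decay keeps weights off bins that carry no
# class signal (the z-score normalization amplifies signal-free bins to
# unit scale, so without a penalty the network can lock onto their noise).
rprop_train <- function(x, target, hidden, epochs = 600L,
                        eta_plus = 1.2, eta_minus = 0.5,
                        step0 = 0.05, step_min = 1e-9, step_max = 5,
                        weight_decay = 3e-4,
                        validate = NULL, patience = 15L, check_every = 10L) {
  dimnames(x) <- NULL; dimnames(target) <- NULL
  sizes <- c(ncol(x), hidden, ncol(target))
  n_layer <- length(sizes) - 1L
  weights <- vector("list", n_layer); biases <- vector("list", n_layer)
  for (l in seq_len(n_layer)) {
    r <- 1 / sqrt(sizes[l])
    weights[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -r, r),
                           sizes[l], sizes[l + 1L])
    biases[[l]] <- stats::runif(sizes[l + 1L], -r, r)
  }
  stepW <- lapply(weights, function(w) array(step0, dim(w)))
  stepB <- lapply(biases, function(b) rep(step0, length(b)))
  prevW <- lapply(weights, function(w) array(0, dim(w)))
  prevB <- lapply(biases, function(b) rep(0, length(b)))
  n <- nrow(x)
  best <- list(score = c(-Inf, -Inf), weights = weights, biases = biases,
               epoch = 0L)
  stale <- 0L
  for (ep in seq_len(epochs)) {
    acts <- vector("list", n_layer + 1L)
    acts[[1]] <- x
    for (l in seq_len(n_layer)) {
      acts[[l + 1L]] <- tanh(sweep(acts[[l]] %*% weights[[l]], 2,
                                   biases[[l]], `+`))
    }
    delta <- (acts[[n_layer + 1L]] - target) * (1 - acts[[n_layer + 1L]]^2)
    for (l in rev(seq_len(n_layer))) {
      gW <- crossprod(acts[[l]], delta) / n + weight_decay * weights[[l]]
      gB <- colMeans(delta)
      if (l > 1L) {
        delta <- (delta %*% t(weights[[l]])) * (1 - acts[[l]]^2)
      }
      sW <- sign(gW) * sign(prevW[[l]])
      stepW[[l]] <- clamp(stepW[[l]] * ifelse(sW > 0, eta_plus,
                                              ifelse(sW < 0, eta_minus, 1)),
                          step_min, step_max)
      gW[sW < 0] <- 0   # iRprop-: forget the gradient after a sign flip
      weights[[l]] <- weights[[l]] - sign(gW) * stepW[[l]]
      prevW[[l]] <- gW
      sB <- sign(gB) * sign(prevB[[l]])
      stepB[[l]] <- clamp(stepB[[l]] * ifelse(sB > 0, eta_plus,
                                              ifelse(sB < 0, eta_minus, 1)),
                          step_min, step_max)
      gB[sB < 0] <- 0
      biases[[l]] <- biases[[l]] - sign(gB) * stepB[[l]]
      prevB[[l]] <- gB
    }
    if (!is.null(validate) && ep %% check_every == 0L) {
      sc <- validate(weights, biases)   # c(success, secondary margin score)
      if (sc[1] > best$score[1]) {
        best <- list(score = sc, weights = weights, biases = biases, epoch = ep)
        stale <- 0L
      } else {
        # equal success with a better margin still refreshes the kept model,
        # but only strict success gains reset the patience counter
        if (sc[1] == best$score[1] && sc[2] > best$score[2]) {
          best <- list(score = sc, weights = weights, biases = biases,
                       epoch = ep)
        }
        stale <- stale + 1L
        if (stale >= patience) break
      }
    }
  }
  if (is.null(validate)) {
    list(weights = weights, biases = biases, epochs_run = epochs,
         score = c(NA_real_, NA_real_))
  } else {
    list(weights = best$weights, biases = best$biases, epochs_run = best$epoch,
         score = best$score)
  }
}

# Stratified split of labels into train/validation/test index sets.
stratified_split <- function(labels, ratios = c(0.70, 0.15, 0.15)) {
  stopifnot(abs(sum(ratios) - 1) < 1e-8)
  idx <- list(train = integer(0), validation = integer(0), test = integer(0))
  for (cl in unique(labels)) {
    pool <- sample(which(labels == cl))
    n <- length(pool)
    n_tr <- round(ratios[1] * n)
    n_va <- round(ratios[2] * n)
    n_tr <- max(1L, min(n_tr, n - 1L))
    n_va <- max(0L, min(n_va, n - n_tr - 1L))
    idx$train <- c(idx$train, pool[seq_len(n_tr)])
    idx$validation <- c(idx$validation, pool[n_tr + seq_len(n_va)])
    idx$test <- c(idx$test, pool[(n_tr + n_va + 1L):n])
  }
  idx
}

# Cut the 62 dataset bins down to the model's input: control lines use
# bins 1-31, test lines bins 32-62, the alcohol model all 62.
input_bins <- function(kind) {
  switch(kind, alcohol = 1:62, control = 1:31, testline = 32:62)
}

# Kind-specific defaults. A small weight decay (1e-4) keeps every
# network off noise in the signal-free bins, which per-bin z-scoring
# amplifies to unit scale; the five-class test-line net additionally
# needs longer training than the binary ones to sharpen the boundaries
# between its deliberately overlapping classes. The default reject
# threshold sits at the midpoint of the
# reverse-mapped [0, 1] scale for every kind: the candidate must be at
# least halfway to its +1 target, so rejection marks genuine ambiguity
# rather than imperfect saturation. Stricter per-class cuts remain the
# user's dial for trading false positives against false negatives.
default_trainer <- function(kind) {
  switch(kind,
    testline = list(epochs = 4000L, weight_decay = 1e-4, patience = 40L),
    list(epochs = 3000L, weight_decay = 1e-4, patience = 30L))
}

default_threshold <- function(kind) {
  0.5
}

#' Train a lateral-histogram classifier
#'
#' Stratified seeded 70/15/15 split; normalization statistics, mapping
#' bounds and reverse-mapping bounds are computed on the training split
#' only; one-per-class targets (raw 0/1, mapped to -1/+1 for the tanh
#' network); full-batch iRprop- with early stopping on validation success.
#'
#' @param dataset data.frame with columns `bin_001` ... `bin_062` and
#'   `label` (see [generate_histogram_dataset()]).
#' @param kind `"alcohol"`, `"control"` or `"testline"`; fixes the network
#'   structure (62-5-2, 31-1-2, 31-7-7-5) and the input bins.
#' @param split_ratios training/validation/test proportions.
#' @param threshold confidence threshold on the reverse-mapped `[0, 1]`
#'   scale, recycled per class; `NULL` selects the default 0.5 (the
#'   candidate output must be at least halfway to its target).
#' @param trainer named list of optimizer settings overriding the
#'   kind-specific `rprop` defaults (`epochs`, `weight_decay`, `step0`,
#'   `patience`, `check_every`, ...).
#' @param seed integer seed for the split and weight initialization.
#' @return list with `model` (class `mlp_classifier`) and `reports` (list
#'   of [evaluate_classifier()] reports for the three splits).
#' @export
train_classifier <- function(dataset, kind = classifier_kinds(),
                             split_ratios = c(0.70, 0.15, 0.15),
                             threshold = NULL, trainer = list(), seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(threshold)) threshold <- default_threshold(kind)
  tr_defaults <- default_trainer(kind)
  trainer <- utils::modifyList(tr_defaults, trainer)
  st <- classifier_structure(kind)
  bins <- input_bins(kind)
  bin_cols <- sprintf("bin_%03d", 1:62)
  if (!all(c(bin_cols, "label") %in% names(dataset))) {
    stop("dataset must have columns bin_001..bin_062 and label", call. = FALSE)
  }
  labels <- as.character(dataset$label)
  if (!all(labels %in% st$labels)) {
    stop("data error: labels outside ", paste(st$labels, collapse = "/"),
         call. = FALSE)
  }
  if (any(table(factor(labels, levels = st$labels)) < 2L)) {
    stop("data error: every class needs at least 2 samples", call. = FALSE)
  }
  x_all <- as.matrix(dataset[, bin_cols])[, bins, drop = FALSE]

  with_seed(seed, {
    split <- stratified_split(labels, split_ratios)
    x_tr <- x_all[split$train, , drop = FALSE]
    y_lab <- lapply(split, function(ix) labels[ix])

    norm_stats <- list(mean = colMeans(x_tr),
                       sd = pmax(apply(x_tr, 2, stats::sd), 1e-9))
    xn_tr <- normalize_input(x_tr, norm_stats)
    map_bounds <- list(min = apply(xn_tr, 2, min), max = apply(xn_tr, 2, max))
    rng <- map_bounds$max - map_bounds$min
    if (any(rng <= 0)) stop("model-fit error: constant input bin", call. = FALSE)

    onehot <- function(lv) {
      t(vapply(lv, function(l) as.numeric(st$labels == l),
               numeric(length(st$labels))))
    }
    reverse_bounds <- list(min = apply(onehot(y_lab$train), 2, min),
                           max = apply(onehot(y_lab$train), 2, max))
    rrng <- reverse_bounds$max - reverse_bounds$min
    if (any(rrng <= 0)) stop("model-fit error: class absent from training split",
                             call. = FALSE)
    target_tr <- onehot(y_lab$train) * 2 - 1
    xm_tr <- map_input(xn_tr, map_bounds)
    thresholds <- rep_len(threshold, length(st$labels))

    proto <- list(kind = kind, input_dim = length(bins),
                  layer_sizes = c(st$hidden, length(st$labels)),
                  norm_stats = norm_stats, map_bounds = map_bounds,
                  reverse_bounds = reverse_bounds, thresholds = thresholds,
                  labels = st$labels, input_bins = bins, seed = seed)
    xm_va <- map_input(normalize_input(x_all[split$validation, , drop = FALSE],
                                       norm_stats), map_bounds)
    target_va <- onehot(y_lab$validation) * 2 - 1
    validate <- function(weights, biases) {
      yv <- mlp_forward(xm_va, weights, biases)
      yr <- reverse_map(yv, reverse_bounds)
      k <- apply(yr, 1, which.max)
      ok <- yr[cbind(seq_len(nrow(yr)), k)] >= thresholds[k] &
        st$labels[k] == y_lab$validation
      # success first; negative squared error breaks success ties toward
      # larger-margin fits
      c(mean(ok), -mean((yv - target_va)^2))
    }
    # several restarts from independent initializations guard against an
    # unlucky starting point; the restart with the best validation
    # success (margin as tie-break) is kept
    n_init <- trainer$n_init %||% 3L
    trainer$n_init <- NULL
    args <- c(list(x = xm_tr, target = target_tr, hidden = st$hidden,
                   validate = if (length(split$validation) > 0L) validate),
              trainer)
    fit <- NULL
    for (restart in seq_len(n_init)) {
      cand <- do.call(rprop_train, args)
      if (is.null(fit) || isTRUE(cand$score[1] > fit$score[1]) ||
          (isTRUE(cand$score[1] == fit$score[1]) &&
           isTRUE(cand$score[2] > fit$score[2]))) {
        fit <- cand
      }
    }
    model <- proto
    model$weights <- fit$weights
    model$biases <- fit$biases
    class(model) <- "mlp_classifier"

    reports <- lapply(c(train = "train", validation = "validation",
                        test = "test"), function(sp) {
      evaluate_classifier(model, x_all[split[[sp]], , drop = FALSE],
                          labels[split[[sp]]], split = sp)
    })
    list(model = model, reports = reports, split = split)
  })
}

#' @export
print.mlp_classifier <- function(x, ...) {
  cat("<mlp_classifier> kind=", x$kind, " structure ", x$input_dim, "-",
      paste(x$layer_sizes, collapse = "-"),
      " labels: ", paste(x$labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Evaluate a classifier on a labeled set
#'
#' The confusion matrix has one row per true class and the predicted
#' classes plus `"undetermined"` as columns; success is the exact-match
#' rate in percent, an undetermined prediction counting as incorrect.
#'
#' @param model an `mlp_classifier`.
#' @param x matrix of preprocessed histograms (rows), already on the 62-bin
#'   (or model-input) scale — 62-bin rows are cut to the model's bins.
#' @param labels true class labels.
#' @param split name recorded in the report.
#' @return list of class `evaluation_report` with `split`, `n`,
#'   `success` (%) and `confusion`.
#' @export
evaluate_classifier <- function(model, x, labels, split = "test") {
  labels <- as.character(labels)
  if (!all(labels %in% model$labels)) {
    stop("unknown label in evaluation set", call. = FALSE)
  }
  if (ncol(x) == 62L && model$input_dim != 62L) {
    x <- x[, model$input_bins, drop = FALSE]
  }
  pred <- classify_histogram(x, model)
  confusion <- table(true = factor(labels, levels = model$labels),
                     predicted = factor(pred, levels = c(model$labels,
                                                         "undetermined")))
  structure(list(split = split, n = length(labels),
                 success = 100 * mean(pred == labels),
                 confusion = confusion),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", x$split, " (", x$n, " samples): success ",
      sprintf("%.3f%%", x$success), "\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' Save / load a trained classifier as JSON
#'
#' @param model an `mlp_classifier`.
#' @param path JSON file path.
#' @return `save_classifier` returns `path` invisibly; `load_classifier`
#'   the restored model.
#' @export
save_classifier <- function(model, path) {
  obj <- unclass(model)
  obj$weights <- lapply(obj$weights, function(w) unclass(as.data.frame(w)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  obj$weights <- lapply(obj$weights, function(w) as.matrix(as.data.frame(w)))
  obj$weights <- lapply(obj$weights, function(w) {
    dimnames(w) <- NULL
    w
  })
  obj$biases <- lapply(obj$biases, as.numeric)
  obj$norm_stats <- lapply(obj$norm_stats, as.numeric)
  obj$map_bounds <- lapply(obj$map_bounds, as.numeric)
  obj$reverse_bounds <- lapply(obj$reverse_bounds, as.numeric)
  obj$input_bins <- as.integer(obj$input_bins)
  structure(obj, class = "mlp_classifier")
}
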