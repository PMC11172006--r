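# Model-agnostic classifier contract plus the built-in baseline.
#
# A classifier is a named entry in the registry exposing three capabilities:
#   fit(x, y, val, config)        -> fitted state
#   fine_tune(base, x, y, val, config) -> new state warm-started from `base`
#   predict_scores(state, x)      -> P(positive) in [0,1] per input
# `x` may be a list of M-mode images or a precomputed feature matrix from
# mmode_features(); states are plain serializable lists.

.classifiers <- new.env(parent = emptyenv())

#' Register a classifier implementation
#' @param name registry key (e.g. "baseline").
#' @param contract `list(fit =, fine_tune =, predict_scores =)`.
#' @export
register_classifier <- function(name, contract) {
  stopifnot(is.function(contract$fit), is.function(contract$fine_tune),
            is.function(contract$predict_scores))
  assign(name, contract, envir = .classifiers)
  invisible(name)
}

#' Look up a registered classifier by name
#' @param name registry key.
#' @export
get_classifier <- function(name) {
  if (!exists(name, envir = .classifiers, inherits = FALSE)) {
    stop_taaft("unknown classifier: ", name, class = "taaft_config_error")
  }
  get(name, envir = .classifiers)
}

#' Classifier configuration
#'
#' Fixed hyperparameters for the baseline (no hyperparameter search):
#' gradient-descent step size and iteration counts, L2 penalty, class
#' weighting, decision threshold and seed. Fine-tuning uses
#' `learning_rate * fine_tune_lr_scale` for `fine_tune_iter` iterations.
#'
#' @param classifier registry name.
#' @param learning_rate gradient-descent step size.
#' @param n_iter full-fit iterations.
#' @param fine_tune_lr_scale step-size reduction for warm-started fine-tuning.
#' @param fine_tune_iter fine-tuning iterations.
#' @param l2 ridge penalty on non-intercept coefficients.
#' @param class_weights "balanced" (inverse-frequency) or "none".
#' @param threshold decision threshold on the positive-class probability.
#' @param n_bins depth bins for the row-variance feature profile.
#' @param seed RNG seed recorded in the state (the baseline itself is
#'   deterministic).
#' @export
classifier_config <- function(classifier = "baseline",
                              learning_rate = 0.5, n_iter = 400,
                              fine_tune_lr_scale = 0.1, fine_tune_iter = 600,
                              l2 = 1e-3, class_weights = "balanced",
                              threshold = 0.5, n_bins = 16, seed = 0) {
  structure(list(classifier = classifier, learning_rate = learning_rate,
                 n_iter = as.integer(n_iter),
                 fine_tune_lr_scale = fine_tune_lr_scale,
                 fine_tune_iter = as.integer(fine_tune_iter),
                 l2 = l2, class_weights = class_weights,
                 threshold = threshold, n_bins = as.integer(n_bins),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Fixed M-mode feature extraction
#'
#' Each image is first min-max normalized, making the features invariant to
#' the acquisition gain of the source machine (per-image normalization is
#' standard practice before model input). The pleural band is then located
#' as the brightest row of the normalized image so the depth profile can be
#' anchored to the pleura rather than to absolute depth. Features per
#' M-mode image (rows = depth, cols = time): a pleura-anchored binned
#' per-row temporal standard-deviation profile of the sub-pleural region
#' (`n_bins` bins — high when sliding is present, near the noise floor when
#' absent), the mean row-sd of the supra-pleural region (static in both
#' classes), the mean absolute frame-to-frame intensity change, and global
#' intensity statistics (mean, sd, 10th/90th percentiles).
#'
#' @param images list of matrices, or a single matrix.
#' @param n_bins number of bins for the sub-pleural row profile.
#' @return numeric matrix (n x p) with rownames from the list names; carries
#'   class `mmode_features`.
#' @export
mmode_features <- function(images, n_bins = 16) {
  if (is.matrix(images)) images <- list(images)
  feat <- t(vapply(images, function(img) {
    rng <- range(img)
    if (rng[2] > rng[1]) img <- (img - rng[1]) / (rng[2] - rng[1])
    nr <- nrow(img)
    row_sd <- sqrt(rowSums((img - rowMeans(img))^2) / (ncol(img) - 1))
    band <- which.max(rowMeans(img))
    # sub-pleural region, skipping the band margin; keep at least n_bins rows
    lo <- min(band + round(0.03 * nr), nr - n_bins + 1)
    below_sd <- row_sd[max(1, lo):nr]
    bins <- split(below_sd, cut(seq_along(below_sd), n_bins, labels = FALSE))
    profile <- vapply(bins, mean, numeric(1))
    above_rows <- seq_len(max(1, band - round(0.03 * nr)))
    above_sd <- mean(row_sd[above_rows])
    tdiff <- mean(abs(img[, -1, drop = FALSE] - img[, -ncol(img), drop = FALSE]))
    q <- stats::quantile(img, c(0.1, 0.9), names = FALSE)
    c(profile, above_sd = above_sd, tdiff = tdiff, mean = mean(img),
      sd = stats::sd(img), q10 = q[1], q90 = q[2])
  }, numeric(n_bins + 6)))
  rownames(feat) <- names(images)
  colnames(feat) <- c(paste0("subpleural_sd_bin", seq_len(n_bins)),
                      "above_sd", "tdiff", "mean", "sd", "q10", "q90")
  structure(feat, class = c("mmode_features", class(feat)))
}

as_features <- function(x, config) {
  if (inherits(x, "mmode_features")) return(unclass(x))
  if (is.list(x) && !is.data.frame(x)) {
    return(unclass(mmode_features(x, n_bins = config$n_bins)))
  }
  if (is.matrix(x)) return(x)
  stop_taaft("cannot interpret training input as images or features",
             class = "taaft_validation_error")
}

# Weighted logistic gradient descent. Deterministic: zero (or warm-start)
# initialization, fixed iteration count, no stochastic minibatching.
logistic_gd <- function(X, y, w, beta, lr, n_iter, l2) {
  Xi <- cbind(intercept = 1, X)
  sw <- sum(w)
  for (it in seq_len(n_iter)) {
    p <- stats::plogis(drop(Xi %*% beta))
    grad <- drop(crossprod(Xi, w * (p - y))) / sw
    grad[-1] <- grad[-1] + l2 * beta[-1]
    beta <- beta - lr * grad
  }
  beta
}

class_weight_vector <- function(y, mode) {
  if (identical(mode, "balanced")) {
    n <- length(y)
    w <- ifelse(y == 1, n / (2 * sum(y == 1)), n / (2 * sum(y == 0)))
  } else {
    w <- rep(1, length(y))
  }
  w
}

baseline_train <- function(x, y, val, config, base = NULL) {
  X <- as_features(x, config)
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    stop_taaft("training data must contain both classes",
               class = "taaft_validation_error")
  }
  if (is.null(base)) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    scale[scale == 0] <- 1
    beta <- rep(0, ncol(X) + 1)
    lr <- config$learning_rate
    n_iter <- config$n_iter
  } else {
    # warm start: keep the base model's standardization so that fine-tuning
    # adapts the decision boundary, not the feature scale
    center <- base$center; scale <- base$scale
    beta <- base$beta
    lr <- config$learning_rate * config$fine_tune_lr_scale
    n_iter <- config$fine_tune_iter
  }
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  w <- class_weight_vector(y, config$class_weights)
  beta <- logistic_gd(Xs, y, w, beta, lr, n_iter, config$l2)
  state <- structure(list(
    classifier = "baseline", beta = beta, center = center, scale = scale,
    config = config, n_train = length(y),
    fine_tuned = !is.null(base)
  ), class = "lus_model")
  if (!is.null(val)) {
    state$val_loss <- baseline_val_loss(state, val)
  }
  state
}

baseline_val_loss <- function(state, val) {
  s <- baseline_predict(state, val$x)
  y <- as.integer(val$y)
  eps <- 1e-12
  -mean(y * log(s + eps) + (1 - y) * log(1 - s + eps))
}

baseline_predict <- function(state, x) {
  X <- as_features(x, state$config)
  Xs <- sweep(sweep(X, 2, state$center), 2, state$scale, "/")
  unname(stats::plogis(drop(cbind(1, Xs) %*% state$beta)))
}

register_classifier("baseline", list(
  fit = function(x, y, val = NULL, config = classifier_config()) {
    baseline_train(x, y, val, config)
  },
  fine_tune = function(base, x, y, val = NULL, config = base$config) {
    baseline_train(x, y, val, config, base = base)
  },
  predict_scores = baseline_predict
))

#' Fit the built-in baseline classifier
#'
#' A lightweight linear model over fixed M-mode features (see
#' [mmode_features()]), trained by deterministic weighted logistic gradient
#' descent with inverse-frequency class weights by default.
#'
#' @param x list of M-mode images, or an [mmode_features()] matrix.
#' @param y binary labels (1 = absent sliding).
#' @param val optional `list(x =, y =)` secondary validation set; its
#'   cross-entropy is recorded in the state for monitoring.
#' @param config a [classifier_config()].
#' @return a serializable `lus_model` state.
#' @export
baseline_fit <- function(x, y, val = NULL, config = classifier_config()) {
  baseline_train(x, y, val, config)
}

#' Fine-tune a baseline state on new data
#'
#' Warm-starts from the base state's parameters with a reduced step size;
#' the base state is never mutated. With `fine_tune_iter = 0` the returned
#' model scores identically to the base.
#'
#' @param base a fitted `lus_model`.
#' @inheritParams baseline_fit
#' @export
baseline_fine_tune <- function(base, x, y, val = NULL, config = base$config) {
  baseline_train(x, y, val, config, base = base)
}

#' Predict positive-class probabilities
#' @param state a fitted `lus_model`.
#' @param x images or feature matrix.
#' @return numeric vector in [0,1].
#' @export
predict_scores <- function(state, x) {
  get_classifier(state$classifier)$predict_scores(state, x)
}

#' Serialize / restore a model state
#' @param state a `lus_model`.
#' @param path file path.
#' @export
save_model <- function(state, path) {
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

#' @export
print.lus_model <- function(x, ...) {
  cat(sprintf("<lus_model: %s> %strained on %d examples\n", x$classifier,
              if (isTRUE(x$fine_tuned)) "fine-tuned, " else "", x$n_train))
  invisible(x)
}
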