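#' SVM configuration
#'
#' Settings for the radial-basis-function SVM used throughout the pipeline.
#' The defaults follow common practice for this classifier: cost `C = 1` and
#' kernel width `gamma = 1 / n_features` (resolved at fit time when `gamma`
#' is `NULL`).
#'
#' @param C Cost parameter, > 0.
#' @param gamma Kernel width, > 0, or `NULL` for `1 / n_features`.
#' @param probability Fit a Platt-style sigmoid mapping decision values to
#'   class probabilities (default `TRUE`).
#' @param platt_folds Internal stratified folds used to obtain out-of-fold
#'   decision values for the sigmoid fit; `0` fits the sigmoid on training
#'   decision values directly (cheaper, less calibrated).
#' @param seed Seed for the internal fold shuffling; training is
#'   deterministic given this seed and the input row order.
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(C = 1, gamma = NULL, probability = TRUE,
                       platt_folds = 3L, seed = 1L) {
  if (!is.numeric(C) || C <= 0) abort("C must be > 0")
  if (!is.null(gamma) && (!is.numeric(gamma) || gamma <= 0)) {
    abort("gamma must be > 0 (or NULL for 1/n_features)")
  }
  structure(
    list(C = C, gamma = gamma, probability = isTRUE(probability),
         platt_folds = as.integer(platt_folds), seed = as.integer(seed)),
    class = "svm_config"
  )
}

#' @export
print.svm_config <- function(x, ...) {
  cat(sprintf("<svm_config: C = %g, gamma = %s, probability = %s>\n",
              x$C, if (is.null(x$gamma)) "1/n_features" else format(x$gamma),
              x$probability))
  invisible(x)
}

MODEL_FORMAT_VERSION <- "mirstress-model-1"

as_xy <- function(data, features = NULL) {
  feats <- features %||% feature_names(data)
  missing <- setdiff(feats, names(data))
  if (length(missing) > 0L) {
    abort(sprintf("missing feature column(s): %s%s",
                  paste(head(missing, 10L), collapse = ", "),
                  if (length(missing) > 10L) ", ..." else ""))
  }
  x <- as.matrix(data[feats])
  if (!all(is.finite(x))) abort("non-finite feature values")
  y <- if ("label" %in% names(data)) label_factor(data$label) else NULL
  list(x = x, y = y, features = feats)
}

# Decision values oriented so that larger values favour the positive class.
# libsvm orders its decision column by first-seen training label, so the
# orientation is read off the column name and normalized here once.
oriented_decision_values <- function(fit, x) {
  pr <- predict(fit, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  f <- as.numeric(dv[, 1])
  if (first != "positive") f <- -f
  f
}

# Feature standardization fitted on the training set.  PseKNC features live
# on very different scales (most K = 5 frequencies are 0 or tiny), and with
# gamma = 1/n_features an unstandardized RBF kernel degenerates towards a
# constant; z-scaling restores a well-conditioned kernel.  Zero-variance
# columns get scale 1 so they map to a constant 0 and drop out of distances.
fit_scaler <- function(x) {
  center <- colMeans(x)
  s <- apply(x, 2L, sd)
  s[!is.finite(s) | s == 0] <- 1
  list(center = center, scale = s)
}

apply_scaler <- function(scaler, x) {
  scale(x, center = scaler$center, scale = scaler$scale)
}

# SVM + its feature scaler, the unit every fit in the package goes through.
fit_raw_svm <- function(x, y, C, gamma, kernel = "radial") {
  scaler <- fit_scaler(x)
  fit <- e1071::svm(x = apply_scaler(scaler, x), y = y, scale = FALSE,
                    kernel = kernel, cost = C, gamma = gamma,
                    probability = FALSE)
  fit$mirstress_scaler <- scaler
  fit
}

scaled_decision_values <- function(fit, x) {
  oriented_decision_values(fit, apply_scaler(fit$mirstress_scaler, x))
}

# Platt-style sigmoid calibration: P(positive | f) = plogis(a + b f), fitted
# by quasibinomial GLM on (out-of-fold) decision values with Platt's
# smoothed targets, which keeps the fit finite on separable data.
fit_platt <- function(f, y_pos) {
  n_pos <- sum(y_pos)
  n_neg <- sum(!y_pos)
  t_pos <- (n_pos + 1) / (n_pos + 2)
  t_neg <- 1 / (n_neg + 2)
  t <- ifelse(y_pos, t_pos, t_neg)
  co <- tryCatch(
    stats::coef(glm(t ~ f, family = quasibinomial())),
    error = function(e) NULL
  )
  if (is.null(co) || any(!is.finite(co))) co <- c(`(Intercept)` = 0, f = 1)
  unname(co)
}

stratified_fold_ids <- function(y_pos, k, seed) {
  fold <- integer(length(y_pos))
  with_seed_(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- which(y_pos == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Train an RBF-kernel SVM on an encoded dataset
#'
#' Fits a support vector machine with a radial-basis-function kernel
#' `K(x, x') = exp(-gamma * ||x - x'||^2)` via the standard libsvm solver,
#' plus a Platt-style sigmoid calibration of decision values to positive-class
#' probabilities based on seeded internal cross-validation. Features are
#' z-standardized internally on the training set (the center/scale vectors
#' are stored in the model and re-applied at prediction); without this the
#' RBF kernel at `gamma = 1/n_features` is nearly constant on raw PseKNC
#' features, whose entries are mostly tiny.
#'
#' @param data Labeled feature tibble from [encode_dataset()] (labels
#'   `positive`/`negative`, both classes present).
#' @param config [svm_config()].
#' @return An object of class `stress_svm` holding the fitted solver state
#'   (support coefficients and bias), the calibration coefficients, the
#'   ordered feature names, both configs' fingerprints and class counts.
#' @export
train_svm <- function(data, config = svm_config()) {
  xy <- as_xy(data)
  if (is.null(xy$y) || any(is.na(xy$y))) abort("training data must be fully labeled")
  tab <- table(xy$y)
  if (any(tab == 0L)) abort("training data must contain both classes")
  if (any(tab < 2L)) abort("need at least 2 examples per class")
  gamma <- config$gamma %||% (1 / ncol(xy$x))
  fit <- fit_raw_svm(xy$x, xy$y, config$C, gamma)
  platt <- NULL
  if (config$probability) {
    y_pos <- xy$y == "positive"
    k <- config$platt_folds
    if (k >= 2L && all(tab >= k)) {
      fold <- stratified_fold_ids(y_pos, k, config$seed)
      f_oof <- numeric(length(y_pos))
      for (fd in seq_len(k)) {
        tr <- fold != fd
        sub <- fit_raw_svm(xy$x[tr, , drop = FALSE], droplevels(xy$y[tr]),
                           config$C, gamma)
        f_oof[!tr] <- scaled_decision_values(sub, xy$x[!tr, , drop = FALSE])
      }
      platt <- fit_platt(f_oof, y_pos)
    } else {
      platt <- fit_platt(scaled_decision_values(fit, xy$x), y_pos)
    }
  }
  structure(
    list(
      format = MODEL_FORMAT_VERSION,
      fit = fit,
      platt = platt,
      features = xy$features,
      config = list(C = config$C, gamma = gamma,
                    probability = config$probability,
                    platt_folds = config$platt_folds, seed = config$seed),
      encoder_fingerprint = attr(data, "encoder_fingerprint"),
      pseknc_config = attr(data, "pseknc_config"),
      n_pos = unname(tab["positive"]),
      n_neg = unname(tab["negative"])
    ),
    class = "stress_svm"
  )
}

#' @export
print.stress_svm <- function(x, ...) {
  cat(sprintf("<stress_svm: %d features, C = %g, gamma = %.4g, trained on %d+ / %d->\n",
              length(x$features), x$config$C, x$config$gamma, x$n_pos, x$n_neg))
  invisible(x)
}

#' Predict stress responsiveness for encoded sequences
#'
#' @param object A trained [train_svm()] model.
#' @param newdata Feature tibble covering the model's feature columns. If it
#'   carries an encoder fingerprint differing from the model's, prediction is
#'   refused rather than silently re-encoded.
#' @param ... Unused.
#' @return Tibble with `id` (if present), `decision_value`,
#'   `prob_positive`, and `class` (`positive` iff `prob_positive >= 0.5`;
#'   the probability is a strictly monotone map of the decision value).
#' @export
predict.stress_svm <- function(object, newdata, ...) {
  fp_new <- attr(newdata, "encoder_fingerprint")
  if (!is.null(fp_new) && !is.null(object$encoder_fingerprint) &&
      !identical(fp_new, object$encoder_fingerprint)) {
    abort("encoder mismatch: newdata was encoded with a different PseKNC configuration than the model")
  }
  xy <- as_xy(newdata, features = object$features)
  f <- scaled_decision_values(object$fit, xy$x)
  if (!is.null(object$platt)) {
    p <- plogis(object$platt[1] + object$platt[2] * f)
  } else {
    p <- as.numeric(f > 0)
  }
  out <- tibble(
    decision_value = f,
    prob_positive = p,
    class = ifelse(p >= 0.5, "positive", "negative")
  )
  if ("id" %in% names(newdata)) out <- bind_cols(tibble(id = newdata$id), out)
  out
}

#' Grid search over the (gamma, C) log grid
#'
#' Evaluates every pair `(gamma, C) = (2^a, 2^b)` for exponents `a, b` on the
#' given grid (default -5..5 in steps of 2, i.e. 6 values per axis, 36
#' candidates) by stratified cross-validated pooled auROC of the decision
#' values, and returns the best configuration; ties are broken by smaller C,
#' then smaller gamma.
#'
#' @param data Labeled feature tibble (typically balanced).
#' @param exponents Integer exponent grid used for both axes.
#' @param folds CV folds for the internal evaluation.
#' @param seed Seed for the fold assignment (shared across candidates).
#' @param include_default Also evaluate the default pair
#'   `(gamma = 1/n_features, C = 1)` as a candidate.
#' @return The winning [svm_config()]; the full results table is attached as
#'   attribute `"grid"` (columns `gamma`, `C`, `auROC`).
#' @export
grid_search_svm <- function(data, exponents = seq(-5L, 5L, by = 2L),
                            folds = 5L, seed = 1L, include_default = FALSE) {
  if (length(exponents) == 0L) abort("empty exponent grid")
  xy <- as_xy(data)
  cand <- tidyr::expand_grid(gamma = 2^exponents, C = 2^exponents)
  if (include_default) {
    cand <- bind_rows(cand, tibble(gamma = 1 / ncol(xy$x), C = 1))
    cand <- distinct(cand)
  }
  y_pos <- xy$y == "positive"
  fold <- stratified_fold_ids(y_pos, folds, seed)
  score_candidate <- function(gamma, C) {
    f_oof <- numeric(length(y_pos))
    for (fd in sort(unique(fold))) {
      tr <- fold != fd
      sub <- fit_raw_svm(xy$x[tr, , drop = FALSE], droplevels(xy$y[tr]), C, gamma)
      f_oof[!tr] <- scaled_decision_values(sub, xy$x[!tr, , drop = FALSE])
    }
    auroc_trapezoid(y_pos, f_oof)
  }
  cand$auROC <- purrr::map2_dbl(cand$gamma, cand$C, score_candidate)
  ranked <- arrange(cand, dplyr::desc(.data$auROC), .data$C, .data$gamma)
  best <- ranked[1, ]
  out <- svm_config(C = best$C, gamma = best$gamma)
  attr(out, "grid") <- cand
  out
}

#' Save / load a trained model
#'
#' The artifact embeds a format-version string; loading refuses a mismatched
#' version rather than guessing.
#'
#' @param model A `stress_svm` object.
#' @param path File path.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "stress_svm"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "stress_svm") ||
      !identical(model$format, MODEL_FORMAT_VERSION)) {
    abort(sprintf("model file '%s' has an unsupported format (expected %s)",
                  path, MODEL_FORMAT_VERSION))
  }
  model
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the support-vector coefficients of a trained model
#'
#' One row per support vector: the signed Lagrange coefficient
#' `alpha_i * y_i` (bounded by C in absolute value) and the training-row
#' index. `sum(coefficient)` is 0 up to solver tolerance.
#'
#' @param x A `stress_svm` model.
#' @param ... Unused.
#' @return A tibble with columns `index`, `coefficient`.
#' @method tidy stress_svm
#' @export
tidy.stress_svm <- function(x, ...) {
  tibble(index = as.integer(x$fit$index),
         coefficient = as.numeric(x$fit$coefs))
}

#' One-row summary of a trained model
#'
#' @param x A `stress_svm` model.
#' @param ... Unused.
#' @return Tibble with feature count, kernel parameters, support-vector
#'   count, bias, calibration coefficients and class counts.
#' @method glance stress_svm
#' @export
glance.stress_svm <- function(x, ...) {
  tibble(
    n_features = length(x$features),
    C = x$config$C,
    gamma = x$config$gamma,
    n_support = nrow(x$fit$SV),
    bias = -x$fit$rho,
    platt_intercept = if (is.null(x$platt)) NA_real_ else x$platt[1],
    platt_slope = if (is.null(x$platt)) NA_real_ else x$platt[2],
    n_pos = x$n_pos,
    n_neg = x$n_neg
  )
}
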