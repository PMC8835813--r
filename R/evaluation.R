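#' @include utils.R
NULL

# ROC staircase over unique score thresholds (descending), ties grouped so
# tied blocks become diagonal segments under the trapezoid rule -- this makes
# the area equal the pairwise-concordance statistic with ties counted 1/2.
roc_points_ <- function(y_pos, score) {
  P <- sum(y_pos)
  N <- sum(!y_pos)
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  y <- y_pos[ord]
  last <- cumsum(rle(s)$lengths)  # index of last element of each tied block
  tp <- cumsum(y)[last]
  fp <- cumsum(!y)[last]
  tibble(threshold = c(Inf, s[last]),
         fpr = c(0, fp / N), tpr = c(0, tp / P),
         tp = c(0L, tp), fp = c(0L, fp))
}

auroc_trapezoid <- function(y_pos, score) {
  pts <- roc_points_(y_pos, score)
  100 * sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
}

# Precision-recall points at the same tied-block thresholds, and the
# step-interpolated area (right-continuous in recall): area accrues as
# precision-at-threshold times the recall increment, never by linear
# interpolation between PR points.
pr_points_ <- function(y_pos, score) {
  pts <- roc_points_(y_pos, score)[-1, ]  # drop the (0,0) anchor
  P <- sum(y_pos)
  tibble(threshold = pts$threshold,
         recall = pts$tp / P,
         precision = pts$tp / (pts$tp + pts$fp))
}

auprc_step <- function(y_pos, score) {
  pts <- pr_points_(y_pos, score)
  dr <- diff(c(0, pts$recall))
  100 * sum(dr * pts$precision, na.rm = TRUE)
}

#' Classification metrics from labels and probabilities
#'
#' Computes the confusion counts at a probability threshold plus the
#' seven-metric suite standard for this task: sensitivity
#' `Sen = TP/(TP+FN)`, specificity `Spe = TN/(TN+FP)`, balanced accuracy
#' `Acc = (Sen+Spe)/2`, precision `Pre = TP/(TP+FP)`, F-score
#' `F = 2TP/(2TP+FP+FN)`, and the areas under the ROC curve (trapezoid over
#' the tied-block staircase) and the precision-recall curve (step
#' interpolation). All seven are reported as percentages. `Acc` is the mean
#' of Sen and Spe, not raw accuracy, so it stays meaningful on imbalanced
#' test sets.
#'
#' @param truth Vector of `"positive"`/`"negative"` truth labels.
#' @param prob Positive-class probabilities (or any monotone score in
#'   `[0, 1]` for the curve metrics).
#' @param threshold Classification threshold on `prob` (default 0.5;
#'   predicted positive iff `prob >= threshold`).
#' @param curves Compute ROC/PR curves and their areas. With single-class
#'   truth the curve metrics are undefined and raise an error; set
#'   `curves = FALSE` to get the threshold metrics that remain defined.
#' @return An object of class `metrics_bundle`: confusion counts, a one-row
#'   metrics tibble, and (if `curves`) the ROC and PR point tables.
#' @export
#' @examples
#' m <- compute_metrics(c("positive", "negative", "positive", "negative"),
#'                      c(0.9, 0.8, 0.7, 0.6))
#' glance(m)
compute_metrics <- function(truth, prob, threshold = 0.5, curves = TRUE) {
  if (length(truth) != length(prob)) {
    abort("truth and prob must have equal length")
  }
  y_pos <- label_factor(truth) == "positive"
  pred_pos <- prob >= threshold
  TP <- sum(y_pos & pred_pos); FN <- sum(y_pos & !pred_pos)
  TN <- sum(!y_pos & !pred_pos); FP <- sum(!y_pos & pred_pos)
  rate <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  Sen <- rate(TP, TP + FN)
  Spe <- rate(TN, TN + FP)
  Acc <- if (is.na(Sen) || is.na(Spe)) NA_real_ else (Sen + Spe) / 2
  Pre <- rate(TP, TP + FP)
  F_score <- rate(2 * TP, 2 * TP + FP + FN)
  roc <- pr <- NULL
  auROC <- auPRC <- NA_real_
  if (curves) {
    if (sum(y_pos) == 0L || sum(!y_pos) == 0L) {
      abort("curve metrics (auROC/auPRC) need both classes in `truth`; use curves = FALSE for threshold metrics only")
    }
    roc <- roc_points_(y_pos, prob)[c("threshold", "fpr", "tpr")]
    pr <- pr_points_(y_pos, prob)
    auROC <- auroc_trapezoid(y_pos, prob)
    auPRC <- auprc_step(y_pos, prob)
  }
  structure(
    list(
      counts = c(TP = TP, TN = TN, FP = FP, FN = FN),
      metrics = tibble(Sen = Sen, Spe = Spe, Acc = Acc, Pre = Pre,
                       F_score = F_score, auROC = auROC, auPRC = auPRC),
      roc_points = roc,
      pr_points = pr,
      threshold = threshold
    ),
    class = "metrics_bundle"
  )
}

#' @export
print.metrics_bundle <- function(x, ...) {
  cat("<metrics_bundle>\n")
  cat(sprintf("  TP %d  TN %d  FP %d  FN %d (threshold %.2f)\n",
              x$counts["TP"], x$counts["TN"], x$counts["FP"], x$counts["FN"],
              x$threshold))
  print(round(x$metrics, 2))
  invisible(x)
}

#' @describeIn compute_metrics Long tibble of the seven metrics.
#' @param x A `metrics_bundle`.
#' @param ... Unused.
#' @method tidy metrics_bundle
#' @export
tidy.metrics_bundle <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @describeIn compute_metrics One-row tibble: counts then the seven metrics.
#' @method glance metrics_bundle
#' @export
glance.metrics_bundle <- function(x, ...) {
  bind_cols(as_tibble(as.list(x$counts)), x$metrics)
}

#' Balance a dataset by undersampling the majority class
#'
#' Keeps every minority-class row and draws a uniform random subset of the
#' majority class without replacement to match its size, so that e.g. a
#' 376-positive / 3823-negative pool yields 376 + 376 rows. Already balanced
#' input is returned unchanged. Deterministic given the seed.
#'
#' @param data Labeled feature tibble.
#' @param seed Integer seed for the draw.
#' @return Balanced tibble (minority rows first, in original order, then the
#'   sampled majority rows in original order); attributes are preserved.
#' @export
balance_dataset <- function(data, seed = 1L) {
  y <- label_factor(data$label)
  if (any(is.na(y))) abort("balance_dataset needs labels on every row")
  tab <- table(y)
  if (any(tab == 0L)) abort("both classes must be present to balance")
  if (tab["positive"] == tab["negative"]) return(data)
  minority <- names(tab)[which.min(tab)]
  keep_min <- which(y == minority)
  maj_idx <- which(y != minority)
  pick <- with_seed_(seed, sort(sample(maj_idx, size = min(tab))))
  out <- data[c(keep_min, pick), , drop = FALSE]
  for (a in c("encoder_fingerprint", "pseknc_config")) {
    attr(out, a) <- attr(data, a)
  }
  out
}

aggregate_cv <- function(predictions, fold_metrics, scheme, folds_map, seed, k) {
  pooled <- compute_metrics(predictions$truth, predictions$prob)
  if (scheme == "fivefold" && nrow(fold_metrics) > 0L) {
    # threshold metrics averaged over folds; curve areas from pooled scores
    for (m in c("Sen", "Spe", "Acc", "Pre", "F_score")) {
      pooled$metrics[[m]] <- mean(fold_metrics[[m]], na.rm = TRUE)
    }
  }
  structure(
    list(scheme = scheme, k = k, seed = seed,
         folds = folds_map,
         predictions = predictions,
         fold_metrics = fold_metrics,
         aggregate = pooled),
    class = "cv_result"
  )
}

#' Stratified k-fold cross-validation of the SVM pipeline
#'
#' Positives and negatives are each shuffled (seeded) and split into k
#' near-equal subsets; fold i unites the i-th subset of each class, so every
#' example is tested exactly once and the per-fold class ratio matches the
#' dataset within one example. Threshold metrics are averaged over folds;
#' auROC/auPRC are computed on the pooled held-out scores (well defined even
#' for tiny folds). As a degenerate convenience, `k = nrow(data)` puts one
#' example per fold, reproducing leave-one-out predictions.
#'
#' @param data Labeled feature tibble.
#' @param k Number of folds (default 5).
#' @param config [svm_config()] for the per-fold models.
#' @param seed Seed for the fold assignment.
#' @return An object of class `cv_result`: fold map, pooled held-out
#'   predictions, per-fold metrics and the aggregate [compute_metrics()]
#'   bundle.
#' @export
kfold_cv <- function(data, k = 5L, config = svm_config(), seed = 1L) {
  k <- as.integer(k)
  n <- nrow(data)
  if (k < 2L) abort("k must be >= 2")
  y <- label_factor(data$label)
  if (k == n) {
    fold <- seq_len(n)
  } else {
    tab <- table(y)
    if (any(tab < k)) {
      abort(sprintf("each class needs >= k examples (have %d positive, %d negative, k = %d)",
                    tab["positive"], tab["negative"], k))
    }
    fold <- stratified_fold_ids(y == "positive", k, seed)
  }
  ids <- if ("id" %in% names(data)) data$id else as.character(seq_len(n))
  preds <- vector("list", k)
  fold_metrics <- vector("list", k)
  for (fd in seq_len(k)) {
    tr <- fold != fd
    model <- train_svm(data[tr, , drop = FALSE], config)
    pr <- predict(model, data[!tr, , drop = FALSE])
    preds[[fd]] <- tibble(id = ids[!tr], fold = fd,
                          truth = as.character(y[!tr]),
                          prob = pr$prob_positive,
                          decision_value = pr$decision_value)
    if (k < n && length(unique(y[!tr])) == 2L) {
      fm <- compute_metrics(as.character(y[!tr]), pr$prob_positive)
      fold_metrics[[fd]] <- bind_cols(tibble(fold = fd), fm$metrics)
    }
  }
  aggregate_cv(
    predictions = bind_rows(preds),
    fold_metrics = bind_rows(fold_metrics),
    scheme = if (k == n) "loocv" else "fivefold",
    folds_map = tibble(id = ids, fold = fold),
    seed = seed, k = k
  )
}

#' Leave-one-out cross-validation
#'
#' Each observation in turn is held out and predicted by a model trained on
#' the rest; metrics are computed once on the n pooled held-out predictions.
#' There is no random partitioning, so the result is unique for a given
#' dataset.
#'
#' @param data Labeled feature tibble with `n >= 3` rows.
#' @param config [svm_config()].
#' @return A `cv_result` with scheme `"loocv"`.
#' @export
loocv <- function(data, config = svm_config()) {
  if (nrow(data) < 3L) abort("LOOCV needs at least 3 observations")
  kfold_cv(data, k = nrow(data), config = config)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %s (k = %d), %d held-out predictions>\n",
              x$scheme, x$k, nrow(x$predictions)))
  print(round(x$aggregate$metrics, 2))
  invisible(x)
}

#' Per-fold metrics of a cross-validation result
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Tibble of per-fold threshold and curve metrics (empty for LOOCV,
#'   whose metrics are only defined pooled).
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$fold_metrics

#' One-row aggregate metrics of a cross-validation result
#' @param x A `cv_result`.
#' @param ... Unused.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  bind_cols(tibble(scheme = x$scheme, k = x$k), x$aggregate$metrics)
}

#' Write a metrics report in the standard column order
#'
#' @param x A `metrics_bundle` or `cv_result`.
#' @param path Output TSV path.
#' @param digits Decimal places for the percentage columns (round-half-even).
#' @return `path`, invisibly.
#' @export
write_metrics <- function(x, path, digits = 2) {
  m <- if (inherits(x, "cv_result")) x$aggregate$metrics else x$metrics
  out <- as_tibble(lapply(m, round, digits = digits))
  names(out) <- c("Sen", "Spe", "Acc", "Pre", "F-score", "auROC", "auPRC")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
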