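#' Rank features by SVM recursive feature elimination
#'
#' Classic backward elimination: at each iteration a linear-kernel SVM is
#' fitted on the surviving features, the weight vector
#' `w = sum_i alpha_i y_i x_i` is computed from the support coefficients,
#' features are scored by `w^2`, and the `step` lowest-scoring features are
#' removed; the final ranking is the reverse of removal order (last removed =
#' most important). The weight vector is only defined for a linear kernel, so
#' ranking always uses one even though downstream classification uses the
#' RBF kernel. Ties in `w^2` are broken by original column order (stable
#' sort), making the ranking deterministic.
#'
#' @param data Labeled feature tibble.
#' @param step Features removed per iteration (default 1, the canonical
#'   procedure; larger steps trade fidelity for speed). Must be smaller than
#'   the initial feature count.
#' @param C Cost parameter of the per-iteration linear SVM.
#' @return An object of class `rfe_ranking`: a tibble `(rank, feature)` plus
#'   the per-iteration elimination log and each feature's `w^2` at removal.
#' @export
rfe_rank <- function(data, step = 1L, C = 1) {
  xy <- as_xy(data)
  if (is.null(xy$y) || any(is.na(xy$y))) abort("rfe_rank needs a fully labeled dataset")
  step <- as.integer(step)
  P <- length(xy$features)
  if (step < 1L) abort("step must be >= 1")
  if (step >= P) {
    abort(sprintf("step (%d) must be smaller than the feature count (%d); the first iteration would eliminate everything", step, P))
  }
  surviving <- xy$features
  position <- setNames(seq_along(surviving), surviving)  # tie-break order
  removed <- character(0)
  w2_at_removal <- numeric(0)
  elimination_log <- list()
  it <- 0L
  while (length(surviving) > 0L) {
    it <- it + 1L
    fit <- fit_raw_svm(xy$x[, surviving, drop = FALSE], xy$y, C = C,
                       gamma = 1 / length(surviving), kernel = "linear")
    w <- as.numeric(crossprod(fit$coefs, fit$SV))
    w2 <- setNames(w^2, surviving)
    ord <- order(w2, position[surviving])
    drop <- surviving[ord[seq_len(min(step, length(surviving)))]]
    elimination_log[[it]] <- drop
    removed <- c(removed, drop)
    w2_at_removal <- c(w2_at_removal, w2[drop])
    surviving <- setdiff(surviving, drop)
  }
  structure(
    list(
      ranking = tibble(rank = seq_len(P), feature = rev(removed)),
      elimination_log = elimination_log,
      w2_at_removal = setNames(w2_at_removal, removed)
    ),
    class = "rfe_ranking"
  )
}

#' @export
print.rfe_ranking <- function(x, ...) {
  cat(sprintf("<rfe_ranking: %d features in %d iterations; top: %s>\n",
              nrow(x$ranking), length(x$elimination_log),
              paste(head(x$ranking$feature, 3L), collapse = ", ")))
  invisible(x)
}

#' @describeIn rfe_rank The ranking as a tibble `(rank, feature, w2_at_removal)`.
#' @param x An `rfe_ranking`.
#' @param ... Unused.
#' @method tidy rfe_ranking
#' @export
tidy.rfe_ranking <- function(x, ...) {
  mutate(x$ranking, w2_at_removal = unname(x$w2_at_removal[.data$feature]))
}

#' Incremental feature-selection curve
#'
#' Walks down the RFE ranking adding `grid_step` features at a time (the
#' full set is always included as the last point), evaluates each prefix by
#' stratified k-fold cross-validated auROC/auPRC with an RBF SVM at default
#' parameters (`gamma = 1/subset size`, `C = 1`), and selects the subset size
#' maximizing auROC; ties are broken by higher auPRC, then smaller size.
#'
#' @param data Labeled feature tibble.
#' @param ranking An [rfe_rank()] result (or a character vector of feature
#'   names, best first).
#' @param grid_step Features added per curve point (default 10).
#' @param folds CV folds per point (default 5).
#' @param seed Seed shared by all CV runs on the curve.
#' @param config [svm_config()] evaluated at each subset size; its `gamma`
#'   is left `NULL` so each subset uses `1/size`.
#' @return An object of class `selection_curve` with the per-size curve and
#'   `chosen_size` / `chosen_features`.
#' @export
selection_curve <- function(data, ranking, grid_step = 10L, folds = 5L,
                            seed = 1L, config = svm_config()) {
  feats <- if (inherits(ranking, "rfe_ranking")) ranking$ranking$feature else ranking
  P <- length(feats)
  sizes <- unique(c(seq(grid_step, P, by = grid_step), P))
  meta <- setdiff(names(data), feature_names(data))
  curve <- purrr::map_dfr(sizes, function(m) {
    sub <- data[c(meta, feats[seq_len(m)])]
    for (a in c("encoder_fingerprint", "pseknc_config")) {
      attr(sub, a) <- attr(data, a)
    }
    cv <- kfold_cv(sub, k = folds, config = config, seed = seed)
    tibble(n_features = m,
           auROC = cv$aggregate$metrics$auROC,
           auPRC = cv$aggregate$metrics$auPRC)
  })
  best <- arrange(curve, dplyr::desc(.data$auROC), dplyr::desc(.data$auPRC),
                  .data$n_features)[1, ]
  structure(
    list(curve = curve,
         chosen_size = best$n_features,
         chosen_features = feats[seq_len(best$n_features)],
         grid_step = grid_step, folds = folds, seed = seed),
    class = "selection_curve"
  )
}

#' @export
print.selection_curve <- function(x, ...) {
  cat(sprintf("<selection_curve: %d sizes evaluated; chosen %d features (auROC %.2f)>\n",
              nrow(x$curve), x$chosen_size,
              x$curve$auROC[x$curve$n_features == x$chosen_size]))
  invisible(x)
}

#' @describeIn selection_curve The curve as a tibble
#'   `(n_features, auROC, auPRC, chosen)`.
#' @param x A `selection_curve`.
#' @param ... Unused.
#' @method tidy selection_curve
#' @export
tidy.selection_curve <- function(x, ...) {
  mutate(x$curve, chosen = .data$n_features == x$chosen_size)
}

#' Restrict a feature matrix to a selected feature set
#'
#' @param data Encoded feature tibble.
#' @param features Character vector of feature names to keep (e.g.
#'   `chosen_features` of a [selection_curve()]), kept in the given order.
#' @return The restricted tibble, metadata columns and attributes preserved.
#' @export
select_features <- function(data, features) {
  missing <- setdiff(features, names(data))
  if (length(missing) > 0L) {
    abort(sprintf("unknown feature(s): %s", paste(head(missing, 5L), collapse = ", ")))
  }
  meta <- setdiff(names(data), feature_names(data))
  out <- data[c(meta, features)]
  for (a in c("encoder_fingerprint", "pseknc_config")) {
    attr(out, a) <- attr(data, a)
  }
  out
}

#' Write / read a feature ranking
#'
#' TSV with columns `rank` and `feature`.
#'
#' @param ranking An `rfe_ranking` (or its [tidy()] tibble).
#' @param path File path.
#' @return `write_ranking()` returns `path` invisibly; `read_ranking()`
#'   returns a character vector of features, best first.
#' @export
write_ranking <- function(ranking, path) {
  tab <- if (inherits(ranking, "rfe_ranking")) ranking$ranking else ranking
  readr::write_tsv(tab[c("rank", "feature")], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  tab <- readr::read_tsv(path, col_types = "ic", progress = FALSE)
  tab$feature[order(tab$rank)]
}
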