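#' Configuration of an end-to-end training run
#'
#' Collects every knob of the clean -> encode -> balance -> select ->
#' grid-search -> train -> cross-validate pipeline, so a run is fully
#' reproducible from its resolved configuration snapshot.
#'
#' @param mode Dataset mode: `"miRNA"` (mature only), `"premiRNA"`
#'   (precursor only) or `"combined"` (paired, concatenated features).
#' @param positive,negative FASTA paths for the positive / negative class
#'   (mature sequences in `miRNA` and `combined` modes, precursors in
#'   `premiRNA` mode).
#' @param positive_precursor,negative_precursor Precursor FASTA paths,
#'   required in combined mode (paired to the mature files by record ID).
#' @param pseknc A [pseknc_config()].
#' @param svm An [svm_config()]; ignored when `grid_search` is `TRUE`.
#' @param grid_search Run [grid_search_svm()] to pick `(gamma, C)`.
#' @param reduce_redundancy Apply [reduce_redundancy()] after cleaning.
#' @param identity_threshold Identity threshold for redundancy reduction.
#' @param selection Run SVM-RFE + incremental curve to select features.
#' @param selection_fraction Fraction of the balanced data (stratified,
#'   seeded) used for ranking and the curve (default 0.5, so selection does
#'   not see the full training responses).
#' @param rfe_step Features removed per RFE iteration.
#' @param curve_step Features added per curve point.
#' @param cv_scheme `"fivefold"` or `"loocv"`.
#' @param cv_folds Folds for the fivefold scheme.
#' @param seed_balance,seed_folds,seed_selection Seeds for undersampling,
#'   fold assignment and the selection subsample.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("miRNA", "premiRNA", "combined"),
                       positive, negative,
                       positive_precursor = NULL, negative_precursor = NULL,
                       pseknc = pseknc_config(), svm = svm_config(),
                       grid_search = FALSE,
                       reduce_redundancy = FALSE, identity_threshold = 0.8,
                       selection = FALSE, selection_fraction = 0.5,
                       rfe_step = 1L, curve_step = 10L,
                       cv_scheme = c("fivefold", "loocv"), cv_folds = 5L,
                       seed_balance = 1L, seed_folds = 2L, seed_selection = 3L,
                       out_dir = NULL) {
  mode <- match.arg(mode)
  cv_scheme <- match.arg(cv_scheme)
  if (mode == "combined" &&
      (is.null(positive_precursor) || is.null(negative_precursor))) {
    abort("combined mode requires positive_precursor and negative_precursor FASTA paths")
  }
  structure(
    list(mode = mode, positive = positive, negative = negative,
         positive_precursor = positive_precursor,
         negative_precursor = negative_precursor,
         pseknc = pseknc, svm = svm, grid_search = isTRUE(grid_search),
         reduce_redundancy = isTRUE(reduce_redundancy),
         identity_threshold = identity_threshold,
         selection = isTRUE(selection),
         selection_fraction = selection_fraction,
         rfe_step = as.integer(rfe_step), curve_step = as.integer(curve_step),
         cv_scheme = cv_scheme, cv_folds = as.integer(cv_folds),
         seed_balance = as.integer(seed_balance),
         seed_folds = as.integer(seed_folds),
         seed_selection = as.integer(seed_selection),
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; the nested `pseknc:` and
#' `svm:` maps mirror [pseknc_config()] / [svm_config()] arguments.
#'
#' @param path YAML file.
#' @param ... Overrides applied on top of the file values.
#' @return A [run_config()].
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$pseknc)) vals$pseknc <- do.call(pseknc_config, vals$pseknc)
  if (!is.null(vals$svm)) vals$svm <- do.call(svm_config, vals$svm)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

config_snapshot <- function(config) {
  snap <- config[!vapply(config, is.null, logical(1))]
  snap$pseknc <- list(K_values = config$pseknc$K_values,
                      lambda = config$pseknc$lambda,
                      omega = config$pseknc$omega)
  snap$svm <- config$svm[c("C", "gamma", "probability", "platt_folds", "seed")]
  snap$svm <- snap$svm[!vapply(snap$svm, is.null, logical(1))]
  lapply(snap, function(v) if (is.numeric(v) || is.logical(v)) unname(v) else v)
}

run_stage <- function(state, name, expr) {
  t0 <- Sys.time()
  value <- tryCatch(expr, error = function(e) {
    for (f in state$written) if (file.exists(f)) unlink(f)
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  n <- if (is.data.frame(value)) nrow(value) else length(value)
  line <- sprintf("stage=%s n_out=%s", name, n)
  inform(sprintf("%s elapsed=%.2fs", line, elapsed))
  # persisted log omits wall-clock times so identical runs give identical files
  state$log <- c(state$log, line)
  value
}

load_class_records <- function(config, state) {
  role <- if (config$mode == "premiRNA") "precursor" else "mature"
  prep <- function(path, label, r) {
    rec <- clean_dataset(read_fasta(path, role = r, label = label))
    if (config$reduce_redundancy) {
      rec <- reduce_redundancy(rec, config$identity_threshold)
    }
    state$log <- c(state$log, paste0(label, "/", r, ": ", provenance(rec)))
    rec
  }
  pos <- prep(config$positive, "positive", role)
  neg <- prep(config$negative, "negative", role)
  if (config$mode == "combined") {
    pos_p <- prep(config$positive_precursor, "positive", "precursor")
    neg_p <- prep(config$negative_precursor, "negative", "precursor")
    bind_rows(pair_combined(pos, pos_p), pair_combined(neg, neg_p))
  } else {
    bind_rows(pos, neg)
  }
}

stratified_subsample <- function(data, fraction, seed) {
  y <- label_factor(data$label)
  idx <- with_seed_(seed, {
    unlist(lapply(levels(y), function(cls) {
      i <- which(y == cls)
      sort(sample(i, size = max(1L, round(fraction * length(i)))))
    }))
  })
  out <- data[sort(idx), , drop = FALSE]
  for (a in c("encoder_fingerprint", "pseknc_config")) {
    attr(out, a) <- attr(data, a)
  }
  out
}

#' Run the full training pipeline
#'
#' Executes clean -> encode -> balance -> (subsample + SVM-RFE + incremental
#' selection) -> (grid search) -> train -> cross-validate, logging each
#' stage, and optionally writes the model, ranking, selection curve, CV
#' report and a resolved-config snapshot to `config$out_dir`. Identical
#' configuration and seeds give identical artifacts and reports.
#'
#' @param config A [run_config()].
#' @return A list with elements `model`, `cv`, `ranking`, `curve`,
#'   `svm_config`, `data` (the balanced, possibly feature-restricted
#'   training tibble), `files` (written paths) and `log`.
#' @export
run_train <- function(config) {
  stopifnot(inherits(config, "run_config"))
  state <- new.env(parent = emptyenv())
  state$log <- character(0)
  state$written <- character(0)

  records <- run_stage(state, "clean", load_class_records(config, state))
  encoded <- run_stage(state, "encode", encode_dataset(records, config$pseknc))
  balanced <- run_stage(state, "balance",
                        balance_dataset(encoded, seed = config$seed_balance))

  ranking <- NULL
  curve <- NULL
  train_data <- balanced
  if (config$selection) {
    sel_data <- run_stage(state, "selection_subsample",
                          stratified_subsample(balanced,
                                               config$selection_fraction,
                                               config$seed_selection))
    ranking <- run_stage(state, "rfe_rank",
                         rfe_rank(sel_data, step = config$rfe_step))
    curve <- run_stage(state, "selection_curve",
                       selection_curve(sel_data, ranking,
                                       grid_step = config$curve_step,
                                       folds = config$cv_folds,
                                       seed = config$seed_folds))
    train_data <- run_stage(state, "select_features",
                            select_features(balanced, curve$chosen_features))
  }

  svm_cfg <- config$svm
  if (config$grid_search) {
    svm_cfg <- run_stage(state, "grid_search",
                         grid_search_svm(train_data, folds = config$cv_folds,
                                         seed = config$seed_folds))
  }

  model <- run_stage(state, "train", train_svm(train_data, svm_cfg))
  cv <- run_stage(state, "cross_validate", {
    if (config$cv_scheme == "loocv") {
      loocv(train_data, svm_cfg)
    } else {
      kfold_cv(train_data, k = config$cv_folds, config = svm_cfg,
               seed = config$seed_folds)
    }
  })

  files <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(name) {
      p <- file.path(config$out_dir, name)
      state$written <- c(state$written, p)
      p
    }
    files["model"] <- save_model(model, out("model.rds"))
    files["cv_metrics"] <- write_metrics(cv, out("cv_metrics.tsv"))
    readr::write_tsv(cv$predictions, out("cv_predictions.tsv"), progress = FALSE)
    files["cv_predictions"] <- file.path(config$out_dir, "cv_predictions.tsv")
    if (!is.null(ranking)) files["ranking"] <- write_ranking(ranking, out("ranking.tsv"))
    if (!is.null(curve)) {
      readr::write_tsv(tidy(curve), out("selection_curve.tsv"), progress = FALSE)
      files["curve"] <- file.path(config$out_dir, "selection_curve.tsv")
    }
    yaml::write_yaml(config_snapshot(config), out("config.yaml"))
    files["config"] <- file.path(config$out_dir, "config.yaml")
    writeLines(state$log, out("run.log"))
    files["log"] <- file.path(config$out_dir, "run.log")
  }

  list(model = model, cv = cv, ranking = ranking, curve = curve,
       svm_config = svm_cfg, data = train_data, files = files,
       log = state$log)
}

model_is_combined <- function(model) any(startsWith(model$features, "mat_"))

# Validate raw records against the model's encoder constraints; never drops
# silently -- failures come back with a reason.
split_encodable <- function(records, config) {
  min_len <- min_sequence_length(config)
  reason <- rep(NA_character_, nrow(records))
  bad_alpha <- grepl(sprintf("[^%s]", paste(RNA_BASES, collapse = "")), records$seq)
  reason[bad_alpha] <- "non-standard residues (outside A/U/G/C)"
  too_short <- !bad_alpha & nchar(records$seq) < min_len
  reason[too_short] <- sprintf("shorter than the minimum encodable length (%d nt)", min_len)
  list(ok = records[is.na(reason), , drop = FALSE],
       rejected = tibble(id = records$id[!is.na(reason)],
                         reason = reason[!is.na(reason)]))
}

#' Predict stress responsiveness for FASTA input
#'
#' Applies a trained model to new sequences end to end: read, normalize,
#' validate against the model's encoder constraints, encode with the model's
#' stored PseKNC configuration, restrict to the model's selected features
#' and predict. Sequences failing validation are reported with reasons,
#' never silently dropped.
#'
#' @param model A `stress_svm` model or a path to one ([load_model()]).
#' @param fasta Mature-sequence FASTA path (or the precursor FASTA in a
#'   precursor-mode model).
#' @param precursor_fasta Precursor FASTA, required by combined-mode models
#'   (paired to `fasta` by record ID).
#' @param out_dir If non-`NULL`, writes `predictions.tsv` and
#'   `rejected.tsv` there.
#' @return List with `predictions` (tibble `id`, `class`,
#'   `prob_positive`) and `rejected` (tibble `id`, `reason`).
#' @export
run_predict <- function(model, fasta, precursor_fasta = NULL, out_dir = NULL) {
  if (is.character(model)) model <- load_model(model)
  config <- model$pseknc_config %||% pseknc_config()
  combined <- model_is_combined(model)
  if (combined && is.null(precursor_fasta)) {
    abort("this model was trained on paired mature + precursor features; supply precursor_fasta")
  }
  if (!combined && !is.null(precursor_fasta)) {
    abort("this model was not trained in combined mode; drop precursor_fasta")
  }
  mature <- read_fasta(fasta, role = "mature")
  chk <- split_encodable(mature, config)
  rejected <- chk$rejected
  if (combined) {
    prec <- read_fasta(precursor_fasta, role = "precursor")
    chk_p <- split_encodable(prec, config)
    rejected <- bind_rows(rejected, chk_p$rejected)
    pairs <- pair_combined(chk$ok, chk_p$ok)
    encoded <- encode_dataset(pairs, config)
  } else {
    encoded <- encode_dataset(chk$ok, config)
  }
  pr <- predict(model, encoded)
  predictions <- select(pr, "id", "class", "prob_positive")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(predictions, file.path(out_dir, "predictions.tsv"),
                     progress = FALSE)
    readr::write_tsv(rejected, file.path(out_dir, "rejected.tsv"),
                     progress = FALSE)
  }
  list(predictions = predictions, rejected = rejected)
}

#' Evaluate a trained model on a labeled independent test set
#'
#' Predicts the test sequences with [run_predict()] and scores the
#' predictions with [compute_metrics()], reporting the independent-test
#' summary (class sizes, Sen, Spe, Acc) alongside the full bundle.
#'
#' @param model A `stress_svm` model or a path to one.
#' @param fasta,precursor_fasta As in [run_predict()].
#' @param labels Tibble (`id`, `label`) or a label TSV path; must cover
#'   every accepted test record.
#' @param out_dir If non-`NULL`, writes `test_metrics.tsv` there.
#' @return List with `summary` (one-row tibble `P`, `N`, `Sen`, `Spe`,
#'   `Acc`), `metrics` (the [compute_metrics()] bundle) and `predictions`.
#' @export
run_evaluate <- function(model, fasta, labels, precursor_fasta = NULL,
                         out_dir = NULL) {
  if (is.character(labels)) labels <- read_labels(labels)
  pred <- run_predict(model, fasta, precursor_fasta = precursor_fasta)
  joined <- left_join(pred$predictions, labels, by = "id")
  if (any(is.na(joined$label))) {
    abort(sprintf("no label for test record(s): %s",
                  paste(head(joined$id[is.na(joined$label)], 5L), collapse = ", ")))
  }
  bundle <- compute_metrics(joined$label, joined$prob_positive)
  summary <- tibble(
    P = sum(joined$label == "positive"),
    N = sum(joined$label == "negative"),
    Sen = bundle$metrics$Sen, Spe = bundle$metrics$Spe, Acc = bundle$metrics$Acc
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(mutate(summary, dplyr::across(c("Sen", "Spe", "Acc"),
                                                   ~ round(.x, 2))),
                     file.path(out_dir, "test_metrics.tsv"), progress = FALSE)
  }
  list(summary = summary, metrics = bundle, predictions = joined)
}
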