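test_that("metric formulas reproduce hand-computable confusion tables", {
  # counts realizing Sen 66.13 / Spe 64.53 at scale 10000 per class
  truth <- c(rep("positive", 10000), rep("negative", 10000))
  prob <- c(rep(0.9, 6613), rep(0.1, 3387), rep(0.9, 3547), rep(0.1, 6453))
  m <- glance(compute_metrics(truth, prob))
  expect_equal(m$TP, 6613)
  expect_equal(round(m$Sen, 2), 66.13)
  expect_equal(round(m$Spe, 2), 64.53)
  expect_equal(round(m$Acc, 2), 65.33)
  expect_equal(round(m$Pre, 2), 65.09)
  expect_equal(round(m$F_score, 2), 65.61)
})

test_that("perfect predictions score 100 on every metric", {
  truth <- rep(c("positive", "negative"), each = 5)
  prob <- rep(c(0.9, 0.1), each = 5)
  m <- glance(compute_metrics(truth, prob))
  expect_equal(unname(unlist(m[c("Sen", "Spe", "Acc", "Pre", "F_score",
                                 "auROC", "auPRC")])),
               rep(100, 7))
})

test_that("auROC equals the pairwise-concordance oracle, including ties", {
  truth <- c("positive", "negative", "positive", "negative")
  prob <- c(0.9, 0.8, 0.7, 0.6)
  m <- compute_metrics(truth, prob)
  expect_equal(m$metrics$auROC, 75)
  expect_equal(m$metrics$auROC, oracle_auroc_concordance(truth, prob))

  set.seed(801)
  for (i in 1:20) {
    n <- sample(6:25, 1)
    truth_i <- sample(c("positive", "negative"), n, replace = TRUE,
                      prob = c(0.5, 0.5))
    if (length(unique(truth_i)) < 2) truth_i[1:2] <- c("positive", "negative")
    # quantized scores force ties
    prob_i <- round(runif(n), 1)
    expect_equal(compute_metrics(truth_i, prob_i)$metrics$auROC,
                 oracle_auroc_concordance(truth_i, prob_i), tolerance = 1e-10)
  }
})

test_that("auROC and auPRC agree with pROC / precrec-style references", {
  skip_if_not_installed("pROC")
  set.seed(802)
  truth <- sample(c("positive", "negative"), 60, replace = TRUE)
  truth[1:2] <- c("positive", "negative")
  prob <- runif(60)
  m <- compute_metrics(truth, prob)
  ref <- suppressMessages(
    pROC::auc(pROC::roc(response = truth, predictor = prob,
                        levels = c("negative", "positive"), direction = "<")))
  expect_equal(m$metrics$auROC, 100 * as.numeric(ref), tolerance = 1e-10)
})

test_that("derived metric identities hold on random bundles", {
  set.seed(803)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    truth <- sample(c("positive", "negative"), n, replace = TRUE)
    truth[1:2] <- c("positive", "negative")
    prob <- runif(n)
    m <- glance(compute_metrics(truth, prob))
    expect_equal(m$Acc, (m$Sen + m$Spe) / 2, tolerance = 1e-12)
    if (!is.na(m$Pre) && (m$Pre + m$Sen) > 0) {
      expect_equal(m$F_score, 2 * m$Pre * m$Sen / (m$Pre + m$Sen),
                   tolerance = 1e-9)
    }
    expect_true(all(m[c("Sen", "Spe", "Acc", "auROC", "auPRC")] >= 0 &
                      m[c("Sen", "Spe", "Acc", "auROC", "auPRC")] <= 100,
                    na.rm = TRUE))
  }
})

test_that("label flip with complemented scores swaps Sen and Spe", {
  set.seed(804)
  truth <- sample(c("positive", "negative"), 30, replace = TRUE)
  truth[1:2] <- c("positive", "negative")
  prob <- runif(30)
  m1 <- glance(compute_metrics(truth, prob))
  flipped <- ifelse(truth == "positive", "negative", "positive")
  m2 <- glance(compute_metrics(flipped, 1 - prob, threshold = 0.5))
  # threshold asymmetry (>= vs <) can move exact-0.5 scores; avoid them above
  expect_equal(m2$Sen, m1$Spe, tolerance = 1e-9)
  expect_equal(m2$Spe, m1$Sen, tolerance = 1e-9)
})

test_that("single-class truth yields threshold metrics but refuses curves", {
  truth <- rep("positive", 4)
  prob <- c(0.9, 0.8, 0.3, 0.7)
  expect_error(compute_metrics(truth, prob), "both classes")
  m <- glance(compute_metrics(truth, prob, curves = FALSE))
  expect_equal(m$Sen, 75)
  expect_true(is.na(m$Spe))
  expect_true(is.na(m$auROC))
})

test_that("balance_dataset undersamples the majority class reproducibly", {
  set.seed(805)
  pool <- tibble::tibble(
    id = sprintf("s%04d", 1:(376 + 3823)),
    label = c(rep("positive", 376), rep("negative", 3823)),
    f1 = rnorm(4199), f2 = rnorm(4199)
  )
  bal <- balance_dataset(pool, seed = 42)
  expect_equal(nrow(bal), 752L)
  expect_equal(sum(bal$label == "positive"), 376L)
  expect_equal(sum(bal$label == "negative"), 376L)
  expect_equal(anyDuplicated(bal$id), 0L)
  # deterministic given seed
  expect_identical(balance_dataset(pool, seed = 42)$id, bal$id)
  expect_false(identical(balance_dataset(pool, seed = 43)$id, bal$id))
  # already balanced input is the identity
  expect_identical(balance_dataset(bal, seed = 1), bal)
  expect_error(balance_dataset(dplyr::filter(pool, label == "negative"), 1),
               "both classes")
})

test_that("stratified folds partition the data with balanced class ratios", {
  data <- toy_feature_data(n_per_class = 100, shift = 1, seed = 806)
  cv <- kfold_cv(data, k = 5, seed = 7)
  expect_equal(sort(cv$folds$id), sort(data$id))
  counts <- cv$folds |>
    dplyr::left_join(data[c("id", "label")], by = "id") |>
    dplyr::count(fold, label)
  expect_true(all(counts$n == 20))  # 100+100 split 5 ways: 20+20 per fold
  expect_equal(nrow(cv$predictions), 200L)
  expect_equal(anyDuplicated(cv$predictions$id), 0L)
  expect_error(kfold_cv(toy_feature_data(3, seed = 1), k = 5), ">= k")
})

test_that("k = n fold assignment reproduces LOOCV predictions", {
  data <- toy_feature_data(n_per_class = 6, shift = 2, seed = 807)
  lo <- loocv(data)
  kv <- kfold_cv(data, k = nrow(data))
  expect_equal(lo$scheme, "loocv")
  expect_equal(lo$predictions$prob, kv$predictions$prob)
  expect_equal(nrow(lo$predictions), nrow(data))
  # deterministic: no random partitioning at all
  expect_identical(glance(loocv(data)), glance(lo))
})

test_that("cross-validation separates a strongly shifted toy problem", {
  data <- toy_feature_data(n_per_class = 30, shift = 3, seed = 808)
  cv <- kfold_cv(data, k = 5, seed = 11)
  expect_gt(cv$aggregate$metrics$auROC, 95)
  # aggregate threshold metrics are fold means; curve areas are pooled
  expect_equal(cv$aggregate$metrics$Sen, mean(tidy(cv)$Sen))
  pooled <- compute_metrics(cv$predictions$truth, cv$predictions$prob)
  expect_equal(cv$aggregate$metrics$auROC, pooled$metrics$auROC)
})

test_that("metrics reports are written in the standard column order", {
  truth <- rep(c("positive", "negative"), each = 6)
  prob <- c(runif(6, 0.4, 1), runif(6, 0, 0.6))
  m <- compute_metrics(truth, prob)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metrics(m, path)
  hdr <- readLines(path, n = 1)
  expect_equal(hdr, "Sen\tSpe\tAcc\tPre\tF-score\tauROC\tauPRC")
})
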