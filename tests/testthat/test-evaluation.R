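lv <- hearing_loss_levels(clinical_only = TRUE)

test_that("stratified folds partition the data with balanced class counts", {
  labels <- rep(lv, each = 10)
  f <- stratified_folds(labels, k = 10, seed = 3)
  expect_equal(sort(unique(f$fold)), 1:10)
  # 40 samples, 4 classes x 10, k=10: every fold one of each class
  for (k in 1:10)
    expect_equal(sort(as.character(labels[f$fold == k])), sort(lv))
  # unbalanced: 657 of a class over 10 folds -> per-fold counts in {65, 66}
  big <- c(rep("conductive", 657), rep("sensorineural", 7777))
  fb <- stratified_folds(big, k = 10, seed = 1)
  per_fold <- table(fb$fold[big == "conductive"])
  expect_true(all(per_fold %in% c(65, 66)))
  expect_equal(sum(per_fold), 657)
  expect_error(stratified_folds(c(rep("normal", 3), rep("mixed", 20)), k = 10),
               "normal")
})

test_that("fold class proportions track the global proportions", {
  set.seed(2)
  labels <- sample(lv, 3000, replace = TRUE, prob = c(0.17, 0.05, 0.27, 0.51))
  f <- stratified_folds(labels, k = 10, seed = 9)
  global <- prop.table(table(factor(labels, lv)))
  for (k in 1:10) {
    fold_prop <- prop.table(table(factor(labels[f$fold == k], lv)))
    expect_true(all(abs(fold_prop - global) < 1 / sum(f$fold == k)))
  }
})

test_that("confusion matrix counts in fixed order, permutation-invariant", {
  truth <- c("normal", "mixed", "mixed", "sensorineural")
  pred <- c("normal", "sensorineural", "mixed", "sensorineural")
  cm <- confusion(truth, pred)
  expect_equal(sum(cm), 4)
  expect_equal(unname(cm["mixed", "sensorineural"]), 1L)
  expect_equal(unname(diag(unclass(cm))), c(1L, 0L, 1L, 1L))
  o <- sample(4)
  expect_equal(unclass(confusion(truth[o], pred[o])), unclass(cm))
  all_right <- confusion(truth, truth)
  expect_equal(sum(diag(unclass(all_right))), 4)
  expect_error(confusion(truth, pred[1:3]), "equal length")
})

test_that("metric family: identities and worked values", {
  set.seed(8)
  truth <- sample(lv, 300, replace = TRUE)
  pred <- ifelse(runif(300) < 0.8, truth, sample(lv, 300, replace = TRUE))
  cm <- confusion(truth, pred)
  m <- metrics_from_confusion(cm)
  # overall accuracy equals support-weighted recall
  expect_equal(m$accuracy, m$recall)
  u <- unclass(cm)
  expect_equal(m$per_class$tp + m$per_class$fn, unname(rowSums(u)))
  expect_equal(m$per_class$tp + m$per_class$fp, unname(colSums(u)))
  expect_true(all(unlist(m[c("accuracy", "precision", "recall", "f1")]) >= 0 &
                    unlist(m[c("accuracy", "precision", "recall", "f1")]) <= 1))
  # perfect diagonal matrix: everything 100%
  mp <- metrics_from_confusion(confusion(truth, truth))
  expect_equal(unlist(mp[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  # F1 = 0 convention when precision + recall = 0
  cm0 <- matrix(0L, 4, 4, dimnames = list(truth = lv, predicted = lv))
  cm0[1, 2] <- 10L   # normal always predicted conductive
  class(cm0) <- c("confusion_matrix", class(cm0))
  m0 <- metrics_from_confusion(cm0)
  expect_equal(m0$per_class$f1[1], 0)
  expect_error(metrics_from_confusion(cm0 * 0L), "empty")
})

test_that("cv aggregation: mean within range, zero sd for identical folds", {
  r <- metrics_from_confusion(confusion(rep("normal", 5), rep("normal", 5)))
  agg <- aggregate_cv(list(r, r, r))
  expect_equal(unname(agg$sd), rep(0, 4))
  expect_equal(unname(agg$mean[["accuracy"]]), 1)
  expect_error(aggregate_cv(list(r)), "at least 2")
})

test_that("micro-OvR AUC equals exhaustive pair counting (brute force)", {
  brute_auc <- function(pos, scores) {
    s_pos <- scores[pos]; s_neg <- scores[!pos]
    tot <- 0
    for (a in s_pos) for (b in s_neg)
      tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(s_pos) * length(s_neg))
  }
  set.seed(14)
  for (rep in 1:5) {
    n <- 40
    truth <- sample(lv, n, replace = TRUE)
    P <- matrix(rexp(n * 4), n, 4)
    P <- P / rowSums(P)
    y_idx <- match(truth, lv)
    ind <- matrix(0L, n, 4); ind[cbind(1:n, y_idx)] <- 1L
    expect_equal(roc_auc_micro_ovr(truth, P),
                 brute_auc(as.vector(ind) == 1, as.vector(P)))
  }
  # perfect classifier
  truth <- sample(lv, 30, replace = TRUE)
  Pp <- matrix(0, 30, 4); Pp[cbind(1:30, match(truth, lv))] <- 1
  expect_equal(roc_auc_micro_ovr(truth, Pp), 1)
  # constant scores: all ties, AUC 1/2
  expect_equal(roc_auc_micro_ovr(truth, matrix(0.25, 30, 4)), 0.5)
  expect_error(roc_auc_micro_ovr(truth, Pp[, 1:3]), "n x 4")
})

test_that("binary AUC worked example and pROC cross-check", {
  # truths (1,0,1,0), scores (.9,.8,.7,.1): 3 of 4 pairs correct -> 0.75
  pos <- c(TRUE, FALSE, TRUE, FALSE)
  scores <- c(0.9, 0.8, 0.7, 0.1)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - 2 * 3 / 2) / (2 * 2)
  expect_equal(auc, 0.75)
  set.seed(4)
  truth <- sample(lv, 60, replace = TRUE)
  P <- matrix(runif(240), 60, 4); P <- P / rowSums(P)
  ind <- matrix(0L, 60, 4); ind[cbind(1:60, match(truth, lv))] <- 1L
  ref <- as.numeric(pROC::auc(as.vector(ind), as.vector(P), quiet = TRUE,
                              direction = "<"))
  expect_equal(roc_auc_micro_ovr(truth, P), ref, tolerance = 1e-12)
})

test_that("mcnemar: hand-evaluated formulas with and without correction", {
  # n01=12, n10=2: corrected chi-square = 81/14
  truth <- rep("normal", 100)
  a <- c(rep("mixed", 12), rep("normal", 88))          # A wrong on 1..12
  b <- c(rep("normal", 98), rep("mixed", 2))           # B wrong on 99..100
  m <- mcnemar_compare(truth, a, b)
  expect_equal(m$n01, 12); expect_equal(m$n10, 2)
  expect_equal(m$n00, 0); expect_equal(m$n11, 86)
  expect_equal(m$statistic, 81 / 14)
  expect_equal(m$p_value, pchisq(81 / 14, 1, lower.tail = FALSE))
  expect_equal(round(m$p_value, 4), 0.0162)
  raw <- mcnemar_compare(truth, a, b, correction = FALSE)
  expect_equal(raw$statistic, (12 - 2)^2 / 14)
  # n01 = n10 = 10 with correction: chi-square 0.05
  a2 <- c(rep("mixed", 10), rep("normal", 90))
  b2 <- c(rep("normal", 90), rep("mixed", 10))
  m2 <- mcnemar_compare(truth, a2, b2)
  expect_equal(m2$statistic, 0.05)
  expect_equal(round(m2$p_value, 3), 0.823)
  # identical classifiers: degenerate, p = 1
  m3 <- mcnemar_compare(truth, a, a)
  expect_true(m3$degenerate)
  expect_equal(m3$statistic, 0); expect_equal(m3$p_value, 1)
})

test_that("mcnemar tracks the exact binomial test at small counts", {
  truth <- rep("normal", 60)
  for (counts in list(c(8, 2), c(10, 5), c(12, 12), c(3, 9))) {
    n01 <- counts[1]; n10 <- counts[2]
    a <- c(rep("mixed", n01), rep("normal", 60 - n01))
    b <- c(rep("normal", 60 - n10), rep("mixed", n10))
    m <- mcnemar_compare(truth, a, b)          # with continuity correction
    exact <- binom.test(n01, n01 + n10, 0.5)$p.value
    expect_lt(abs(m$p_value - exact), 0.25)
    # agreement in the rejection decision at alpha = 0.05 for these cases
    expect_equal(m$p_value < 0.05, exact < 0.05)
  }
})

test_that("cross-validation experiment wiring: folds, pooling, conservation", {
  d <- generate_audiograms(generator_config(n = 400, seed = 19))
  exp <- run_cv_experiment(d, model = "tree", k = 5, seed = 2)
  expect_equal(nrow(exp$cv$folds), 5)
  expect_equal(sum(exp$pooled_confusion), 400)
  expect_gt(exp$cv$mean[["accuracy"]], 0.85)
  expect_true(exp$auc > 0.9 && exp$auc <= 1)
  expect_true(exp$cv$mean[["accuracy"]] >= min(exp$cv$folds$accuracy) &&
                exp$cv$mean[["accuracy"]] <= max(exp$cv$folds$accuracy))
})
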