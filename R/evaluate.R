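#' Stratified K-fold assignment
#'
#' Each class is shuffled with the given seed and dealt round-robin across
#' the K folds, so per-class fold counts differ by at most one and every
#' fold's class proportions track the whole dataset's.
#'
#' @param labels Class labels (any discrete values).
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the within-class shuffles.
#' @return A list of class `stratified_folds`: `fold` (integer vector in
#'   1..k parallel to `labels`), `k`, `seed`.
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  k <- as.integer(k)
  counts <- table(labels)
  small <- names(counts)[counts < k]
  if (length(small))
    stop("class smaller than k: ", paste(small, collapse = ", "))
  fold <- integer(n)
  with_private_seed(seed, {
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  out <- list(fold = fold, k = k, seed = as.integer(seed))
  class(out) <- "stratified_folds"
  out
}

#' Confusion matrix in fixed class order
#'
#' Rows are true classes, columns predicted, in the fixed order
#' (normal, conductive, mixed, sensorineural).
#'
#' @param truth,predicted Parallel label vectors in the clinical classes.
#' @return A 4 x 4 integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  lv <- hearing_loss_levels(clinical_only = TRUE)
  t_idx <- labels_to_index(truth)
  p_idx <- labels_to_index(predicted)
  cm <- matrix(0L, 4, 4, dimnames = list(truth = lv, predicted = lv))
  for (i in seq_along(t_idx))
    cm[t_idx[i], p_idx[i]] <- cm[t_idx[i], p_idx[i]] + 1L
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' @export
print.confusion_matrix <- function(x, ...) {
  y <- x
  class(y) <- "matrix"
  print(y, ...)
  invisible(x)
}

#' Metric family from a confusion matrix
#'
#' Per class (one-vs-rest): TP, TN, FP, FN, then precision TP/(TP+FP),
#' recall TP/(TP+FN) and F1 = 2 PR/(P+R), with the 0/0 convention that an
#' undefined ratio is 0. Overall accuracy is trace/total; aggregate
#' precision/recall/F1 are support-weighted by default (macro available).
#'
#' @param cm A [confusion()] matrix.
#' @param average `"weighted"` (support-weighted, default) or `"macro"`.
#' @return A list of class `metrics_report`: `per_class` data frame,
#'   `accuracy`, `precision`, `recall`, `f1` (aggregates, all in `[0,1]`).
#' @export
metrics_from_confusion <- function(cm, average = c("weighted", "macro")) {
  average <- match.arg(average)
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  K <- nrow(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  safe_div <- function(a, b) ifelse(b == 0, 0, a / b)
  prec <- safe_div(tp, tp + fp)
  rec <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * prec * rec, prec + rec)
  support <- rowSums(cm)
  wts <- if (average == "weighted") support / total else rep(1 / K, K)
  per_class <- data.frame(class = rownames(cm), tp = tp, tn = tn, fp = fp,
                          fn = fn, precision = prec, recall = rec, f1 = f1,
                          support = support, row.names = NULL)
  out <- list(per_class = per_class,
              accuracy = sum(tp) / total,
              precision = sum(wts * prec),
              recall = sum(wts * rec),
              f1 = sum(wts * f1),
              average = average)
  class(out) <- "metrics_report"
  out
}

#' Aggregate per-fold metrics into a cross-validation report
#'
#' Arithmetic mean and population (ddof = 0) standard deviation of each
#' aggregate metric over the folds, the reporting convention of
#' "mean (+/- sd)" cross-validation tables.
#'
#' @param fold_reports List of [metrics_from_confusion()] reports, one per
#'   fold (at least 2).
#' @return A list of class `cv_report`: `folds` (data frame of per-fold
#'   aggregates), `mean` and `sd` (named vectors over accuracy, precision,
#'   recall, f1).
#' @export
aggregate_cv <- function(fold_reports) {
  if (length(fold_reports) < 2L) stop("need at least 2 folds")
  mets <- c("accuracy", "precision", "recall", "f1")
  folds <- do.call(rbind, lapply(fold_reports, function(r)
    as.data.frame(r[mets])))
  folds <- cbind(fold = seq_len(nrow(folds)), folds)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- list(folds = folds,
              mean = vapply(folds[mets], mean, numeric(1)),
              sd = vapply(folds[mets], pop_sd, numeric(1)))
  class(out) <- "cv_report"
  out
}

#' @export
print.cv_report <- function(x, digits = 2, ...) {
  cat(sprintf("%d-fold cross-validation:\n", nrow(x$folds)))
  for (m in names(x$mean))
    cat(sprintf("  %-9s %.*f%% (+/- %.*f%%)\n", m, digits,
                100 * x$mean[[m]], digits, 100 * x$sd[[m]]))
  invisible(x)
}

#' Micro-averaged one-vs-rest ROC AUC
#'
#' The K one-vs-rest binary problems are pooled into a single set of
#' (indicator, score) pairs and the AUC is the normalized Mann-Whitney
#' rank statistic (ties contribute 1/2), equivalent to trapezoidal
#' integration of the pooled ROC curve.
#'
#' @param truth Label vector in the clinical classes.
#' @param probabilities n x 4 matrix of class probabilities in fixed class
#'   order (each row a probability simplex point).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc_micro_ovr <- function(truth, probabilities) {
  y_idx <- labels_to_index(truth)
  P <- as.matrix(probabilities)
  if (nrow(P) != length(y_idx) || ncol(P) != 4L)
    stop("probabilities must be an n x 4 matrix parallel to truth")
  ind <- matrix(0L, nrow(P), 4L)
  ind[cbind(seq_len(nrow(P)), y_idx)] <- 1L
  pos <- as.vector(ind) == 1L
  scores <- as.vector(P)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC undefined: pooled truth vector has a single class")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' McNemar's paired test for two classifiers
#'
#' From per-sample correctness of classifiers A and B on the same samples,
#' counts n00 (both wrong), n01 (A wrong, B right), n10 (A right, B
#' wrong), n11 (both right). Under the null hypothesis the two error rates
#' are equal; the statistic is chi-square with 1 degree of freedom on the
#' discordant counts, with Edwards' continuity correction
#' (|n01 - n10| - 1)^2 / (n01 + n10) by default, or the classical
#' (n01 - n10)^2 / (n01 + n10) without.
#'
#' @param truth True labels.
#' @param preds_a,preds_b Predictions of the two classifiers.
#' @param correction Apply the continuity correction (default `TRUE`).
#' @return A list of class `mcnemar_result`: `n00`, `n01`, `n10`, `n11`,
#'   `statistic`, `p_value`, `correction`, `degenerate` (`TRUE` when there
#'   are no discordant pairs, in which case statistic = 0 and p = 1).
#' @export
mcnemar_compare <- function(truth, preds_a, preds_b, correction = TRUE) {
  if (length(truth) != length(preds_a) || length(truth) != length(preds_b))
    stop("truth, preds_a and preds_b must have equal length")
  ok_a <- as.character(preds_a) == as.character(truth)
  ok_b <- as.character(preds_b) == as.character(truth)
  n00 <- sum(!ok_a & !ok_b); n01 <- sum(!ok_a & ok_b)
  n10 <- sum(ok_a & !ok_b); n11 <- sum(ok_a & ok_b)
  nd <- n01 + n10
  if (nd == 0) {
    stat <- 0; p <- 1; degen <- TRUE
  } else {
    num <- if (correction) (abs(n01 - n10) - 1)^2 else (n01 - n10)^2
    stat <- num / nd
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    degen <- FALSE
  }
  out <- list(n00 = n00, n01 = n01, n10 = n10, n11 = n11,
              statistic = stat, p_value = p,
              correction = correction, degenerate = degen)
  class(out) <- "mcnemar_result"
  out
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf("McNemar's test (%s continuity correction)\n",
              if (x$correction) "with" else "without"))
  cat(sprintf("  n00=%d n01=%d n10=%d n11=%d\n", x$n00, x$n01, x$n10, x$n11))
  cat(sprintf("  chi-square = %.4f, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Run a stratified cross-validation experiment
#'
#' The full evaluation protocol on a labelled, QC-passing audiogram set.
#' Within every fold: the normalizer is fitted on the training fold only,
#' class weights are computed on the training fold, the model is trained
#' and then evaluated on the held-out fold. Per-fold metrics are
#' aggregated, fold predictions are pooled into a single confusion matrix
#' and a pooled micro-averaged one-vs-rest AUC.
#'
#' @param set A labelled audiogram set (all records complete, labels in the
#'   four clinical classes).
#' @param model One of `"bilstm"`, `"lstm"`, `"tree"`.
#' @param model_cfg A [model_config()] (sequence models) or
#'   [tree_config()] (tree); `NULL` = defaults.
#' @param normalization Feature-scaling method for the sequence models.
#' @param k Number of folds.
#' @param seed Seed for fold assignment and per-fold model training.
#' @param use_class_weights Weight the training loss by balanced class
#'   weights (sequence models; default `TRUE`).
#' @return A list of class `cv_experiment`: `cv` ([aggregate_cv()] report),
#'   `pooled_confusion`, `pooled_metrics`, `auc`, `model`, `normalization`,
#'   `k`, `seed`.
#' @export
run_cv_experiment <- function(set, model = c("bilstm", "lstm", "tree"),
                              model_cfg = NULL,
                              normalization = "zscore",
                              k = 10L, seed = 1L,
                              use_class_weights = TRUE) {
  model <- match.arg(model)
  if (is.null(set$label) || anyNA(set$label))
    stop("run_cv_experiment requires a fully labelled set")
  labels <- as.character(set$label)
  folds <- stratified_folds(labels, k = k, seed = seed)
  truth_all <- character(0)
  pred_all <- character(0)
  proba_all <- NULL
  reports <- vector("list", folds$k)
  for (f in seq_len(folds$k)) {
    te <- folds$fold == f
    tr <- !te
    truth <- labels[te]
    if (model == "tree") {
      feats <- flatten_features(set)
      cfg <- if (is.null(model_cfg)) tree_config() else model_cfg
      fit <- train_tree_baseline(feats[tr, , drop = FALSE], labels[tr], cfg)
      P <- predict_tree_proba(fit, feats[te, , drop = FALSE])
    } else {
      cfg <- if (is.null(model_cfg)) model_config(architecture = model)
             else model_cfg
      cfg$seed <- cfg$seed + f            # fold-specific stream
      seqs <- encode_sequences(set)
      tr_seqs <- subset_sequences(seqs, which(tr))
      norm <- fit_normalizer(tr_seqs, normalization)
      enc_tr <- apply_normalizer(norm, tr_seqs)
      enc_te <- apply_normalizer(norm, subset_sequences(seqs, which(te)))
      cw <- if (use_class_weights) compute_class_weights(labels[tr]) else NULL
      fit <- train_sequence_model(enc_tr, labels[tr], cw, cfg)
      P <- predict_proba(fit, enc_te)
    }
    pred <- as.character(proba_to_label(P))
    reports[[f]] <- metrics_from_confusion(confusion(truth, pred))
    truth_all <- c(truth_all, truth)
    pred_all <- c(pred_all, pred)
    proba_all <- rbind(proba_all, P)
  }
  pooled_cm <- confusion(truth_all, pred_all)
  out <- list(cv = aggregate_cv(reports),
              pooled_confusion = pooled_cm,
              pooled_metrics = metrics_from_confusion(pooled_cm),
              auc = roc_auc_micro_ovr(truth_all, proba_all),
              model = model, normalization = normalization,
              k = folds$k, seed = seed)
  class(out) <- "cv_experiment"
  out
}

#' Subset a feature_sequences object by record index
#'
#' @param seqs A `feature_sequences` object.
#' @param idx Integer row indices.
#' @return The subset `feature_sequences`.
#' @export
subset_sequences <- function(seqs, idx) {
  out <- list(air = seqs$air[idx, , drop = FALSE],
              bone = seqs$bone[idx, , drop = FALSE],
              bone_present = seqs$bone_present[idx, , drop = FALSE],
              freqs = seqs$freqs)
  class(out) <- "feature_sequences"
  out
}
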