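#' Model evaluation: ranking metrics, threshold metrics, cross-validation
#'
#' Scores are suitabilities in [0, 1]; labels are 1 for presence, 0 for
#' background. "Suitable" always means score >= threshold.
#'
#' @name evaluation
NULL

check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2)
    stop("undefined metric: need both presence and background points")
}

#' Rank AUC (area under the ROC curve)
#'
#' Mann-Whitney formulation: the probability that a random presence outscores
#' a random background point, ties counted 1/2.
#'
#' @param scores suitability scores.
#' @param labels 0/1 class labels.
#' @return AUC in [0, 1].
#' @export
rank_auc <- function(scores, labels) {
  check_two_classes(labels)
  r <- rank(scores)                 # midranks handle ties as 1/2
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-interpolated average precision over distinct score thresholds:
#' `AP = sum_t (recall_t - recall_{t-1}) * precision_t`, thresholds swept from
#' the highest score down. Ties are handled by treating each distinct score as
#' one threshold.
#'
#' @inheritParams rank_auc
#' @return AUC-PR in [0, 1]; the no-skill baseline is the presence prevalence.
#' @export
precision_recall_auc <- function(scores, labels) {
  check_two_classes(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  n1 <- sum(labels == 1)
  last <- which(!duplicated(s, fromLast = TRUE))  # last row of each tie group
  precision <- tp[last] / (tp[last] + fp[last])
  recall <- tp[last] / n1
  sum(diff(c(0, recall)) * precision)
}

#' Threshold-dependent metric set
#'
#' Confusion counts with predicted-suitable = score >= threshold;
#' `PCC = 100 (TP+TN)/N`, `sensitivity = TP/(TP+FN)`,
#' `specificity = TN/(TN+FP)`, Cohen's kappa from the marginal expected
#' agreement, and `TSS = sensitivity + specificity - 1` (asserted as an
#' identity at construction). Also fills the two ranking AUCs.
#'
#' @inheritParams rank_auc
#' @param threshold classification threshold.
#' @param split label recorded in the result (`"train"` or `"cv_mean"`).
#' @return Object of class `metric_set`.
#' @export
threshold_metrics <- function(scores, labels, threshold, split = "train") {
  check_two_classes(labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1); fn <- sum(!pred & labels == 1)
  tn <- sum(!pred & labels == 0); fp <- sum(pred & labels == 0)
  n <- tp + fn + tn + fp
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  p_o <- (tp + tn) / n
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (p_e >= 1) 0 else (p_o - p_e) / (1 - p_e)
  metric_set(auc_roc = rank_auc(scores, labels),
             auc_pr = precision_recall_auc(scores, labels),
             pcc = 100 * p_o, kappa = kappa,
             sensitivity = sens, specificity = spec,
             tss = sens + spec - 1,
             threshold_used = threshold, split = split)
}

#' Metric container with the TSS identity enforced
#' @param auc_roc,auc_pr,pcc,kappa,sensitivity,specificity,tss,threshold_used
#'   metric values (`pcc` on the percent scale).
#' @param split `"train"` or `"cv_mean"`.
#' @export
metric_set <- function(auc_roc = NA_real_, auc_pr = NA_real_, pcc, kappa,
                       sensitivity, specificity, tss, threshold_used,
                       split = "train") {
  stopifnot(isTRUE(all.equal(tss, sensitivity + specificity - 1)))
  stopifnot(kappa >= -1 - 1e-9, kappa <= 1 + 1e-9)
  structure(list(auc_roc = auc_roc, auc_pr = auc_pr, pcc = pcc, kappa = kappa,
                 tss = tss, sensitivity = sensitivity,
                 specificity = specificity, threshold_used = threshold_used,
                 split = split),
            class = "metric_set")
}

#' @exportS3Method base::print
print.metric_set <- function(x, ...) {
  cat(sprintf(paste0("metric_set (%s): AUC %.3f, AUC-PR %.3f, PCC %.1f%%, ",
                     "kappa %.3f, TSS %.3f, sens %.3f, spec %.3f @ thr %.3f\n"),
              x$split, x$auc_roc, x$auc_pr, x$pcc, x$kappa, x$tss,
              x$sensitivity, x$specificity, x$threshold_used))
  invisible(x)
}

metric_row <- function(m) {
  data.frame(split = m$split, auc_roc = m$auc_roc, auc_pr = m$auc_pr,
             pcc = m$pcc, kappa = m$kappa, tss = m$tss,
             sensitivity = m$sensitivity, specificity = m$specificity,
             threshold_used = m$threshold_used)
}

#' Sensitivity = specificity threshold
#'
#' Candidate thresholds are the observed scores; returns the candidate
#' minimizing `|sensitivity - specificity|`, ties resolved to the lower
#' threshold.
#'
#' @inheritParams rank_auc
#' @return the selected threshold (a score value).
#' @export
sens_eq_spec_threshold <- function(scores, labels) {
  check_two_classes(labels)
  cand <- sort(unique(scores))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  gap <- vapply(cand, function(th) {
    sens <- sum(scores >= th & labels == 1) / n1
    spec <- sum(scores < th & labels == 0) / n0
    abs(sens - spec)
  }, numeric(1))
  cand[which.min(gap)]       # which.min takes the first (lowest) on ties
}

#' Stratified k-fold cross-validation of one model specification
#'
#' Folds are assigned per class by a seeded random permutation, so every fold
#' keeps both classes and per-class fold sizes differ by at most one. For
#' each fold the model is refit on the other k-1 folds, the held-out fold is
#' scored, and threshold metrics are computed at the sensitivity =
#' specificity threshold of that fold's *training* scores (no leakage). The
#' cross-validated summary is the unweighted mean over folds.
#'
#' @param spec a [model_spec].
#' @param t a design table.
#' @param k number of folds (workflow default 10).
#' @param seed fold-assignment seed; per-fold fit seeds derive from it.
#' @return list with `metrics` (a `metric_set`, split `"cv_mean"`),
#'   `folds` (per-fold data.frame), and `assignment` (fold id per row).
#' @export
cross_validate <- function(spec, t, k = 10, seed = 1) {
  y <- t$response
  if (sum(y == 1) < k || sum(y == 0) < k)
    stop("fold error: fewer than k points in one class")
  fold <- integer(nrow(t))
  withr_seed(seed, {
    for (cls in c(0, 1)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    fit_spec <- spec
    fit_spec$seed <- (spec$seed + f * 1009L) %% .Machine$integer.max
    m <- fit_model(fit_spec, t[fold != f, , drop = FALSE])
    train_scores <- predict_scores(m, t[fold != f, , drop = FALSE])
    thr <- sens_eq_spec_threshold(train_scores, y[fold != f])
    test_scores <- predict_scores(m, t[fold == f, , drop = FALSE])
    ms <- threshold_metrics(test_scores, y[fold == f], thr, split = "cv")
    rows[[f]] <- cbind(fold = f, metric_row(ms))
  }
  folds <- do.call(rbind, rows)
  mean_of <- function(col) mean(folds[[col]])
  metrics <- metric_set(auc_roc = mean_of("auc_roc"),
                        auc_pr = mean_of("auc_pr"),
                        pcc = mean_of("pcc"), kappa = mean_of("kappa"),
                        sensitivity = mean_of("sensitivity"),
                        specificity = mean_of("specificity"),
                        tss = mean_of("sensitivity") + mean_of("specificity") - 1,
                        threshold_used = mean_of("threshold_used"),
                        split = "cv_mean")
  list(metrics = metrics, folds = folds, assignment = fold)
}
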