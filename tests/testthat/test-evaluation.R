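# brute-force oracles, kept deliberately naive and separate from the
# implementations they check
brute_auc <- function(scores, labels) {
  ps <- scores[labels == 1]; bs <- scores[labels == 0]
  mean(outer(ps, bs, function(a, b) (a > b) + 0.5 * (a == b)))
}
brute_ap <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0; ap <- 0
  for (th in ths) {
    tp <- sum(scores >= th & labels == 1)
    fp <- sum(scores >= th & labels == 0)
    rec <- tp / sum(labels == 1)
    ap <- ap + (rec - prev_rec) * tp / (tp + fp)
    prev_rec <- rec
  }
  ap
}
brute_kappa <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  (po - pe) / (1 - pe)
}

test_that("rank_auc matches hand-computed and degenerate cases", {
  expect_equal(rank_auc(c(0.8, 0.6, 0.4, 0.7), c(1, 1, 0, 0)), 0.75)
  expect_equal(rank_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(rank_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(rank_auc(1:3, c(1, 1, 1)), "undefined metric")
})

test_that("rank_auc equals brute-force pairwise enumeration", {
  withr_seed(3, {
    for (i in 1:50) {
      n <- sample(4:50, 1)
      labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
      scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # force ties
      expect_equal(rank_auc(scores, labels), brute_auc(scores, labels))
    }
  })
})

test_that("precision_recall_auc matches its enumeration oracle", {
  expect_equal(precision_recall_auc(c(0.9, 0.1), c(1, 0)), 1)
  # 6-point toy with a tie
  s <- c(0.9, 0.7, 0.7, 0.5, 0.3, 0.1)
  y <- c(1, 1, 0, 0, 1, 0)
  expect_equal(precision_recall_auc(s, y), brute_ap(s, y))
  withr_seed(8, {
    for (i in 1:30) {
      n <- sample(5:40, 1)
      y <- c(1, 0, rbinom(n - 2, 1, 0.4))
      s <- sample(seq(0, 1, 0.1), n, replace = TRUE)
      expect_equal(precision_recall_auc(s, y), brute_ap(s, y))
    }
    # random scores, balanced classes: AP ~ prevalence
    y <- rep(c(0, 1), 5000)
    s <- runif(10000)
    expect_equal(precision_recall_auc(s, y), 0.5, tolerance = 0.02)
  })
})

test_that("threshold metrics reproduce the hand-computed confusion matrix", {
  # TP=40 FN=10 TN=45 FP=5 at threshold 0.5
  scores <- c(rep(0.9, 40), rep(0.1, 10), rep(0.1, 45), rep(0.9, 5))
  labels <- c(rep(1, 50), rep(0, 50))
  m <- threshold_metrics(scores, labels, 0.5)
  expect_equal(m$pcc, 85)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$kappa, 0.7)
  expect_equal(m$tss, 0.7)
  # all correct
  m <- threshold_metrics(c(0.9, 0.9, 0.1), c(1, 1, 0), 0.5)
  expect_equal(m$pcc, 100)
  expect_equal(m$kappa, 1)
  expect_equal(m$tss, 1)
})

test_that("kappa matches the closed form on random 2x2 tables and is ~0 for
           label-independent predictions", {
  withr_seed(12, {
    for (i in 1:50) {
      cf <- sample(1:50, 4, replace = TRUE)   # tp, fn, fp, tn
      scores <- c(rep(0.9, cf[1]), rep(0.1, cf[2]),
                  rep(0.9, cf[3]), rep(0.1, cf[4]))
      labels <- c(rep(1, cf[1] + cf[2]), rep(0, cf[3] + cf[4]))
      m <- threshold_metrics(scores, labels, 0.5)
      expect_equal(m$kappa, brute_kappa(cf[1], cf[3], cf[2], cf[4]))
      expect_equal(m$tss, m$sensitivity + m$specificity - 1)
    }
    labels <- rbinom(20000, 1, 0.5)
    scores <- runif(20000)
    expect_equal(threshold_metrics(scores, labels, 0.5)$kappa, 0,
                 tolerance = 0.05)
  })
})

test_that("metrics are invariant to point order", {
  withr_seed(19, {
    s <- runif(100); y <- rbinom(100, 1, 0.5); y[1:2] <- c(0, 1)
    perm <- sample(100)
    expect_equal(rank_auc(s, y), rank_auc(s[perm], y[perm]))
    expect_equal(precision_recall_auc(s, y),
                 precision_recall_auc(s[perm], y[perm]))
    m1 <- threshold_metrics(s, y, 0.4)
    m2 <- threshold_metrics(s[perm], y[perm], 0.4)
    expect_equal(m1$kappa, m2$kappa)
  })
})

test_that("sens_eq_spec threshold matches exhaustive enumeration", {
  expect_equal(sens_eq_spec_threshold(c(0.9, 0.8, 0.7, 0.2, 0.3, 0.6),
                                      c(1, 1, 1, 0, 0, 0)), 0.7)
  expect_equal(sens_eq_spec_threshold(c(0.8, 0.3), c(1, 0)), 0.8)
  brute <- function(s, y) {
    cand <- sort(unique(s))
    gaps <- sapply(cand, function(th) abs(mean(s[y == 1] >= th) -
                                            mean(s[y == 0] < th)))
    cand[which.min(gaps)]
  }
  withr_seed(23, {
    for (i in 1:30) {
      n <- sample(6:60, 1)
      y <- c(1, 0, rbinom(n - 2, 1, 0.5))
      s <- round(runif(n), 2)
      expect_equal(sens_eq_spec_threshold(s, y), brute(s, y))
    }
  })
})

test_that("cross_validate is stratified, seeded, and perfect on separable data", {
  withr_seed(77, {
    t <- structure(data.frame(
      point_id = 1:60, x = runif(60), y = runif(60),
      response = rep(c(1, 0), c(24, 36)),
      sig = c(runif(24, 0.8, 1), runif(36, 0, 0.2)),
      noise = rnorm(60)),
      class = c("design_table", "data.frame"))
  })
  spec <- model_spec("rf", settings = list(n_trees = 100), seed = 2)
  cv1 <- cross_validate(spec, t, k = 6, seed = 4)
  cv2 <- cross_validate(spec, t, k = 6, seed = 4)
  expect_identical(cv1$assignment, cv2$assignment)
  expect_equal(cv1$metrics$auc_roc, cv2$metrics$auc_roc)
  # per-class fold sizes differ by at most 1
  for (cls in c(0, 1)) {
    sizes <- table(cv1$assignment[t$response == cls])
    expect_lte(diff(range(sizes)), 1)
  }
  # separable toy: every algorithm reaches cv AUC 1
  for (alg in c("glm_stepwise", "mars", "brt", "rf", "maxent_like")) {
    cv <- cross_validate(model_spec(alg, seed = 3), t, k = 6, seed = 4)
    expect_equal(cv$metrics$auc_roc, 1,
                 info = paste("algorithm", alg))
  }
  expect_error(cross_validate(spec, t[1:12, ], k = 10), "fold error")
})
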