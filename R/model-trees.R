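# The two tree ensembles, thin R wrappers over the compiled CART core.
#
# rf: probability random forest — gini-split CART on bootstrap samples with
# mtry = floor(sqrt(p)) split candidates per node; suitability is the
# tree-average terminal-node presence fraction.
#
# brt: stochastic gradient boosting with bernoulli loss, bag fraction 0.5,
# shallow trees; the tree count is chosen at the deviance minimum of a
# seeded stratified 20% internal holdout, and the kept model is the one fit
# on the remaining 80%, truncated at that iteration.

fit_rf <- function(X, y, settings, seed) {
  p <- ncol(X)
  mtry <- settings$mtry %||% max(1L, floor(sqrt(p)))
  trees <- withr_seed(seed,
    .cpp_rf_fit(X, as.numeric(y), as.integer(settings$n_trees),
                as.integer(mtry), as.integer(settings$min_node),
                as.integer(settings$max_depth)))
  list(fit = list(trees = trees), variables_used = colnames(X))
}

predict_rf <- function(fit, X) .cpp_forest_predict(fit$trees, X)

fit_brt <- function(X, y, settings, seed) {
  n <- nrow(X)
  res <- withr_seed(seed, {
    hold <- integer()
    for (cls in c(0, 1)) {
      idx <- which(y == cls)
      nh <- max(1L, floor(settings$holdout_fraction * length(idx)))
      hold <- c(hold, sample(idx, nh))
    }
    tr <- setdiff(seq_len(n), hold)
    .cpp_brt_fit(X[tr, , drop = FALSE], as.numeric(y[tr]),
                 X[hold, , drop = FALSE], as.numeric(y[hold]),
                 as.integer(settings$n_trees_max), settings$learning_rate,
                 settings$bag_fraction, as.integer(settings$tree_depth),
                 as.integer(settings$min_node))
  })
  best <- which.min(res$valid_deviance)
  feats <- sort(unique(unlist(lapply(res$trees[seq_len(best)], function(tr) {
    f <- tr[, 1]
    f[f >= 0]
  }))))
  list(fit = list(trees = res$trees, f0 = res$f0,
                  lr = settings$learning_rate, best_iter = best),
       variables_used = colnames(X)[feats + 1])
}

predict_brt <- function(fit, X)
  .cpp_brt_predict(fit$trees, fit$f0, fit$lr, as.integer(fit$best_iter), X)
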