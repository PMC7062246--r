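# Maxent-style model as an infinitely-weighted penalized logistic regression
# (the maxnet equivalence): linear + quadratic + hinge features of each
# predictor, lasso-penalized logistic fit with background points carrying a
# large weight. Lambda is chosen deterministically by AIC along the lasso
# path (weighted deviance + 2 df) and scaled by a regularization multiplier;
# cross-validated deviance is unusable here because the 100x background
# weighting makes fold deviance insensitive to the presence fit. Bundling the
# Java Maxent is out of scope; this glmnet formulation is the documented
# stand-in. Reported suitability is plogis(eta + log(W)) — a fixed monotone
# rescale of the linear predictor that undoes the background down-weighting
# so scores spread over [0, 1]; every downstream use is rank- or
# threshold-based, so the rescale is inert.

maxent_features <- function(X, knots) {
  p <- ncol(X)
  parts <- list(X, X^2)
  names_out <- c(paste0("lin_", colnames(X)), paste0("quad_", colnames(X)))
  for (j in seq_len(p)) {
    for (k in knots[[j]]) {
      parts <- c(parts, list(pmax(X[, j] - k, 0), pmax(k - X[, j], 0)))
      names_out <- c(names_out,
                     paste0("hingeR_", colnames(X)[j], "_", signif(k, 6)),
                     paste0("hingeL_", colnames(X)[j], "_", signif(k, 6)))
    }
  }
  out <- do.call(cbind, parts)
  colnames(out) <- names_out
  out
}

fit_maxent_like <- function(X, y, settings, seed) {
  knots <- lapply(seq_len(ncol(X)), function(j)
    unique(stats::quantile(X[, j],
                           probs = seq(0.1, 0.9,
                                       length.out = settings$n_hinge_knots),
                           type = 7, names = FALSE)))
  # presences are also added as background rows (the maxnet convention):
  # the background must cover the presence feature space or the weighted
  # IRLS can diverge on separable data
  Xa <- rbind(X, X[y == 1, , drop = FALSE])
  ya <- c(y, rep(0, sum(y == 1)))
  FT <- maxent_features(Xa, knots)
  # zero-variance columns (hinges pinned at a distribution edge) break
  # glmnet's internal standardization
  keep <- apply(FT, 2, function(col) stats::sd(col) > 0)
  FT <- FT[, keep, drop = FALSE]
  w <- ifelse(ya == 1, 1, settings$background_weight)
  fit <- suppressWarnings(
    glmnet::glmnet(FT, ya, family = "binomial", weights = w, alpha = 1,
                   nlambda = 50, lambda.min.ratio = 1e-4))
  dev <- (1 - fit$dev.ratio) * fit$nulldev
  aic <- dev + 2 * fit$df
  lam <- fit$lambda[which.min(aic)] * settings$reg_multiplier
  lam <- min(max(lam, min(fit$lambda)), max(fit$lambda))
  list(fit = list(glmnet = fit, lambda = lam, knots = knots, keep = keep,
                  W = settings$background_weight),
       variables_used = colnames(X))
}

predict_maxent_like <- function(fit, X) {
  FT <- maxent_features(X, fit$knots)[, fit$keep, drop = FALSE]
  eta <- drop(stats::predict(fit$glmnet, newx = FT, s = fit$lambda,
                             type = "link"))
  stats::plogis(eta + log(fit$W))
}
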