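# Additive (degree-1) multivariate adaptive regression splines, built
# directly: forward selection of reflected hinge pairs by least-squares RSS,
# then backward pruning of individual basis functions by generalized
# cross-validation with the stated penalty (GVL penalty 2.0), and a final
# logistic refit on the surviving basis so scores live on [0, 1].
#
# GCV(k) = (RSS/n) / (1 - C(k)/n)^2 with effective parameter count
# C(k) = k + penalty * (k - 1) / 2, k counting the intercept plus hinge
# columns — the classical accounting where each knot costs `penalty` extra
# parameters shared by its reflected pair.

mars_hinge <- function(x, knot, dir) {
  if (dir > 0) pmax(x - knot, 0) else pmax(knot - x, 0)
}

mars_build_basis <- function(X, terms) {
  n <- nrow(X)
  if (nrow(terms) == 0) return(matrix(1, n, 1))
  cols <- lapply(seq_len(nrow(terms)), function(i)
    mars_hinge(X[, terms$var[i]], terms$knot[i], terms$dir[i]))
  cbind(1, do.call(cbind, cols))
}

fit_mars <- function(X, y, settings, seed) {
  n <- nrow(X)
  vars <- colnames(X)
  K <- settings$n_knots
  cand <- do.call(rbind, lapply(seq_along(vars), function(j) {
    q <- unique(stats::quantile(X[, j], probs = seq(0.05, 0.95,
                                                    length.out = K),
                                type = 7, names = FALSE))
    if (length(q)) data.frame(var = j, knot = q) else NULL
  }))
  penalty <- settings$gcv_penalty
  gcv <- function(rss, k) {
    c_eff <- min(k + penalty * (k - 1) / 2, n - 1)
    (rss / n) / (1 - c_eff / n)^2
  }
  # forward: add the reflected hinge pair with the largest RSS drop
  B <- matrix(1, n, 1)
  terms <- data.frame(var = integer(), knot = numeric(), dir = integer())
  rss <- sum((y - mean(y))^2)
  max_pairs <- max(1, floor((settings$max_terms - 1) / 2))
  taken <- rep(FALSE, nrow(cand))
  for (s in seq_len(max_pairs)) {
    best <- 0L
    best_rss <- rss * (1 - 1e-7)
    for (ci in which(!taken)) {
      H <- cbind(mars_hinge(X[, cand$var[ci]], cand$knot[ci], 1),
                 mars_hinge(X[, cand$var[ci]], cand$knot[ci], -1))
      f <- stats::lm.fit(cbind(B, H), y)
      r <- sum(f$residuals^2)
      if (r < best_rss) { best_rss <- r; best <- ci }
    }
    if (best == 0L) break
    taken[best] <- TRUE
    B <- cbind(B,
               mars_hinge(X[, cand$var[best]], cand$knot[best], 1),
               mars_hinge(X[, cand$var[best]], cand$knot[best], -1))
    terms <- rbind(terms,
                   data.frame(var = rep(cand$var[best], 2),
                              knot = rep(cand$knot[best], 2),
                              dir = c(1L, -1L)))
    rss <- best_rss
  }
  # backward pruning on individual basis columns, keep the GCV-best subset
  fit_rss <- function(act) {
    f <- stats::lm.fit(mars_build_basis(X, terms[act, , drop = FALSE]), y)
    sum(f$residuals^2)
  }
  cur <- seq_len(nrow(terms))
  best_set <- cur
  best_gcv <- gcv(fit_rss(cur), length(cur) + 1)
  while (length(cur) > 0) {
    gcvs <- vapply(seq_along(cur),
                   function(i) gcv(fit_rss(cur[-i]), length(cur)),
                   numeric(1))
    i <- which.min(gcvs)
    cur <- cur[-i]
    if (gcvs[i] <= best_gcv) { best_gcv <- gcvs[i]; best_set <- cur }
  }
  terms_sel <- terms[best_set, , drop = FALSE]
  Bsel <- mars_build_basis(X, terms_sel)
  gfit <- suppressWarnings(stats::glm.fit(Bsel, y,
                                          family = stats::binomial()))
  coefs <- gfit$coefficients
  coefs[is.na(coefs)] <- 0
  list(fit = list(terms = terms_sel, coef = coefs),
       variables_used = if (nrow(terms_sel)) sort(unique(vars[terms_sel$var]))
                        else character(0))
}

predict_mars <- function(fit, X) {
  B <- mars_build_basis(X, fit$terms)
  eta <- drop(B %*% fit$coef)
  stats::plogis(eta)
}
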