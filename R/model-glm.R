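# Bidirectional stepwise logistic regression by AIC. The candidate scope is
# main effects + squared terms + all pairwise interactions of the screened
# variables, capped at `max_terms` candidate terms (combinatorial guard);
# the search starts from the main-effects model.

fit_glm_stepwise <- function(X, y, settings, seed) {
  vars <- colnames(X)
  df <- data.frame(.y = y, X, check.names = FALSE)
  main <- vars
  cand <- main
  if (isTRUE(settings$squared))
    cand <- c(cand, paste0("I(", vars, "^2)"))
  if (isTRUE(settings$interactions) && length(vars) >= 2) {
    cmb <- utils::combn(vars, 2)
    cand <- c(cand, paste0(cmb[1, ], ":", cmb[2, ]))
  }
  if (length(cand) > settings$max_terms)
    cand <- cand[seq_len(settings$max_terms)]
  start_f <- stats::as.formula(paste(".y ~", paste(main, collapse = " + ")))
  upper_f <- stats::as.formula(paste(".y ~", paste(cand, collapse = " + ")))
  fit0 <- suppressWarnings(stats::glm(start_f, data = df,
                                      family = stats::binomial()))
  fit <- suppressWarnings(stats::step(fit0,
                                      scope = list(lower = .y ~ 1,
                                                   upper = upper_f),
                                      direction = "both", trace = 0))
  used <- intersect(vars, all.vars(stats::formula(fit)))
  # slim the model object: drop per-row payloads not needed for prediction
  fit$model <- NULL
  fit$data <- NULL
  fit$y <- NULL
  fit$residuals <- NULL
  fit$fitted.values <- NULL
  fit$weights <- NULL
  fit$prior.weights <- NULL
  fit$linear.predictors <- NULL
  fit$effects <- NULL
  list(fit = list(glm = fit), variables_used = used)
}

predict_glm_stepwise <- function(fit, X) {
  df <- as.data.frame(X)
  suppressWarnings(stats::predict(fit$glm, newdata = df, type = "response"))
}
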