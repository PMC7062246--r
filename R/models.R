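#' Suitability model specifications and the common fitting interface
#'
#' Five algorithm families behind one interface: bidirectional stepwise GLM
#' (AIC, squared terms and pairwise interactions), additive MARS with GCV
#' pruning, stochastic boosted regression trees, a probability random forest,
#' and a maxent-style infinitely-weighted penalized logistic regression on
#' linear + quadratic + hinge features. Every fit is seeded and row-order
#' canonicalized, so the same spec, table and seed reproduce the same model.
#'
#' @name sdm_models
NULL

ALGORITHMS <- c("glm_stepwise", "mars", "brt", "rf", "maxent_like")

default_settings <- function(algorithm) {
  switch(algorithm,
    glm_stepwise = list(squared = TRUE, interactions = TRUE, max_terms = 200,
                        min_presences = 10),
    mars = list(degree = 1, gcv_penalty = 2.0, max_terms = 21, n_knots = 15,
                min_presences = 10),
    brt = list(bag_fraction = 0.5, learning_rate = 0.01, tree_depth = 3,
               n_trees_max = 1500, min_node = 10, holdout_fraction = 0.2,
               min_presences = 10),
    rf = list(n_trees = 1000, mtry = NULL, min_node = 5, max_depth = 0,
              min_presences = 10),
    maxent_like = list(n_hinge_knots = 5, background_weight = 100,
                       reg_multiplier = 1, min_presences = 10),
    stop("unknown algorithm '", algorithm, "'"))
}

#' Model specification
#'
#' @param algorithm one of `"glm_stepwise"`, `"mars"`, `"brt"`, `"rf"`,
#'   `"maxent_like"`.
#' @param background_method `"kde"` or `"target"` (bookkeeping label).
#' @param settings named list of algorithm settings; unset entries take the
#'   documented defaults (BRT bag fraction 0.5, MARS degree 1 with GCV
#'   penalty 2.0, stepwise GLM with squared and interaction terms, ...).
#' @param seed integer seed for the fit's stochastic components.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(algorithm, background_method = c("kde", "target"),
                       settings = list(), seed = 1L) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  background_method <- match.arg(background_method)
  defaults <- default_settings(algorithm)
  unknown <- setdiff(names(settings), names(defaults))
  if (length(unknown))
    stop("unknown setting(s) for ", algorithm, ": ",
         paste(unknown, collapse = ", "))
  defaults[names(settings)] <- settings
  structure(list(algorithm = algorithm,
                 background_method = background_method,
                 settings = defaults, seed = as.integer(seed)),
            class = "model_spec")
}

#' @exportS3Method base::print
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec: %s / %s background, seed %d\n", x$algorithm,
              x$background_method, x$seed))
  invisible(x)
}

#' Fit one suitability model
#'
#' Rows are put into a canonical order before fitting, so the scorer is
#' invariant to the row order of the design table even for the bootstrap
#' based algorithms. Internal-selection algorithms (stepwise GLM, MARS, BRT)
#' report the reduced set in `variables_used`; RF and the maxent-style model
#' retain every variable they are given.
#'
#' @param spec a [model_spec].
#' @param t a design table with both classes.
#' @return Object of class `fitted_model` with `spec`, `variables_used`,
#'   `feature_names` (training column order), `train_auc`, `cv_auc`
#'   (`NA` until [cross_validate]), and `gates`.
#' @export
fit_model <- function(spec, t) {
  vars <- design_vars(t)
  y <- t$response
  if (length(unique(y)) < 2)
    stop("class error: design table has a single class")
  if (sum(y == 1) < spec$settings$min_presences)
    stop("class error: fewer than ", spec$settings$min_presences,
         " presences")
  ord <- do.call(order, c(list(-y), unname(as.list(t[, vars, drop = FALSE])),
                          list(t$x, t$y)))
  X <- as.matrix(t[ord, vars, drop = FALSE])
  y <- y[ord]
  fit <- tryCatch(
    switch(spec$algorithm,
           glm_stepwise = fit_glm_stepwise(X, y, spec$settings, spec$seed),
           mars = fit_mars(X, y, spec$settings, spec$seed),
           brt = fit_brt(X, y, spec$settings, spec$seed),
           rf = fit_rf(X, y, spec$settings, spec$seed),
           maxent_like = fit_maxent_like(X, y, spec$settings, spec$seed)),
    error = function(e)
      stop("fit error in ", spec$algorithm, " (settings: ",
           paste(names(spec$settings), unlist(lapply(spec$settings, format)),
                 sep = "=", collapse = ", "), "): ", conditionMessage(e)))
  m <- structure(list(spec = spec, fit = fit$fit,
                      variables_used = fit$variables_used,
                      feature_names = vars,
                      train_auc = NA_real_, cv_auc = NA_real_,
                      gates = list(overfit_flag = FALSE, dropped = FALSE,
                                   reason = character())),
                 class = "fitted_model")
  m$train_auc <- rank_auc(predict_scores(m, t), t$response)
  m
}

#' @exportS3Method base::print
print.fitted_model <- function(x, ...) {
  cat(sprintf("fitted_model: %s / %s, train AUC %.3f, cv AUC %s\n",
              x$spec$algorithm, x$spec$background_method, x$train_auc,
              if (is.na(x$cv_auc)) "unset" else sprintf("%.3f", x$cv_auc)))
  cat(sprintf("  variables_used: %s\n",
              paste(x$variables_used, collapse = ", ")))
  if (x$gates$overfit_flag || x$gates$dropped)
    cat(sprintf("  gates: overfit=%s dropped=%s (%s)\n",
                x$gates$overfit_flag, x$gates$dropped,
                paste(x$gates$reason, collapse = "; ")))
  invisible(x)
}

#' Score new points with a fitted model
#'
#' @param m a [fit_model] result.
#' @param newdata design table or data.frame containing the model's
#'   `feature_names` columns.
#' @return suitability scores in [0, 1].
#' @export
predict_scores <- function(m, newdata) {
  miss <- setdiff(m$feature_names, names(newdata))
  if (length(miss))
    stop("schema error: missing predictor column(s): ",
         paste(miss, collapse = ", "))
  X <- as.matrix(as.data.frame(newdata)[, m$feature_names, drop = FALSE])
  s <- switch(m$spec$algorithm,
              glm_stepwise = predict_glm_stepwise(m$fit, X),
              mars = predict_mars(m$fit, X),
              brt = predict_brt(m$fit, X),
              rf = predict_rf(m$fit, X),
              maxent_like = predict_maxent_like(m$fit, X))
  pmin(1, pmax(0, as.numeric(s)))
}

#' Predict a suitability raster
#'
#' Applies the scorer to every cell of the stack; nodata wherever any input
#' layer is nodata.
#'
#' @param m a [fit_model] result.
#' @param stack a [raster_stack] containing all of the model's training
#'   layers.
#' @return [raster_grid] of suitabilities in [0, 1].
#' @export
predict_raster <- function(m, stack) {
  miss <- setdiff(m$feature_names, names(stack))
  if (length(miss))
    stop("schema error: stack lacks layer(s): ", paste(miss, collapse = ", "))
  vals <- sapply(m$feature_names,
                 function(nm) rg_values_rowmajor(stack$layers[[nm]]))
  ok <- stats::complete.cases(vals)
  out <- rep(NA_real_, nrow(vals))
  if (any(ok)) {
    df <- as.data.frame(vals[ok, , drop = FALSE])
    names(df) <- m$feature_names
    out[ok] <- predict_scores(m, df)
  }
  rg_from_rowmajor(stack_template(stack), out)
}

#' Apply the overfitting and quality gates
#'
#' `overfit_flag` is set when the train AUC exceeds the cross-validated AUC
#' by more than `overfit_gap`; `dropped` when the cross-validated AUC falls
#' below `min_cv_auc` (or when the caller marks a model still overfit after
#' its re-tuning pass, via `still_overfit`).
#'
#' @param m a [fit_model] result with `cv_auc` filled.
#' @param overfit_gap train-minus-cv AUC gap flagging overfitting
#'   (default 0.05).
#' @param min_cv_auc minimum acceptable cross-validated AUC (default 0.7).
#' @param still_overfit set by the workflow when a re-tuned model remains
#'   overfit; forces `dropped`.
#' @return the model with `gates` filled.
#' @export
apply_gates <- function(m, overfit_gap = 0.05, min_cv_auc = 0.7,
                        still_overfit = FALSE) {
  if (is.na(m$cv_auc))
    stop("ordering error: cv_auc must be filled (run cross_validate) before gates")
  reason <- character()
  overfit <- (m$train_auc - m$cv_auc) > overfit_gap
  if (overfit)
    reason <- c(reason, sprintf("overfit: train-cv AUC gap %.3f > %.3f",
                                m$train_auc - m$cv_auc, overfit_gap))
  dropped <- FALSE
  if (m$cv_auc < min_cv_auc) {
    dropped <- TRUE
    reason <- c(reason, sprintf("dropped: cv AUC %.3f < %.2f", m$cv_auc,
                                min_cv_auc))
  }
  if (still_overfit && overfit) {
    dropped <- TRUE
    reason <- c(reason, "dropped: still overfit after re-tuning")
  }
  m$gates <- list(overfit_flag = overfit, dropped = dropped, reason = reason)
  m
}

#' Stronger-regularization retry settings
#'
#' The automated analog of a human revisiting model-specific parameter
#' settings after an overfitting flag: one documented, per-algorithm step
#' toward a simpler model. Stepwise GLM drops squared and interaction terms;
#' MARS doubles the GCV penalty and halves the term budget; BRT halves the
#' learning rate and shrinks tree depth; RF enlarges terminal nodes and caps
#' depth; the maxent-style model quadruples its regularization multiplier.
#'
#' @param spec a [model_spec].
#' @return a new [model_spec] with the adjusted settings.
#' @export
retune_spec <- function(spec) {
  s <- spec$settings
  s <- switch(spec$algorithm,
    glm_stepwise = utils::modifyList(s, list(squared = FALSE,
                                             interactions = FALSE)),
    mars = utils::modifyList(s, list(gcv_penalty = s$gcv_penalty * 2,
                                     max_terms = max(5, floor(s$max_terms / 2)))),
    brt = utils::modifyList(s, list(learning_rate = s$learning_rate / 2,
                                    tree_depth = max(1, s$tree_depth - 1))),
    rf = utils::modifyList(s, list(min_node = max(20, s$min_node * 4),
                                   max_depth = 12)),
    maxent_like = utils::modifyList(s, list(reg_multiplier = s$reg_multiplier * 4)))
  model_spec(spec$algorithm, spec$background_method, s, spec$seed)
}

#' Fit, cross-validate, gate, and optionally re-tune one model
#'
#' The full per-model pipeline stage: fit on the whole table, 10-fold
#' cross-validation to fill `cv_auc`, gates, and — if the overfit flag is
#' raised — one automated retry with [retune_spec] settings; a second
#' overfit flag drops the model.
#'
#' @param spec a [model_spec].
#' @param t design table.
#' @param k cross-validation folds.
#' @param overfit_gap,min_cv_auc gate parameters.
#' @return list with `model` (gated [fit_model] result), `cv`
#'   (per-fold table), and `retuned` (logical).
#' @export
evaluate_model <- function(spec, t, k = 10, overfit_gap = 0.05,
                           min_cv_auc = 0.7) {
  run_once <- function(sp) {
    m <- fit_model(sp, t)
    cv <- cross_validate(sp, t, k = k, seed = sp$seed)
    m$cv_auc <- cv$metrics$auc_roc
    m$cv_metrics <- cv$metrics
    m$cv_folds <- cv$folds
    list(model = m, cv = cv)
  }
  first <- run_once(spec)
  m <- apply_gates(first$model, overfit_gap, min_cv_auc)
  retuned <- FALSE
  if (m$gates$overfit_flag) {
    retuned <- TRUE
    second <- run_once(retune_spec(spec))
    m2 <- apply_gates(second$model, overfit_gap, min_cv_auc,
                      still_overfit = TRUE)
    m2$gates$reason <- c("re-tuned after overfit flag", m2$gates$reason)
    m <- m2
    first <- second
  }
  list(model = m, cv = first$cv, retuned = retuned)
}
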