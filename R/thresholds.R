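#' Binarization thresholds, ensembles, MESS, and variable importance
#'
#' @name thresholds_ensemble
NULL

#' Compute a binarization threshold
#'
#' Four rules spanning inclusive to restrictive predictions:
#' * `mpp` — minimum predicted presence: the lowest score at any training
#'   presence (most inclusive).
#' * `pct1` / `pct10` — the threshold classifying exactly the lowest
#'   `floor(q n)` training presences (q = 0.01 / 0.10) as unsuitable:
#'   the `(floor(q n) + 1)`-th smallest presence score.
#' * `mss` — the candidate threshold maximizing sensitivity + specificity
#'   (needs background scores too); ties resolved to the lowest threshold.
#'
#' @param rule_kind `"mpp"`, `"pct1"`, `"pct10"`, or `"mss"`.
#' @param presence_scores scores at the training presences.
#' @param all_scores for `mss`: list with `scores` and `labels`
#'   (a scored presence/background set).
#' @return Object of class `threshold_rule` with `kind` and computed `value`.
#' @export
compute_threshold <- function(rule_kind = c("mpp", "pct1", "pct10", "mss"),
                              presence_scores, all_scores = NULL) {
  rule_kind <- match.arg(rule_kind)
  if (length(presence_scores) == 0) stop("empty presence scores")
  value <- switch(rule_kind,
    mpp = min(presence_scores),
    pct1 = pct_threshold(presence_scores, 0.01),
    pct10 = pct_threshold(presence_scores, 0.10),
    mss = {
      if (is.null(all_scores))
        stop("mss threshold needs background scores (all_scores)")
      mss_threshold(all_scores$scores, all_scores$labels)
    })
  structure(list(kind = rule_kind, value = value), class = "threshold_rule")
}

pct_threshold <- function(presence_scores, q) {
  s <- sort(presence_scores)
  s[floor(q * length(s)) + 1]
}

mss_threshold <- function(scores, labels) {
  check_two_classes(labels)
  cand <- sort(unique(scores))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  ss <- vapply(cand, function(th) {
    sum(scores >= th & labels == 1) / n1 +
      sum(scores < th & labels == 0) / n0
  }, numeric(1))
  cand[which.max(ss)]     # first (lowest) maximizer on ties
}

#' Binarize a suitability raster at a threshold
#'
#' Suitable (1) where score >= threshold; nodata propagates.
#'
#' @param suitability a [raster_grid] of scores.
#' @param rule a computed [compute_threshold] result (or a bare number).
#' @return binary [raster_grid].
#' @export
binarize_raster <- function(suitability, rule) {
  thr <- if (inherits(rule, "threshold_rule")) rule$value else rule
  out <- suitability
  out$values <- (suitability$values >= thr) * 1
  out
}

#' Equal-weight binary-map ensemble
#'
#' Cellwise count of retained models predicting suitable habitat. Only
#' non-dropped models should be passed in; `retained_count` records the
#' ensemble denominator rather than rescaling to a fixed model count.
#'
#' @param binaries named list of aligned binary [raster_grid]s.
#' @param rule the [compute_threshold] rule the binaries were made with
#'   (bookkeeping).
#' @return Object of class `ensemble_product` with `binary_layers`,
#'   `ensemble` (integer-count raster) and `retained_count`.
#' @export
build_ensemble <- function(binaries, rule = NULL) {
  stopifnot(length(binaries) >= 1)
  ref <- binaries[[1]]
  acc <- matrix(0, nrow(ref$values), ncol(ref$values))
  anyna <- matrix(FALSE, nrow(ref$values), ncol(ref$values))
  for (nm in names(binaries)) {
    b <- binaries[[nm]]
    if (!identical(dim(b$values), dim(ref$values)) ||
        !isTRUE(all.equal(b$origin, ref$origin)) ||
        !isTRUE(all.equal(b$cell_size, ref$cell_size)))
      stop("alignment error: layer '", nm, "' does not match the ensemble grid")
    v <- b$values
    anyna <- anyna | is.na(v)
    v[is.na(v)] <- 0
    acc <- acc + v
  }
  acc[anyna] <- NA
  structure(list(rule = rule, binary_layers = binaries,
                 ensemble = raster_grid(acc, ref$origin, ref$cell_size,
                                        ref$crs_id),
                 retained_count = length(binaries)),
            class = "ensemble_product")
}

#' @exportS3Method base::print
print.ensemble_product <- function(x, ...) {
  cat(sprintf("ensemble_product: %d retained models%s\n", x$retained_count,
              if (!is.null(x$rule)) paste0(", rule ", x$rule$kind) else ""))
  invisible(x)
}

#' Multivariate environmental similarity surface
#'
#' Per cell and variable, with `f` the percentage of reference values
#' strictly below the cell value `v` and `min`/`max` the reference extremes:
#' `f = 0  ->  100 (v - min) / (max - min)`;
#' `0 < f <= 50  ->  2 f`;
#' `50 < f < 100  ->  2 (100 - f)`;
#' `f = 100  ->  100 (max - v) / (max - min)`.
#' The MESS value is the minimum over variables; negative values flag cells
#' outside the reference range of at least one variable (novel environments
#' where the model extrapolates).
#'
#' @param stack a [raster_stack].
#' @param reference design table of the training rows (presences plus
#'   background by default — restrict upstream for presence-only reference).
#' @param variables variables to include (default: the stack/table overlap).
#' @return Object of class `mess_surface` with `per_variable_similarity`,
#'   `mess` (cellwise minimum [raster_grid]) and `excluded` (degenerate
#'   reference variables).
#' @export
mess_surface <- function(stack, reference,
                         variables = intersect(names(stack),
                                               design_vars(reference))) {
  stopifnot(length(variables) >= 1)
  per_var <- list()
  excluded <- character()
  template <- stack_template(stack)
  mess_vals <- NULL
  for (v in variables) {
    ref <- reference[[v]]
    ref <- ref[is.finite(ref)]
    if (max(ref) == min(ref)) {
      excluded <- c(excluded, v)
      warning("MESS: variable '", v, "' has a degenerate reference range; excluded")
      next
    }
    cell_vals <- rg_values_rowmajor(stack$layers[[v]])
    sim <- mess_similarity(cell_vals, ref)
    per_var[[v]] <- rg_from_rowmajor(template, sim)
    mess_vals <- if (is.null(mess_vals)) sim else pmin(mess_vals, sim)
  }
  if (is.null(mess_vals))
    stop("MESS: every variable had a degenerate reference range")
  structure(list(per_variable_similarity = per_var,
                 mess = rg_from_rowmajor(template, mess_vals),
                 excluded = excluded),
            class = "mess_surface")
}

# similarity of values v to the reference sample (vectorized over v)
mess_similarity <- function(v, ref) {
  n <- length(ref)
  rmin <- min(ref); rmax <- max(ref)
  # count of reference values strictly below each v, via sorted lookup
  f <- 100 * findInterval(v, sort(ref), left.open = TRUE) / n
  f[is.na(v)] <- NA_real_
  out <- ifelse(f == 0, 100 * (v - rmin) / (rmax - rmin),
         ifelse(f <= 50, 2 * f,
         ifelse(f < 100, 2 * (100 - f),
                100 * (rmax - v) / (rmax - rmin))))
  out
}

#' Permutation variable importance (delta AUC)
#'
#' For each variable, its column is shuffled across all rows (presences and
#' background jointly), the model rescored, and the importance reported as
#' the drop in AUC relative to the unpermuted model, averaged over
#' `n_permutations` seeded shuffles. Also reports the normalized percent
#' contribution over positive delta-AUC values.
#'
#' @param m a [fit_model] result.
#' @param t the design table the model was fit on.
#' @param n_permutations shuffles per variable (default 5).
#' @param seed RNG seed.
#' @return Object of class `importance_ranking`: data.frame `per_variable`
#'   (variable, delta_auc, percent_contribution, rank — sorted descending)
#'   plus `n_permutations` and `seed`.
#' @export
permutation_importance <- function(m, t, n_permutations = 5, seed = 1) {
  full_auc <- rank_auc(predict_scores(m, t), t$response)
  vars <- m$feature_names
  delta <- withr_seed(seed, {
    vapply(vars, function(v) {
      drops <- vapply(seq_len(n_permutations), function(i) {
        t2 <- t
        t2[[v]] <- t2[[v]][sample.int(nrow(t2))]
        full_auc - rank_auc(predict_scores(m, t2), t2$response)
      }, numeric(1))
      mean(drops)
    }, numeric(1))
  })
  pos <- pmax(delta, 0)
  pct <- if (sum(pos) > 0) 100 * pos / sum(pos) else rep(0, length(pos))
  per_variable <- data.frame(variable = vars, delta_auc = delta,
                             percent_contribution = pct)
  per_variable <- per_variable[order(-per_variable$delta_auc,
                                     per_variable$variable), ]
  per_variable$rank <- seq_len(nrow(per_variable))
  rownames(per_variable) <- NULL
  structure(list(per_variable = per_variable,
                 n_permutations = n_permutations, seed = as.integer(seed)),
            class = "importance_ranking")
}

#' @exportS3Method base::print
print.importance_ranking <- function(x, ...) {
  cat(sprintf("importance_ranking (%d permutations, seed %d):\n",
              x$n_permutations, x$seed))
  print(x$per_variable, row.names = FALSE)
  invisible(x)
}
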