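#' Predictor harmonization, extraction, and collinearity screening
#'
#' @name predictors
NULL

#' Harmonize a raster onto a template grid (project-aggregate-resample-clip
#' analog)
#'
#' Each output cell takes the value of the source cell whose center is
#' nearest the output cell center (nearest-neighbor resampling); nodata
#' propagates; the result is clipped to the template bounds. Both rasters
#' must already be in the same planar reference system.
#'
#' @param src source [raster_grid].
#' @param template [raster_grid] supplying the output geometry.
#' @return [raster_grid] on the template geometry.
#' @export
parc_harmonize <- function(src, template) {
  ctr <- cell_centers(template)
  # the source cell whose center is nearest a point is the cell containing
  # it (ties on shared edges resolved by the half-open ownership convention);
  # template cells whose centers fall outside source coverage become nodata
  col <- floor((ctr[, 1] - src$origin[1]) / src$cell_size) + 1
  row <- floor((rg_ymax(src) - ctr[, 2]) / src$cell_size) + 1
  inb <- col >= 1 & col <= rg_ncol(src) & row >= 1 & row <= rg_nrow(src)
  if (!any(inb))
    stop("coverage error: template bounds are disjoint from the source raster")
  v <- rep(NA_real_, nrow(ctr))
  v[inb] <- src$values[cbind(row[inb], col[inb])]
  out <- rg_from_rowmajor(template, v)
  out$crs_id <- template$crs_id
  out
}

#' Build the presence/background design table
#'
#' One row per retained point; predictor values are read from the cell
#' containing the point under the half-open ownership convention (see
#' [raster_grid]). Points that fall out of bounds or on a nodata cell in any
#' layer are dropped and counted in the `drop_log` attribute.
#'
#' @param stack a [raster_stack] of screened predictors.
#' @param presences [occurrence_set] or point matrix (response 1).
#' @param background [background_set] or point matrix (response 0).
#' @return `design_table`: a data.frame with `point_id`, `x`, `y`,
#'   `response`, and one column per layer; attribute `drop_log` records
#'   out-of-bounds / nodata drops by class.
#' @export
extract_design_table <- function(stack, presences, background) {
  p_xy <- if (inherits(presences, "occurrence_set")) occ_xy(presences)
          else as_xy(presences)
  b_xy <- if (inherits(background, "background_set")) background$points
          else as_xy(background)
  xy <- rbind(p_xy, b_xy)
  response <- c(rep(1L, nrow(p_xy)), rep(0L, nrow(b_xy)))
  vals <- sapply(stack$layers, function(l) extract_values(l, xy))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1,
                                         dimnames = list(NULL, names(stack)))
  keep <- stats::complete.cases(vals)
  drop_log <- c(presence_dropped = sum(!keep & response == 1),
                background_dropped = sum(!keep & response == 0))
  if (!any(keep))
    stop("extraction error: no points fall on valid cells of the stack")
  out <- data.frame(point_id = seq_len(nrow(xy))[keep],
                    x = xy[keep, 1], y = xy[keep, 2],
                    response = response[keep],
                    vals[keep, , drop = FALSE],
                    check.names = FALSE)
  attr(out, "drop_log") <- drop_log
  class(out) <- c("design_table", "data.frame")
  out
}

design_vars <- function(t) setdiff(names(t), c("point_id", "x", "y", "response"))

#' Kendall's tau-b rank correlation
#'
#' Tie-corrected Kendall coefficient, computed in compiled code by direct
#' pair enumeration.
#'
#' @param x,y numeric vectors of equal length.
#' @return tau-b in `[-1, 1]`, or `NA` for zero-variance input.
#' @export
kendall_tau_b <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  .cpp_kendall_tau_b(as.numeric(x[ok]), as.numeric(y[ok]))
}

#' Pairwise maximum-correlation matrix
#'
#' Entry (i, j) is `max(|Pearson|, |Spearman|, |Kendall tau-b|)` computed on
#' all rows of the design table (presences and background jointly, the SAHM
#' convention; restrict with `rows` to change that). Zero-variance variables
#' get zero entries and are flagged.
#'
#' @param t a design table ([extract_design_table]).
#' @param variables variable names (default: all predictor columns).
#' @param rows optional logical/integer row subset.
#' @param threshold screening threshold carried into the result (default 0.7).
#' @return `correlation_screen`: list with `pairwise_max_r` (symmetric, unit
#'   diagonal), `per_coefficient` matrices, `threshold`, `zero_variance`,
#'   and empty `retained`/`removed` slots filled by [select_uncorrelated].
#' @export
max_correlation_matrix <- function(t, variables = design_vars(t), rows = NULL,
                                   threshold = 0.7) {
  if (!is.null(rows)) t <- t[rows, , drop = FALSE]
  stopifnot(nrow(t) >= 3)
  X <- as.matrix(t[, variables, drop = FALSE])
  p <- ncol(X)
  zero_var <- apply(X, 2, function(v) stats::sd(v, na.rm = TRUE) == 0 ||
                                        !is.finite(stats::sd(v, na.rm = TRUE)))
  pear <- abs(suppressWarnings(stats::cor(X, method = "pearson")))
  spear <- abs(suppressWarnings(stats::cor(X, method = "spearman")))
  kend <- matrix(0, p, p, dimnames = dimnames(pear))
  diag(kend) <- 1
  if (p >= 2) {
    for (i in 1:(p - 1)) for (j in (i + 1):p) {
      if (!zero_var[i] && !zero_var[j]) {
        k <- abs(kendall_tau_b(X[, i], X[, j]))
        kend[i, j] <- kend[j, i] <- if (is.na(k)) 0 else k
      }
    }
  }
  pear[!is.finite(pear)] <- 0
  spear[!is.finite(spear)] <- 0
  m <- pmax(pear, spear, kend)
  m[zero_var, ] <- 0
  m[, zero_var] <- 0
  diag(m) <- 1
  structure(list(pairwise_max_r = m,
                 per_coefficient = list(pearson = pear, spearman = spear,
                                        kendall = kend),
                 threshold = threshold,
                 zero_variance = names(zero_var)[zero_var],
                 retained = character(), removed = list()),
            class = "correlation_screen")
}

#' Drop collinear variables
#'
#' Iteratively, while any retained pair exceeds the threshold, removes the
#' lower-priority member of the worst pair. With `priority = "auto"` the
#' removed variable is the one with the larger mean absolute correlation to
#' all other retained variables (ties broken lexicographically). With an
#' explicit priority order, the member appearing later in (or absent from)
#' the list is removed.
#'
#' @param screen a [max_correlation_matrix] result.
#' @param priority `"auto"` or an ordered character vector (most important
#'   first).
#' @return The screen with `retained` and `removed` filled; each removal
#'   records the triggering pair and correlation.
#' @export
select_uncorrelated <- function(screen, priority = "auto") {
  m <- screen$pairwise_max_r
  retained <- rownames(m)
  removed <- list()
  repeat {
    sub <- m[retained, retained, drop = FALSE]
    diag(sub) <- 0
    if (length(retained) < 2 || max(sub) <= screen$threshold) break
    worst <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    a <- retained[worst[1]]; b <- retained[worst[2]]
    if (identical(priority, "auto")) {
      mean_r <- function(v) mean(sub[v, setdiff(retained, v)])
      drop_var <- if (mean_r(a) > mean_r(b)) a
                  else if (mean_r(b) > mean_r(a)) b
                  else sort(c(a, b))[2]     # tie: keep lexicographic first
    } else {
      rank_of <- function(v) { i <- match(v, priority); if (is.na(i)) Inf else i }
      drop_var <- if (rank_of(a) <= rank_of(b)) b else a
    }
    removed[[drop_var]] <- list(pair = c(a, b), r = unname(max(sub)))
    retained <- setdiff(retained, drop_var)
  }
  screen$retained <- retained
  screen$removed <- removed
  screen
}

#' @exportS3Method base::print
print.correlation_screen <- function(x, ...) {
  cat(sprintf("correlation_screen: %d variables, threshold %.2f\n",
              nrow(x$pairwise_max_r), x$threshold))
  if (length(x$retained))
    cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  for (nm in names(x$removed))
    cat(sprintf("  removed %s (pair %s-%s, r = %.3f)\n", nm,
                x$removed[[nm]]$pair[1], x$removed[[nm]]$pair[2],
                x$removed[[nm]]$r))
  invisible(x)
}

#' Write the correlation screen report
#' @param screen a [correlation_screen].
#' @param matrix_csv path for the max-|r| matrix CSV.
#' @param removals_csv path for the removals log CSV.
#' @export
write_correlation_report <- function(screen, matrix_csv, removals_csv) {
  utils::write.csv(screen$pairwise_max_r, matrix_csv)
  rem <- if (length(screen$removed)) {
    do.call(rbind, lapply(names(screen$removed), function(nm) {
      r <- screen$removed[[nm]]
      data.frame(removed = nm, pair_a = r$pair[1], pair_b = r$pair[2],
                 max_abs_r = r$r)
    }))
  } else data.frame(removed = character(), pair_a = character(),
                    pair_b = character(), max_abs_r = numeric())
  utils::write.csv(rem, removals_csv, row.names = FALSE)
  invisible(matrix_csv)
}
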