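#' Synthetic landscapes, virtual species, and biased samples
#'
#' A stated test world for the whole pipeline: smooth correlated predictor
#' rasters (Gaussian random fields), a parametric logistic suitability
#' function with known driving variables, presence samples drawn
#' proportionally to suitability (optionally through a sampling-bias field),
#' a target-guild occurrence table, and toy management-unit polygons. The
#' fixture CRS is a synthetic planar system with 90-unit cells, mirroring
#' the 90 m analysis convention.
#'
#' @name synthetic_fixtures
NULL

# isotropic Gaussian smoothing by FFT circular convolution
smooth_field <- function(m, range_cells) {
  nr <- nrow(m); nc <- ncol(m)
  di <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dj <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  kern <- exp(-0.5 * (outer(di^2, dj^2, "+")) / range_cells^2)
  kern <- kern / sum(kern)
  Re(stats::fft(stats::fft(m) * stats::fft(kern), inverse = TRUE)) / (nr * nc)
}

#' Generate a stack of correlated Gaussian-random-field predictors
#'
#' Independent white-noise fields are smoothed by FFT convolution with a
#' Gaussian kernel of scale `spatial_range` cells, standardized, then mixed
#' by the Cholesky factor of the requested cross-correlation matrix and
#' standardized again, so each layer has mean ~0, sd 1 and the requested
#' pairwise correlations.
#'
#' @param n_vars number of layers (named `x1..xk`).
#' @param shape `(rows, cols)`, at least 32 x 32.
#' @param spatial_range smoothing scale in cells.
#' @param inter_var_correlation `"independent"` or a positive-definite
#'   correlation matrix.
#' @param seed RNG seed.
#' @param cell_size map units per cell (default 90).
#' @param crs_id fixture reference-system label.
#' @return A [raster_stack].
#' @export
generate_landscape <- function(n_vars, shape = c(128, 128), spatial_range = 8,
                               inter_var_correlation = "independent",
                               seed = 1, cell_size = 90,
                               crs_id = "synthetic-albers-90") {
  stopifnot(all(shape >= 32))
  if (!identical(inter_var_correlation, "independent")) {
    C <- as.matrix(inter_var_correlation)
    stopifnot(nrow(C) == n_vars, ncol(C) == n_vars)
    L <- tryCatch(t(chol(C)),
                  error = function(e) stop("correlation matrix is not positive-definite"))
  } else {
    L <- diag(n_vars)
  }
  fields <- withr_seed(seed, {
    sapply(seq_len(n_vars), function(i) {
      f <- smooth_field(matrix(stats::rnorm(prod(shape)), shape[1], shape[2]),
                        spatial_range)
      as.vector(f)
    })
  })
  # smoothing leaves sizeable chance correlations between layers (the
  # effective sample size is the number of independent patches, not cells);
  # whiten empirically so the realized cross-correlations equal the request
  fields <- scale(fields, center = TRUE, scale = FALSE)
  white <- fields %*% solve(chol(stats::cov(fields)))
  mixed <- white %*% t(L)
  layers <- list()
  for (i in seq_len(n_vars)) {
    v <- mixed[, i]
    v <- (v - mean(v)) / stats::sd(v)
    layers[[paste0("x", i)]] <- raster_grid(matrix(v, shape[1], shape[2]),
                                            c(0, 0), cell_size, crs_id)
  }
  raster_stack(layers)
}

#' Define a virtual species on a landscape
#'
#' Suitability is the inverse logit of
#' `beta0 + sum_i beta_i x_i + sum_i gamma_i x_i^2` evaluated cellwise.
#'
#' @param stack a [raster_stack].
#' @param coefficients list with `intercept` (scalar), `linear` (named
#'   vector) and optional `quadratic` (named vector); names must be stack
#'   layers.
#' @return Object of class `virtual_species` with `coefficients`,
#'   `suitability` ([raster_grid] in (0, 1)) and `driving_variables`.
#' @export
make_virtual_species <- function(stack, coefficients) {
  beta0 <- coefficients$intercept %||% 0
  lin <- coefficients$linear %||% numeric()
  quad <- coefficients$quadratic %||% numeric()
  unknown <- setdiff(c(names(lin), names(quad)), names(stack))
  if (length(unknown))
    stop("unknown variable(s) in coefficients: ",
         paste(unknown, collapse = ", "))
  template <- stack_template(stack)
  eta <- rep(beta0, prod(dim(template$values)))
  for (v in names(lin)) eta <- eta + lin[[v]] * rg_values_rowmajor(stack$layers[[v]])
  for (v in names(quad)) eta <- eta + quad[[v]] * rg_values_rowmajor(stack$layers[[v]])^2
  driving <- sort(unique(c(names(lin)[lin != 0], names(quad)[quad != 0])))
  structure(list(coefficients = list(intercept = beta0, linear = lin,
                                     quadratic = quad),
                 suitability = rg_from_rowmajor(template, stats::plogis(eta)),
                 driving_variables = driving),
            class = "virtual_species")
}

#' Sample biased presence records from a virtual species
#'
#' Cells are drawn with replacement with probability proportional to
#' suitability times the bias field; records are placed at cell centers with
#' complete metadata (post-1980 observation dates, `"observation"` type,
#' 1 m uncertainty) so they pass the default occurrence filters untouched.
#'
#' @param vs a [make_virtual_species] result.
#' @param n number of records.
#' @param bias `"uniform"` or a nonnegative [raster_grid] aligned with the
#'   suitability raster.
#' @param seed RNG seed.
#' @param species_name recorded species label.
#' @return An [occurrence_set].
#' @export
sample_presences <- function(vs, n, bias = "uniform", seed = 1,
                             species_name = "Virtualis exemplaris") {
  stopifnot(n >= 1)
  g <- vs$suitability
  w <- rg_values_rowmajor(g)
  if (!identical(bias, "uniform")) {
    w <- w * pmax(0, rg_values_rowmajor(bias))
  }
  w[is.na(w)] <- 0
  if (sum(w) <= 0) stop("zero total sampling weight")
  centers <- cell_centers(g)
  idx <- withr_seed(seed, sample.int(length(w), n, replace = TRUE, prob = w))
  records <- data.frame(
    species_name = species_name,
    x = centers[idx, 1], y = centers[idx, 2],
    event_date = as.Date("2000-01-01") + (idx %% 3650),
    record_type = "observation",
    coordinate_uncertainty_m = 1,
    source = "synthetic",
    stringsAsFactors = FALSE)
  occurrence_set(records, crs_id = g$crs_id)
}

#' Synthetic target-guild occurrence table
#'
#' Records of "similar species" sampled proportionally to a bias field
#' (uniform by default), each labelled with a lifeform drawn from
#' `lifeforms`, emulating the prepared introduced-species table the
#' target-background scheme consumes.
#'
#' @param template a [raster_grid] giving the landscape extent.
#' @param n number of records.
#' @param lifeforms character vector of lifeform labels to cycle through.
#' @param bias `"uniform"` or a nonnegative [raster_grid].
#' @param seed RNG seed.
#' @return An [occurrence_set] whose records carry a `lifeform` column.
#' @export
synthetic_target_occurrences <- function(template, n,
                                         lifeforms = c("grass", "forb"),
                                         bias = "uniform", seed = 1) {
  w <- if (identical(bias, "uniform")) rep(1, prod(dim(template$values)))
       else pmax(0, rg_values_rowmajor(bias))
  w[is.na(w)] <- 0
  centers <- cell_centers(template)
  res <- withr_seed(seed, {
    idx <- sample.int(length(w), n, replace = TRUE, prob = w)
    lf <- sample(lifeforms, n, replace = TRUE)
    list(idx = idx, lf = lf)
  })
  records <- data.frame(
    species_name = paste0("Guildus sp", match(res$lf, lifeforms)),
    x = centers[res$idx, 1], y = centers[res$idx, 2],
    event_date = as.Date("2005-06-15"),
    record_type = "observation",
    coordinate_uncertainty_m = 1,
    source = "synthetic-target",
    lifeform = res$lf,
    stringsAsFactors = FALSE)
  occurrence_set(records, crs_id = template$crs_id)
}

#' Toy management units tiling part of a landscape
#'
#' An `nx` by `ny` grid of square units covering the template extent,
#' inset slightly so unit boundaries do not coincide with raster edges.
#'
#' @param template a [raster_grid].
#' @param nx,ny unit grid dimensions.
#' @return list of [management_unit]s.
#' @export
make_toy_units <- function(template, nx = 2, ny = 2) {
  x0 <- template$origin[1]; y0 <- template$origin[2]
  w <- (rg_xmax(template) - x0) * 0.9 / nx
  h <- (rg_ymax(template) - y0) * 0.9 / ny
  ox <- x0 + 0.05 * (rg_xmax(template) - x0)
  oy <- y0 + 0.05 * (rg_ymax(template) - y0)
  units <- list()
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    xa <- ox + (i - 1) * w; ya <- oy + (j - 1) * h
    poly <- cbind(x = c(xa, xa + w, xa + w, xa),
                  y = c(ya, ya, ya + h, ya + h))
    units[[paste0("unit_", i, "_", j)]] <-
      management_unit(paste0("unit_", i, "_", j), poly)
  }
  units
}
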