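#' Background (pseudo-absence) generation
#'
#' Two schemes: (1) density-weighted sampling from a Gaussian kernel density
#' estimate of the presences, restricted to a buffered minimum convex polygon
#' — the background sample density then correlates with presence density,
#' up-weighting the invasion front; (2) target-guild sampling, which reuses
#' occurrence records of similar species (same lifeform) inside a 99% KDE
#' isopleth of the focal presences, mimicking the sampling bias of the
#' presence data.
#'
#' @name background
NULL

#' Buffered minimum convex polygon sampling extent
#'
#' Convex hull of the presences dilated uniformly by one third of the larger
#' coordinate range: `buffer = (1/3) * max(x_max - x_min, y_max - y_min)`.
#' (A per-axis reading of that rule exists; `per_axis = TRUE` buffers by a
#' rectangle-anisotropic amount approximated as the mean of the two.)
#'
#' @param presences two-column point matrix or [occurrence_set].
#' @param per_axis use mean of the per-axis buffers instead of their max.
#' @param n_arc arc discretization for the dilation.
#' @return A `sampling_extent` (construction `"buffered_mcp"`).
#' @export
buffered_mcp <- function(presences, per_axis = FALSE, n_arc = 24) {
  pts <- if (inherits(presences, "occurrence_set")) occ_xy(presences)
         else as_xy(presences)
  if (nrow(unique(pts)) < 3)
    stop("degenerate geometry: need >= 3 distinct presence points")
  hull <- convex_hull(pts)
  if (nrow(hull) < 3 || polygon_area(hull) <= 0)
    stop("degenerate geometry: presence points are collinear")
  rx <- diff(range(pts[, 1])); ry <- diff(range(pts[, 2]))
  buffer <- if (per_axis) mean(c(rx, ry)) / 3 else max(rx, ry) / 3
  poly <- buffer_convex_polygon(hull, buffer, n_arc = n_arc)
  sampling_extent(polygon = poly, construction = "buffered_mcp",
                  buffer_distance = buffer)
}

#' Sampling extent container
#'
#' Either a polygon (buffered MCP) or a binary cell mask (polygonized KDE
#' isopleth region), with its construction recorded.
#'
#' @param polygon vertex matrix or `NULL`.
#' @param mask binary [raster_grid] or `NULL`.
#' @param construction `"buffered_mcp"` or `"isopleth_99"` (any isopleth mass
#'   label).
#' @param buffer_distance map units (buffered MCP only).
#' @export
sampling_extent <- function(polygon = NULL, mask = NULL,
                            construction = c("buffered_mcp", "isopleth"),
                            buffer_distance = NULL) {
  if (is.null(polygon) && is.null(mask))
    stop("sampling_extent needs a polygon or a mask")
  structure(list(polygon = polygon, mask = mask,
                 construction = construction[1],
                 buffer_distance = buffer_distance),
            class = "sampling_extent")
}

#' Membership test for a sampling extent
#' @param extent a [sampling_extent].
#' @param xy two-column point matrix.
#' @return logical vector.
#' @export
extent_contains <- function(extent, xy) {
  xy <- as_xy(xy)
  if (!is.null(extent$polygon)) return(points_in_polygon(xy, extent$polygon))
  v <- extract_values(extent$mask, xy)
  !is.na(v) & v > 0
}

#' Gaussian kernel density estimate of presence locations
#'
#' Product Gaussian kernel with per-axis bandwidths. `bandwidth = "auto"`
#' applies the two-dimensional Silverman rule of thumb per axis,
#' `h_i = sd_i * n^(-1/6)` (the d = 2 case of `sigma * n^(-1/(d+4))`;
#' the univariate `n^(-1/5)` rule undersmooths spatial point data).
#'
#' @param presences point matrix or [occurrence_set].
#' @param bandwidth `"auto"`, a scalar, or a length-2 vector (x, y) in map
#'   units.
#' @return Object of class `kernel_density` with `support_points` and
#'   per-axis `bandwidth`.
#' @export
fit_kde <- function(presences, bandwidth = "auto") {
  pts <- if (inherits(presences, "occurrence_set")) occ_xy(presences)
         else as_xy(presences)
  if (nrow(unique(pts)) < 2)
    stop("bandwidth error: need >= 2 distinct points for a KDE")
  if (identical(bandwidth, "auto")) {
    h <- c(stats::sd(pts[, 1]), stats::sd(pts[, 2])) * nrow(pts)^(-1 / 6)
  } else {
    h <- rep(as.numeric(bandwidth), length.out = 2)
  }
  if (any(!is.finite(h)) || any(h <= 0))
    stop("bandwidth error: nonpositive bandwidth (identical coordinates?)")
  structure(list(support_points = pts, bandwidth = h),
            class = "kernel_density")
}

#' Evaluate a KDE at arbitrary points
#' @param k a [fit_kde] result.
#' @param xy two-column point matrix.
#' @return density values (integrates to 1 over the plane).
#' @export
kde_density <- function(k, xy) {
  xy <- as_xy(xy)
  sp <- k$support_points
  hx <- k$bandwidth[1]; hy <- k$bandwidth[2]
  n <- nrow(sp)
  dx <- outer(xy[, 1], sp[, 1], "-") / hx
  dy <- outer(xy[, 2], sp[, 2], "-") / hy
  rowSums(exp(-0.5 * (dx * dx + dy * dy))) / (n * 2 * pi * hx * hy)
}

#' Discretize a KDE on a raster grid
#' @param k a [fit_kde] result.
#' @param template a [raster_grid] supplying the analysis grid.
#' @return [raster_grid] of density at cell centers.
#' @export
kde_grid <- function(k, template) {
  d <- kde_density(k, cell_centers(template))
  rg_from_rowmajor(template, d)
}

#' KDE isopleth region
#'
#' The smallest set of grid cells (by density level) whose enclosed density
#' mass reaches `mass`: cells are sorted by density descending (ties broken
#' by cell index) and accumulated until `sum(density * cell_area) >= mass`.
#'
#' @param k a [fit_kde] result.
#' @param mass enclosed probability mass, in (0, 1); 0.99 for the target-guild
#'   extent.
#' @param template analysis [raster_grid].
#' @return [sampling_extent] with a binary mask (construction
#'   `"isopleth_<mass>"`).
#' @export
kde_isopleth <- function(k, mass, template) {
  stopifnot(mass > 0, mass < 1)
  d <- kde_density(k, cell_centers(template))
  cell_area <- template$cell_size^2
  ord <- order(-d, seq_along(d))         # density desc, ties by cell index
  cum <- cumsum(d[ord]) * cell_area
  total <- sum(d) * cell_area
  # masses are relative to the grid-captured total so a wide-enough grid
  # encloses >= mass of the full integral; when the grid IS the study area
  # (e.g. a synthetic landscape) the isopleth is relative to available mass
  if (total < mass)
    warning(sprintf(paste0("grid captures only %.3f of the KDE mass; ",
                           "the %g isopleth is relative to the captured mass"),
                    total, mass))
  ncells <- which(cum >= min(mass, total * (1 - 1e-12)))[1]
  keep <- ord[seq_len(ncells)]
  m <- numeric(length(d))
  m[keep] <- 1
  sampling_extent(mask = rg_from_rowmajor(template, m),
                  construction = sprintf("isopleth_%g", mass))
}

#' Background point set
#' @param points two-column matrix.
#' @param method `"kde"` or `"target"`.
#' @param seed integer used to draw the sample.
#' @param extent the [sampling_extent] the points were drawn in.
#' @export
background_set <- function(points, method, seed, extent) {
  points <- as_xy(points)
  structure(list(points = points, method = method, n = nrow(points),
                 seed = as.integer(seed), extent = extent),
            class = "background_set")
}

#' @exportS3Method base::print
print.background_set <- function(x, ...) {
  cat(sprintf("background_set: %d points, method '%s', seed %d (extent: %s)\n",
              x$n, x$method, x$seed, x$extent$construction))
  invisible(x)
}

#' Density-weighted KDE background sample
#'
#' Discretizes the KDE on the analysis grid, zeroes cells outside the extent,
#' and draws `n` cells with replacement with probability proportional to the
#' restricted density; points are the sampled cell centers. Reproducible by
#' `seed`.
#'
#' @param k a [fit_kde] result built from the same presences as `extent`.
#' @param extent [sampling_extent] (typically [buffered_mcp]).
#' @param n number of background points (the workflow default is 10,000).
#' @param seed RNG seed.
#' @param template analysis [raster_grid].
#' @return A [background_set] with `method = "kde"`.
#' @export
sample_kde_background <- function(k, extent, n, seed, template) {
  stopifnot(n >= 1)
  centers <- cell_centers(template)
  d <- kde_density(k, centers)
  inside <- extent_contains(extent, centers)
  d[!inside] <- 0
  if (sum(d) <= 0)
    stop("sampling error: extent and density are disjoint on this grid")
  withr_seed(seed, {
    idx <- sample.int(length(d), size = n, replace = TRUE, prob = d)
  })
  background_set(centers[idx, , drop = FALSE], "kde", seed, extent)
}

# run code under a temporary RNG seed without disturbing the caller's RNG
withr_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Target-guild background sample
#'
#' Occurrence records of similar species (matching `lifeform_filter` on the
#' record's lifeform attribute) clipped to `region` (typically the 99% KDE
#' isopleth of the focal presences). If more than `n` remain, a seeded simple
#' random subsample of `n` is taken; otherwise all are kept and `n` shrinks.
#'
#' @param target_occurrences an [occurrence_set] whose records carry a
#'   `lifeform` column.
#' @param lifeform_filter lifeform value(s) to keep (e.g., `"grass"`).
#' @param region a [sampling_extent].
#' @param n maximum number of background points.
#' @param seed RNG seed for the subsample.
#' @return A [background_set] with `method = "target"`.
#' @export
sample_target_background <- function(target_occurrences, lifeform_filter,
                                     region, n, seed) {
  r <- target_occurrences$records
  if (is.null(r$lifeform))
    stop("target occurrences must carry a 'lifeform' column")
  r <- r[r$lifeform %in% lifeform_filter, , drop = FALSE]
  if (nrow(r) == 0)
    stop("empty-target error: no records match lifeform '",
         paste(lifeform_filter, collapse = "/"), "'")
  pts <- as_xy(r[, c("x", "y")])
  inside <- extent_contains(region, pts)
  pts <- pts[inside, , drop = FALSE]
  if (nrow(pts) == 0)
    stop("empty-target error: no matching records inside the region")
  if (nrow(pts) > n) {
    withr_seed(seed, {
      pts <- pts[sample.int(nrow(pts), n), , drop = FALSE]
    })
  }
  background_set(pts, "target", seed, region)
}

#' Write background points as CSV (and the extent polygon as GeoJSON)
#' @param b a [background_set].
#' @param csv_path output CSV (x, y, method, seed).
#' @param geojson_path optional polygon output (skipped for mask extents).
#' @export
write_background <- function(b, csv_path, geojson_path = NULL) {
  utils::write.csv(data.frame(x = b$points[, 1], y = b$points[, 2],
                              method = b$method, seed = b$seed),
                   csv_path, row.names = FALSE)
  if (!is.null(geojson_path) && !is.null(b$extent$polygon))
    write_polygon_geojson(b$extent$polygon, geojson_path,
                          properties = list(construction = b$extent$construction))
  invisible(csv_path)
}
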