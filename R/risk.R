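#' Management-unit risk summaries
#'
#' Regional/local interpretation of the ensemble maps: per-unit suitable
#' area and percent, occurrence counts, distance to the nearest known
#' occurrence, and evaluation of independent points against the ensemble.
#' Cell membership is decided by the cell-center-in-polygon test; distances
#' are Euclidean in the projected plane.
#'
#' @name risk_assessment
NULL

#' Management unit polygon
#'
#' @param name unit label.
#' @param polygon vertex matrix (open ring) in map units.
#' @return Object of class `management_unit` with derived `area`.
#' @export
management_unit <- function(name, polygon) {
  polygon <- as_xy(polygon)
  area <- polygon_area(polygon)
  if (!is.finite(area) || area <= 0) stop("invalid unit polygon: area <= 0")
  structure(list(name = name, polygon = polygon, area = area),
            class = "management_unit")
}

ACRE_M2 <- 4046.8564224
HECTARE_M2 <- 1e4

#' Per-unit suitable habitat summary
#'
#' Suitable cells are those where at least `min_agreement` retained models
#' agree (default: at least half, `ceiling(retained_count / 2)`). For each
#' unit, the suitable area is the count of suitable cells whose centers fall
#' inside the polygon times the cell area; occurrence counts and nearest
#' distances are included when occurrences are supplied. Areas are emitted in
#' map units squared plus hectares and acres (1 ha = 1e4 m², 1 acre =
#' 4046.8564224 m²) under the equal-area map-unit = meter convention.
#'
#' @param ensemble an [build_ensemble] product.
#' @param units list of [management_unit]s.
#' @param min_agreement model-count threshold for "suitable".
#' @param occurrences optional [occurrence_set] for counts/distances.
#' @return data.frame, one row per unit, with `unit_name`, `suitable_area`
#'   (map units squared), `suitable_ha`, `suitable_acres`,
#'   `percent_of_unit`, and when occurrences were given
#'   `n_occurrences_inside` and `min_distance_to_occurrence` (0 whenever an
#'   occurrence lies inside or on the boundary).
#' @export
zonal_risk_summary <- function(ensemble, units,
                               min_agreement = ceiling(ensemble$retained_count / 2),
                               occurrences = NULL) {
  g <- ensemble$ensemble
  centers <- cell_centers(g)
  counts <- rg_values_rowmajor(g)
  suitable <- !is.na(counts) & counts >= min_agreement
  cell_area <- g$cell_size^2
  occ_pts <- if (!is.null(occurrences)) occ_xy(occurrences) else NULL
  rows <- lapply(units, function(u) {
    inside_bounds <- any(centers[, 1] >= min(u$polygon[, 1]) &
                           centers[, 1] <= max(u$polygon[, 1]) &
                           centers[, 2] >= min(u$polygon[, 2]) &
                           centers[, 2] <= max(u$polygon[, 2]))
    if (!inside_bounds) {
      warning("unit '", u$name, "' lies outside the raster bounds")
      return(data.frame(unit_name = u$name, suitable_area = NA_real_,
                        suitable_ha = NA_real_, suitable_acres = NA_real_,
                        percent_of_unit = NA_real_))
    }
    # bounding-box prefilter, then exact cell-center-in-polygon test
    bb <- centers[, 1] >= min(u$polygon[, 1]) - g$cell_size &
      centers[, 1] <= max(u$polygon[, 1]) + g$cell_size &
      centers[, 2] >= min(u$polygon[, 2]) - g$cell_size &
      centers[, 2] <= max(u$polygon[, 2]) + g$cell_size
    idx <- which(bb)
    in_poly <- idx[points_in_polygon(centers[idx, , drop = FALSE], u$polygon)]
    n_suit <- sum(suitable[in_poly])
    area <- n_suit * cell_area
    data.frame(unit_name = u$name, suitable_area = area,
               suitable_ha = area / HECTARE_M2,
               suitable_acres = area / ACRE_M2,
               percent_of_unit = 100 * area / u$area)
  })
  out <- do.call(rbind, rows)
  if (!is.null(occ_pts)) {
    out$n_occurrences_inside <- vapply(units, function(u)
      sum(points_in_polygon(occ_pts, u$polygon)), numeric(1))
    out$min_distance_to_occurrence <- vapply(units, function(u)
      nearest_occurrence_distance(u, occurrences), numeric(1))
  }
  rownames(out) <- NULL
  out
}

#' Distance from a unit to the nearest known occurrence
#'
#' 0 when any occurrence lies within or on the unit boundary; otherwise the
#' minimum Euclidean point-to-boundary distance in map units.
#'
#' @param unit a [management_unit].
#' @param occurrences a nonempty [occurrence_set].
#' @export
nearest_occurrence_distance <- function(unit, occurrences) {
  pts <- occ_xy(occurrences)
  if (nrow(pts) == 0) stop("empty occurrence set")
  min(dist_to_polygon(pts, unit$polygon))
}

#' Evaluate independent points against per-rule ensembles
#'
#' For each threshold rule, a histogram of the ensemble count values at the
#' independent points — how many occurrences were captured at each ensemble
#' agreement level. Points outside the raster bounds are dropped and logged.
#'
#' @param ensembles named list of [build_ensemble] products (name = rule).
#' @param points an [occurrence_set] of independent occurrences.
#' @return data.frame with `rule`, `ensemble_value`, `count`; attribute
#'   `n_dropped` counts out-of-bounds points per rule.
#' @export
independent_point_evaluation <- function(ensembles, points) {
  pts <- occ_xy(points)
  rows <- list()
  dropped <- integer()
  for (nm in names(ensembles)) {
    v <- extract_values(ensembles[[nm]]$ensemble, pts)
    dropped[[nm]] <- sum(is.na(v))
    v <- v[!is.na(v)]
    if (length(v)) {
      tab <- table(factor(v, levels = 0:max(ensembles[[nm]]$retained_count)))
      rows[[nm]] <- data.frame(rule = nm,
                               ensemble_value = as.integer(names(tab)),
                               count = as.integer(tab))
    } else {
      rows[[nm]] <- data.frame(rule = character(), ensemble_value = integer(),
                               count = integer())
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}
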