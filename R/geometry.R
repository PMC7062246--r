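#' Planar polygon utilities
#'
#' Minimal computational geometry for the workflow: convex hulls, uniform
#' dilation of convex polygons, point-in-polygon tests and point-to-polygon
#' distances. All coordinates are planar map units (an equal-area projection
#' is assumed upstream); distances are Euclidean in that plane.
#'
#' @name geometry
#' @keywords internal
NULL

as_xy <- function(pts) {
  if (is.data.frame(pts)) pts <- as.matrix(pts[, c("x", "y")])
  pts <- as.matrix(pts)
  storage.mode(pts) <- "double"
  colnames(pts) <- c("x", "y")
  pts
}

#' Convex hull of a point set
#'
#' @param pts two-column matrix or data.frame with `x`, `y`.
#' @return Matrix of hull vertices in counter-clockwise order (not closed).
#' @export
convex_hull <- function(pts) {
  pts <- as_xy(pts)
  h <- grDevices::chull(pts)          # clockwise
  out <- pts[rev(h), , drop = FALSE]  # counter-clockwise
  out
}

#' Signed / absolute polygon area (shoelace)
#' @param poly vertex matrix (open ring).
#' @export
polygon_area <- function(poly) {
  poly <- as_xy(poly)
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Dilate a convex polygon by a fixed distance
#'
#' Minkowski sum of a convex ring with a disc of radius `d`, approximated by
#' `n_arc` points per vertex arc. Every point of the input polygon ends up at
#' distance >= d from the output boundary.
#'
#' @param poly convex vertex matrix, counter-clockwise.
#' @param d dilation distance (map units), > 0.
#' @param n_arc arc discretization points per vertex.
#' @export
buffer_convex_polygon <- function(poly, d, n_arc = 24) {
  poly <- as_xy(poly)
  stopifnot(d > 0, nrow(poly) >= 3)
  n <- nrow(poly)
  out <- list()
  for (i in seq_len(n)) {
    p_prev <- poly[if (i == 1) n else i - 1, ]
    p <- poly[i, ]
    p_next <- poly[if (i == n) 1 else i + 1, ]
    # outward normals of incoming and outgoing edges (CCW ring: outward = right)
    e1 <- p - p_prev; e2 <- p_next - p
    n1 <- c(e1[2], -e1[1]) / sqrt(sum(e1^2))
    n2 <- c(e2[2], -e2[1]) / sqrt(sum(e2^2))
    a1 <- atan2(n1[2], n1[1]); a2 <- atan2(n2[2], n2[1])
    if (a2 < a1) a2 <- a2 + 2 * pi   # normals rotate CCW along a CCW ring
    angles <- seq(a1, a2, length.out = max(2L, n_arc))
    arc <- cbind(p[1] + d * cos(angles), p[2] + d * sin(angles))
    out[[i]] <- arc
  }
  res <- do.call(rbind, out)
  colnames(res) <- c("x", "y")
  res
}

#' Point-in-polygon test (even-odd rule, boundary inclusive)
#'
#' @param pts two-column matrix of query points.
#' @param poly polygon vertex matrix (open ring).
#' @param tol boundary tolerance in map units.
#' @return logical vector.
#' @export
points_in_polygon <- function(pts, poly, tol = 1e-9) {
  pts <- as_xy(pts); poly <- as_xy(poly)
  n <- nrow(poly)
  j <- c(2:n, 1)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- poly[j, 1]; y2 <- poly[j, 2]
  vapply(seq_len(nrow(pts)), function(k) {
    px <- pts[k, 1]; py <- pts[k, 2]
    # boundary check
    if (min(dist_point_segments(px, py, x1, y1, x2, y2)) <= tol) return(TRUE)
    crossings <- sum((y1 > py) != (y2 > py) &
                       (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1))
    crossings %% 2 == 1
  }, logical(1))
}

# vectorized distance from one point to many segments
dist_point_segments <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  t <- ifelse(len2 > 0, ((px - x1) * dx + (py - y1) * dy) / len2, 0)
  t <- pmin(1, pmax(0, t))
  cx <- x1 + t * dx; cy <- y1 + t * dy
  sqrt((px - cx)^2 + (py - cy)^2)
}

#' Distance from points to a polygon (0 if inside or on the boundary)
#'
#' @inheritParams points_in_polygon
#' @return numeric vector of distances in map units.
#' @export
dist_to_polygon <- function(pts, poly) {
  pts <- as_xy(pts); poly <- as_xy(poly)
  n <- nrow(poly)
  j <- c(2:n, 1)
  inside <- points_in_polygon(pts, poly)
  out <- numeric(nrow(pts))
  for (k in which(!inside)) {
    out[k] <- min(dist_point_segments(pts[k, 1], pts[k, 2],
                                      poly[, 1], poly[, 2],
                                      poly[j, 1], poly[j, 2]))
  }
  out
}

#' Write / read a simple polygon as GeoJSON
#'
#' Single-ring Polygon features; enough to interchange sampling extents and
#' management-unit boundaries as text.
#'
#' @param poly vertex matrix (open ring).
#' @param path output file.
#' @param properties named list stored as feature properties.
#' @export
write_polygon_geojson <- function(poly, path, properties = list()) {
  poly <- as_xy(poly)
  ring <- rbind(poly, poly[1, , drop = FALSE])
  gj <- list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature",
      properties = properties,
      geometry = list(type = "Polygon",
                      coordinates = list(unname(apply(ring, 1, c,
                                                      simplify = FALSE))))
    ))
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_polygon_geojson
#' @param polys named list of vertex matrices (one feature each; the name is
#'   stored as the `name` property).
#' @export
write_polygons_geojson <- function(polys, path) {
  feats <- lapply(names(polys), function(nm) {
    poly <- as_xy(polys[[nm]])
    ring <- rbind(poly, poly[1, , drop = FALSE])
    list(type = "Feature", properties = list(name = nm),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(apply(ring, 1, c,
                                                         simplify = FALSE)))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_polygon_geojson
#' @return `read_polygons_geojson` returns a named list of vertex matrices
#'   (one per feature; name taken from a `name` property when present).
#' @export
read_polygons_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  out <- list()
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    colnames(m) <- c("x", "y")
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    nm <- f$properties$name
    out[[if (is.null(nm)) paste0("feature_", i) else nm]] <- m
  }
  out
}
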