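#' Lightweight single-band planar raster
#'
#' A `raster_grid` holds a rectangular lattice of numeric cell values on a
#' planar (projected, typically equal-area) coordinate system. Row 1 of the
#' value matrix is the northernmost row, matching how grid rasters are stored
#' on disk in the ESRI ASCII grid format this package reads and writes.
#' Nodata is represented as `NA` in memory.
#'
#' Cell-ownership convention (used everywhere points meet rasters): cells are
#' half-open. A point with `x` exactly on a shared vertical edge belongs to
#' the cell to its right; a point with `y` exactly on a shared horizontal edge
#' belongs to the cell below it in map space. Consequently the valid domain is
#' `x in [x0, x0 + ncol * cell_size)` and `y in (y0, y0 + nrow * cell_size]`
#' where `(x0, y0)` is the lower-left corner.
#'
#' @param values numeric matrix; row 1 = top (north).
#' @param origin numeric length-2, lower-left corner `(x0, y0)` in map units.
#' @param cell_size positive cell edge length in map units.
#' @param crs_id free-text identifier of the planar reference system.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, origin = c(0, 0), cell_size = 90,
                        crs_id = "planar") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.numeric(origin), length(origin) == 2L, all(is.finite(origin)),
            is.numeric(cell_size), length(cell_size) == 1L, cell_size > 0)
  structure(list(values = values, origin = as.numeric(origin),
                 cell_size = as.numeric(cell_size), crs_id = crs_id),
            class = "raster_grid")
}

#' @exportS3Method base::print
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid: %d x %d cells, cell_size %g, origin (%g, %g), crs '%s'\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2], x$crs_id))
  v <- x$values[!is.na(x$values)]
  if (length(v)) cat(sprintf("  values: [%g, %g], %d nodata cells\n",
                             min(v), max(v), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

rg_ncol <- function(g) ncol(g$values)
rg_nrow <- function(g) nrow(g$values)
rg_xmax <- function(g) g$origin[1] + rg_ncol(g) * g$cell_size
rg_ymax <- function(g) g$origin[2] + rg_nrow(g) * g$cell_size

#' Cell-center coordinates of every cell
#'
#' @param g a [raster_grid].
#' @return A two-column matrix (x, y), in row-major order over the value
#'   matrix (all columns of row 1, then row 2, ...).
#' @export
cell_centers <- function(g) {
  xs <- g$origin[1] + (seq_len(rg_ncol(g)) - 0.5) * g$cell_size
  ys <- rg_ymax(g) - (seq_len(rg_nrow(g)) - 0.5) * g$cell_size
  cbind(x = rep(xs, times = rg_nrow(g)), y = rep(ys, each = rg_ncol(g)))
}

# row-major linear index helpers matching cell_centers() ordering
rg_values_rowmajor <- function(g) as.vector(t(g$values))
rg_from_rowmajor <- function(g, v) {
  raster_grid(matrix(v, nrow = rg_nrow(g), ncol = rg_ncol(g), byrow = TRUE),
              g$origin, g$cell_size, g$crs_id)
}

#' Locate points on the grid
#'
#' Applies the half-open cell-ownership convention documented in
#' [raster_grid]. Out-of-bounds points get `NA` row/col.
#'
#' @param g a [raster_grid].
#' @param xy two-column matrix of point coordinates.
#' @return data.frame with columns `row`, `col` (1-based; `NA` out of bounds).
#' @export
cell_index <- function(g, xy) {
  xy <- as.matrix(xy)
  col <- floor((xy[, 1] - g$origin[1]) / g$cell_size) + 1
  row <- floor((rg_ymax(g) - xy[, 2]) / g$cell_size) + 1
  bad <- col < 1 | col > rg_ncol(g) | row < 1 | row > rg_nrow(g)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Read cell values under points
#'
#' @inheritParams cell_index
#' @return numeric vector; `NA` for out-of-bounds points or nodata cells.
#' @export
extract_values <- function(g, xy) {
  rc <- cell_index(g, xy)
  out <- rep(NA_real_, nrow(rc))
  ok <- !is.na(rc$row)
  out[ok] <- g$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Aligned multi-layer raster stack
#'
#' @param layers named list of [raster_grid] objects sharing geometry.
#' @return Object of class `raster_stack`.
#' @export
raster_stack <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1L,
            !is.null(names(layers)), all(nzchar(names(layers))))
  ref <- layers[[1]]
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (!inherits(l, "raster_grid"))
      stop("layer '", nm, "' is not a raster_grid")
    if (!identical(dim(l$values), dim(ref$values)) ||
        !isTRUE(all.equal(l$origin, ref$origin)) ||
        !isTRUE(all.equal(l$cell_size, ref$cell_size)))
      stop("layer '", nm, "' is not aligned with layer '", names(layers)[1], "'")
  }
  structure(list(layers = layers), class = "raster_stack")
}

#' @exportS3Method base::print
print.raster_stack <- function(x, ...) {
  cat(sprintf("raster_stack: %d layers [%s], %d x %d cells\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              nrow(x$layers[[1]]$values), ncol(x$layers[[1]]$values)))
  invisible(x)
}

#' @export
names.raster_stack <- function(x) names(x$layers)

stack_template <- function(stack) stack$layers[[1]]

#' Write / read a raster as ESRI ASCII grid
#'
#' Plain-text single-band raster interchange; nodata written as the
#' `nodata` sentinel value.
#'
#' @param g a [raster_grid].
#' @param path file path (.asc).
#' @param nodata sentinel written for `NA` cells.
#' @export
write_asc <- function(g, path, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", rg_ncol(g)),
    sprintf("nrows %d", rg_nrow(g)),
    sprintf("xllcorner %.10g", g$origin[1]),
    sprintf("yllcorner %.10g", g$origin[2]),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %g", nodata)), con)
  v <- g$values
  v[is.na(v)] <- nodata
  # %.17g round-trips doubles exactly, keeping replays bit-identical
  writeLines(apply(v, 1, function(r) paste(sprintf("%.17g", r),
                                           collapse = " ")), con)
  invisible(path)
}

#' @rdname write_asc
#' @param crs_id reference-system label to attach on read (the format itself
#'   does not carry one).
#' @export
read_asc <- function(path, crs_id = "planar") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  raster_grid(m, c(hdr$xllcorner, hdr$yllcorner), hdr$cellsize, crs_id)
}
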