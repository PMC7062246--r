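#' Occurrence record sets
#'
#' An `occurrence_set` is an ordered table of presence records with the
#' provenance fields the cleaning rules need (record type, event date,
#' coordinate uncertainty, source), a planar CRS label, and a `filter_log`
#' counting how many records each cleaning rule removed. Coordinates are
#' assumed to be already projected to a planar equal-area system; geographic
#' coordinates must be reprojected upstream.
#'
#' @param records data.frame with columns `species_name`, `x`, `y`,
#'   `event_date` (`Date`, may be `NA`), `record_type`
#'   (`"observation"`, `"specimen"`, `"other"`), `coordinate_uncertainty_m`
#'   (nonnegative, may be `NA`), `source`.
#' @param crs_id text identifier of the planar reference system.
#' @param filter_log named numeric vector of per-rule removal counts.
#' @return Object of class `occurrence_set`.
#' @export
occurrence_set <- function(records, crs_id = "planar", filter_log = numeric()) {
  required <- c("species_name", "x", "y", "event_date", "record_type",
                "coordinate_uncertainty_m", "source")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop("occurrence records missing column(s): ",
         paste(missing_cols, collapse = ", "))
  stopifnot(all(is.finite(records$x)), all(is.finite(records$y)))
  u <- records$coordinate_uncertainty_m
  if (any(!is.na(u) & u < 0)) stop("coordinate_uncertainty_m must be >= 0")
  structure(list(records = records, crs_id = crs_id,
                 filter_log = filter_log),
            class = "occurrence_set")
}

#' @exportS3Method base::print
print.occurrence_set <- function(x, ...) {
  cat(sprintf("occurrence_set: %d records, crs '%s'\n",
              nrow(x$records), x$crs_id))
  if (length(x$filter_log)) {
    cat("  filter_log:\n")
    for (nm in names(x$filter_log))
      cat(sprintf("    %s: %d removed\n", nm, x$filter_log[[nm]]))
  }
  invisible(x)
}

occ_xy <- function(s) as_xy(s$records[, c("x", "y")])

#' Load occurrence records from a delimited file
#'
#' One record per row. Unparseable dates and uncertainties become `NA` —
#' nothing is dropped at load time; dropping is the filter step's job.
#'
#' @param path CSV/TSV file path (delimiter sniffed from the extension,
#'   comma by default).
#' @param column_map named character vector mapping the canonical field names
#'   (see [occurrence_set]) to the file's column names. Defaults accept
#'   DarwinCore-flavoured headers.
#' @param crs_id reference-system label for the coordinates in the file.
#' @return An [occurrence_set] with an empty filter log.
#' @export
load_occurrences <- function(path,
                             column_map = c(
                               species_name = "species_name",
                               x = "x", y = "y",
                               event_date = "eventDate",
                               record_type = "basisOfRecord",
                               coordinate_uncertainty_m = "coordinateUncertaintyInMeters",
                               source = "source"),
                             crs_id = "planar") {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (field in c("species_name", "x", "y")) {
    col <- column_map[[field]]
    if (is.null(col) || !col %in% names(raw))
      stop("schema error: mapped column '", col %||% field,
           "' for field '", field, "' not found in ", path)
  }
  get_col <- function(field, default) {
    col <- column_map[[field]]
    if (!is.null(col) && col %in% names(raw)) return(raw[[col]])
    # canonical field names are accepted regardless of the map, so files the
    # package itself wrote reload without a custom map
    if (field %in% names(raw)) return(raw[[field]])
    default
  }
  n <- nrow(raw)
  parse_date <- function(v) {
    v <- as.character(v)
    v[!nzchar(trimws(v %||% ""))] <- NA
    # accept full dates or bare years
    d <- as.Date(rep(NA_character_, length(v)))
    full <- suppressWarnings(as.Date(v, optional = TRUE,
                                     tryFormats = c("%Y-%m-%d", "%Y/%m/%d",
                                                    "%m/%d/%Y")))
    d[!is.na(full)] <- full[!is.na(full)]
    yr <- grepl("^\\s*\\d{4}\\s*$", v) & is.na(d)
    if (any(yr)) d[yr] <- as.Date(paste0(trimws(v[yr]), "-01-01"))
    d
  }
  norm_type <- function(v) {
    v <- tolower(trimws(as.character(v)))
    out <- rep("other", length(v))
    out[grepl("observation|humanobservation|machineobservation", v)] <- "observation"
    out[grepl("specimen", v)] <- "specimen"
    out[v %in% c("observation", "specimen")] <- v[v %in% c("observation", "specimen")]
    out
  }
  records <- data.frame(
    species_name = as.character(get_col("species_name", NA_character_)),
    x = as.numeric(raw[[column_map[["x"]]]]),
    y = as.numeric(raw[[column_map[["y"]]]]),
    event_date = parse_date(get_col("event_date", rep(NA_character_, n))),
    record_type = norm_type(get_col("record_type", rep("other", n))),
    coordinate_uncertainty_m =
      suppressWarnings(as.numeric(get_col("coordinate_uncertainty_m",
                                          rep(NA_real_, n)))),
    source = as.character(get_col("source", rep(basename(path), n))),
    stringsAsFactors = FALSE)
  u <- records$coordinate_uncertainty_m
  records$coordinate_uncertainty_m[!is.na(u) & u < 0] <- NA_real_
  occurrence_set(records, crs_id = crs_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply the occurrence cleaning rules
#'
#' Retains records whose type is in `allowed_types`, whose event year is
#' `>= min_year`, and whose coordinate uncertainty is `<= max_uncertainty_m`
#' (boundary inclusive). Records with missing date or uncertainty are removed
#' under the default strict reading; set the `keep_missing_*` switches to
#' retain them. The retained set is a pure conjunction of the rules (order
#' independent); the filter log attributes each removal to the first failing
#' rule in the fixed order type, date, uncertainty, so counts always sum to
#' `input - retained`.
#'
#' @param s an [occurrence_set].
#' @param min_year earliest acceptable event year (default 1980).
#' @param max_uncertainty_m largest acceptable coordinate uncertainty in
#'   meters (default 30, inclusive).
#' @param allowed_types record types retained (default observation, specimen).
#' @param keep_missing_uncertainty retain records with `NA` uncertainty?
#' @param keep_missing_date retain records with `NA` date?
#' @return Filtered [occurrence_set] with an updated filter log.
#' @export
filter_occurrences <- function(s, min_year = 1980, max_uncertainty_m = 30,
                               allowed_types = c("observation", "specimen"),
                               keep_missing_uncertainty = FALSE,
                               keep_missing_date = FALSE) {
  r <- s$records
  yr <- as.integer(format(r$event_date, "%Y"))
  pass_type <- r$record_type %in% allowed_types
  pass_date <- ifelse(is.na(yr), keep_missing_date, yr >= min_year)
  pass_unc <- ifelse(is.na(r$coordinate_uncertainty_m),
                     keep_missing_uncertainty,
                     r$coordinate_uncertainty_m <= max_uncertainty_m)
  keep <- pass_type & pass_date & pass_unc
  log_add <- c(record_type = sum(!pass_type),
               event_date = sum(pass_type & !pass_date),
               coordinate_uncertainty = sum(pass_type & pass_date & !pass_unc))
  occurrence_set(r[keep, , drop = FALSE], s$crs_id,
                 merge_filter_log(s$filter_log, log_add))
}

merge_filter_log <- function(old, add) {
  old <- as.list(old)
  for (nm in names(add))
    old[[nm]] <- (if (is.null(old[[nm]])) 0 else old[[nm]]) + add[[nm]]
  unlist(old)
}

#' Remove centroid artifacts and collapse per-cell duplicates
#'
#' Records within `centroid_tol_m` of any supplied centroid coordinate
#' (administrative centroids are a common georeferencing artifact) are
#' removed. Remaining records are snapped to a `snap_cell_m` grid and
#' collapsed to the first record encountered per cell — per-cell thinning is
#' what model fitting needs, and exact coordinate duplicates are the special
#' case of a shared cell.
#'
#' @param s an [occurrence_set].
#' @param centroid_points optional two-column matrix of centroid coordinates.
#' @param centroid_tol_m removal radius around each centroid (map units).
#' @param snap_cell_m duplicate-collapse grid size (default 90, the analysis
#'   cell analog). Cell index is `floor(coord / snap_cell_m)`.
#' @return Deduplicated [occurrence_set]; removals logged by cause.
#' @export
deduplicate_and_flag <- function(s, centroid_points = NULL,
                                 centroid_tol_m = 100, snap_cell_m = 90) {
  r <- s$records
  near_centroid <- rep(FALSE, nrow(r))
  if (!is.null(centroid_points) && NROW(centroid_points) > 0) {
    cp <- as_xy(centroid_points)
    for (i in seq_len(nrow(cp))) {
      d <- sqrt((r$x - cp[i, 1])^2 + (r$y - cp[i, 2])^2)
      near_centroid <- near_centroid | d <= centroid_tol_m
    }
  }
  r2 <- r[!near_centroid, , drop = FALSE]
  key <- paste(floor(r2$x / snap_cell_m), floor(r2$y / snap_cell_m))
  dup <- duplicated(key)
  log_add <- c(centroid = sum(near_centroid), duplicate_cell = sum(dup))
  occurrence_set(r2[!dup, , drop = FALSE], s$crs_id,
                 merge_filter_log(s$filter_log, log_add))
}

#' Write a cleaned occurrence set as CSV plus a JSON filter log
#'
#' @param s an [occurrence_set].
#' @param csv_path output CSV; the filter log goes to `log_path`.
#' @param log_path output JSON path (default: csv path with `_filterlog.json`).
#' @export
write_occurrences <- function(s, csv_path,
                              log_path = sub("\\.csv$", "_filterlog.json",
                                             csv_path)) {
  utils::write.csv(s$records, csv_path, row.names = FALSE)
  jsonlite::write_json(list(crs_id = s$crs_id,
                            retained = nrow(s$records),
                            filter_log = as.list(s$filter_log)),
                       log_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
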