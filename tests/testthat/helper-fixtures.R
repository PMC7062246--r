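# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except files the tests themselves write to tempdirs.

# tiny aligned stack on a 90-unit grid
toy_stack <- function(nr = 8, nc = 8, cell = 90, layers = c("a", "b")) {
  raster_stack(stats::setNames(lapply(seq_along(layers), function(i) {
    raster_grid(matrix(seq_len(nr * nc) * i, nr, nc, byrow = TRUE),
                c(0, 0), cell, "toy")
  }), layers))
}

# occurrence records data.frame with full metadata
occ_records <- function(x, y, date = as.Date("2005-06-15"),
                        type = "observation", unc = 1, species = "Testus") {
  n <- length(x)
  data.frame(species_name = rep(species, length.out = n), x = x, y = y,
             event_date = rep(as.Date(date), length.out = n),
             record_type = rep(type, length.out = n),
             coordinate_uncertainty_m = rep(unc, length.out = n),
             source = rep("test", length.out = n), stringsAsFactors = FALSE)
}

toy_occurrences <- function(x, y, ...) occurrence_set(occ_records(x, y, ...),
                                                      crs_id = "toy")

# standard medium-size recovery world shared by model tests (cached per run)
recovery_world <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    stack <- generate_landscape(4, c(64, 64), spatial_range = 12, seed = 101)
    vs <- make_virtual_species(stack, list(intercept = 0,
                                           linear = c(x1 = 3, x2 = -3)))
    occ <- sample_presences(vs, 300, seed = 102)
    bg <- background_set(cell_centers(stack$layers[[1]])[
      withr_seed(103, sample.int(64 * 64, 1500, replace = TRUE)), ],
      method = "kde", seed = 103,
      extent = sampling_extent(mask = raster_grid(matrix(1, 64, 64),
                                                  c(0, 0), 90, "toy"),
                               construction = "isopleth"))
    t <- extract_design_table(stack, occ, bg)
    cache <<- list(stack = stack, vs = vs, occ = occ, bg = bg, table = t)
    cache
  }
})
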