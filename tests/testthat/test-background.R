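test_that("buffered_mcp computes the 1/3-max-range buffer", {
  e <- buffered_mcp(cbind(c(0, 3, 0), c(0, 0, 3)))
  expect_equal(e$buffer_distance, 1)            # (1/3) * max(3, 3)
  e <- buffered_mcp(cbind(c(0, 6, 0), c(0, 0, 3)))
  expect_equal(e$buffer_distance, 2)            # (1/3) * max(6, 3)
  expect_error(buffered_mcp(cbind(c(0, 1), c(0, 1))), "degenerate")
  expect_error(buffered_mcp(cbind(c(0, 1, 2), c(0, 1, 2))), "degenerate")
})

test_that("buffered_mcp polygon contains every presence with margin", {
  withr_seed(7, {
    for (i in 1:5) {
      pts <- cbind(runif(20, 0, 100), runif(20, 0, 60))
      e <- buffered_mcp(pts)
      expect_true(all(points_in_polygon(pts, e$polygon)))
      # hull vertices sit at least buffer_distance inside the dilated ring
      hull <- convex_hull(pts)
      for (k in seq_len(nrow(hull))) {
        shifted <- sweep(e$polygon, 2, hull[k, ])
        expect_gte(min(sqrt(rowSums(shifted^2))), e$buffer_distance - 1e-6)
      }
    }
  })
})

test_that("fit_kde gives a normalized, symmetric density", {
  # quadrature on a wide grid integrates to ~1
  pts <- cbind(c(0, 10, 5, 2), c(0, 0, 8, 3))
  k <- fit_kde(pts, bandwidth = 2)
  g <- raster_grid(matrix(0, 100, 100), c(-45, -45), 1)
  d <- kde_density(k, cell_centers(g))
  expect_equal(sum(d) * 1, 1, tolerance = 1e-2)
  # two equal clusters: density symmetric about the midline
  k2 <- fit_kde(cbind(c(-5, 5), c(0, 0)), bandwidth = 1)
  expect_equal(kde_density(k2, cbind(-3, 0)), kde_density(k2, cbind(3, 0)))
  expect_gt(kde_density(k2, cbind(-5, 0)), kde_density(k2, cbind(0, 0)))
  expect_error(fit_kde(cbind(c(1, 1), c(2, 2))), "bandwidth error")
})

test_that("kde_isopleth regions are nested and enclose the stated mass", {
  withr_seed(11, {
    pts <- cbind(rnorm(80, 50, 6), rnorm(80, 50, 6))
  })
  k <- fit_kde(pts)
  template <- raster_grid(matrix(0, 120, 120), c(-10, -10), 1)
  iso50 <- kde_isopleth(k, 0.50, template)
  iso99 <- kde_isopleth(k, 0.99, template)
  # centroid inside the 99% region
  expect_true(extent_contains(iso99, cbind(mean(pts[, 1]), mean(pts[, 2]))))
  # nesting
  m50 <- iso50$mask$values; m99 <- iso99$mask$values
  expect_true(all(m99[m50 == 1] == 1))
  # quadrature mass of the region >= 0.99
  d <- kde_density(k, cell_centers(template))
  inside <- extent_contains(iso99, cell_centers(template))
  expect_gte(sum(d[inside]) * template$cell_size^2, 0.99)
})

test_that("sample_kde_background is seeded, in-extent, and density-weighted", {
  withr_seed(13, {
    pts <- rbind(cbind(rnorm(60, 30, 3), rnorm(60, 30, 3)),  # dense cluster
                 cbind(90, 90))                               # isolated point
  })
  k <- fit_kde(pts)
  ext <- buffered_mcp(pts)
  template <- raster_grid(matrix(0, 64, 64), c(-30, -30), 2.5)
  b1 <- sample_kde_background(k, ext, 500, seed = 5, template = template)
  b2 <- sample_kde_background(k, ext, 500, seed = 5, template = template)
  expect_identical(b1$points, b2$points)
  expect_true(all(extent_contains(ext, b1$points)))
  # sampled density near the cluster exceeds density near the isolated point
  near <- function(b, p, r) sum(sqrt((b$points[, 1] - p[1])^2 +
                                       (b$points[, 2] - p[2])^2) < r)
  expect_gt(near(b1, c(30, 30), 10), near(b1, c(90, 90), 10))
})

test_that("sample_target_background filters, clips, and subsamples", {
  template <- raster_grid(matrix(0, 32, 32), c(0, 0), 10)
  region <- sampling_extent(polygon = cbind(x = c(0, 160, 160, 0),
                                            y = c(0, 0, 320, 320)),
                            construction = "isopleth")
  tgt <- synthetic_target_occurrences(template, 40,
                                      lifeforms = c("grass", "forb"),
                                      seed = 3)
  b <- sample_target_background(tgt, "grass", region, 1000, seed = 9)
  in_region <- extent_contains(region, occ_xy(tgt))
  is_grass <- tgt$records$lifeform == "grass"
  expect_equal(b$n, sum(in_region & is_grass))   # fewer than n: all retained
  expect_true(all(extent_contains(region, b$points)))
  # subsampling path: ask for fewer than available, seeded
  b1 <- sample_target_background(tgt, c("grass", "forb"), region, 5, seed = 9)
  b2 <- sample_target_background(tgt, c("grass", "forb"), region, 5, seed = 9)
  expect_identical(b1$points, b2$points)
  expect_equal(b1$n, 5)
  # no matches -> empty-target error
  expect_error(sample_target_background(tgt, "tree", region, 10, seed = 1),
               "empty-target")
  far_region <- sampling_extent(polygon = cbind(x = c(1e5, 1e5 + 1, 1e5),
                                                y = c(0, 0, 1)),
                                construction = "isopleth")
  expect_error(sample_target_background(tgt, "grass", far_region, 10, 1),
               "empty-target")
})

test_that("kde background cell frequencies track the density (chi-square)", {
  withr_seed(17, {
    pts <- cbind(rnorm(100, 40, 8), rnorm(100, 40, 8))
  })
  k <- fit_kde(pts)
  template <- raster_grid(matrix(0, 40, 40), c(0, 0), 2)
  ext <- buffered_mcp(pts)
  centers <- cell_centers(template)
  d <- kde_density(k, centers)
  d[!extent_contains(ext, centers)] <- 0
  p <- d / sum(d)
  chisq <- vapply(c(1e3, 1e4), function(n) {
    b <- sample_kde_background(k, ext, n, seed = 21, template = template)
    counts <- tabulate(match(paste(b$points[, 1], b$points[, 2]),
                             paste(centers[, 1], centers[, 2])),
                       nbins = nrow(centers))
    keep <- p > 0
    # per-draw chi-square: expectation ~ (#cells)/n, so it must shrink as n
    # grows if the empirical frequencies converge to the restricted density
    sum((counts[keep] - n * p[keep])^2 / (n * p[keep])) / n
  }, numeric(1))
  expect_lt(chisq[2], chisq[1])
})
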