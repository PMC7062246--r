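test_that("the four threshold rules match their hand-derived values", {
  expect_equal(compute_threshold("mpp", c(0.2, 0.5, 0.9))$value, 0.2)
  # n = 10, pct10: exactly floor(0.1*10) = 1 presence below the threshold
  p <- seq(0.1, 1.0, by = 0.1)
  expect_equal(compute_threshold("pct10", p)$value, 0.2)
  expect_equal(compute_threshold("pct1", p)$value, 0.1)  # floor(0.01*10)=0
  all_s <- list(scores = c(0.9, 0.8, 0.7, 0.2, 0.3, 0.6),
                labels = c(1, 1, 1, 0, 0, 0))
  expect_equal(compute_threshold("mss", c(0.9, 0.8, 0.7), all_s)$value, 0.7)
  expect_error(compute_threshold("mpp", numeric()), "empty")
  expect_error(compute_threshold("mss", c(0.5)), "background")
})

test_that("mss equals exhaustive enumeration and breaks ties low", {
  brute_mss <- function(s, y) {
    cand <- sort(unique(s))
    ss <- sapply(cand, function(th) mean(s[y == 1] >= th) +
                                      mean(s[y == 0] < th))
    cand[which(ss == max(ss))[1]]
  }
  withr_seed(41, {
    for (i in 1:40) {
      n <- sample(6:200, 1)
      y <- c(1, 0, rbinom(n - 2, 1, 0.4))
      s <- round(runif(n), 2)
      expect_equal(compute_threshold("mss", s[y == 1],
                                     list(scores = s, labels = y))$value,
                   brute_mss(s, y))
    }
  })
})

test_that("threshold ordering mpp <= pct1 <= pct10 and exact exclusion counts", {
  withr_seed(47, {
    for (i in 1:200) {
      n <- sample(5:300, 1)
      p <- runif(n)
      t_mpp <- compute_threshold("mpp", p)$value
      t_1 <- compute_threshold("pct1", p)$value
      t_10 <- compute_threshold("pct10", p)$value
      expect_lte(t_mpp, t_1)
      expect_lte(t_1, t_10)
      # the stated convention: exactly floor(q n) presences misclassified
      expect_equal(sum(p < t_10), floor(0.10 * n))
      expect_equal(sum(p < t_1), floor(0.01 * n))
      expect_equal(sum(p < t_mpp), 0)
    }
  })
})

test_that("binarize_raster applies the >= convention and keeps nodata", {
  g <- raster_grid(matrix(c(0.4, 0.5, 0.6, NA), 2, 2), c(0, 0), 90)
  b <- binarize_raster(g, 0.5)
  expect_equal(as.vector(b$values), c(0, 1, 1, NA))
  expect_equal(sum(binarize_raster(g, 0)$values, na.rm = TRUE), 3)
})

test_that("ensembles sum cellwise and record the retained count", {
  mk <- function(v) raster_grid(matrix(v, 3, 3, byrow = TRUE), c(0, 0), 90)
  b1 <- mk(c(1, 1, 0, 0, 1, 0, 0, 0, 1))
  b2 <- mk(c(1, 0, 0, 1, 1, 0, 0, 0, 0))
  b3 <- mk(c(1, 1, 1, 0, 1, 0, 0, 0, 0))
  e <- build_ensemble(list(a = b1, b = b2, c = b3))
  expect_equal(as.vector(t(e$ensemble$values)),
               c(3, 2, 1, 1, 3, 0, 0, 0, 1))
  expect_equal(e$retained_count, 3)
  # conservation: total count equals sum of per-layer suitable cells
  expect_equal(sum(e$ensemble$values),
               sum(b1$values) + sum(b2$values) + sum(b3$values))
  # misalignment
  off <- raster_grid(matrix(0, 3, 3), c(5, 0), 90)
  expect_error(build_ensemble(list(a = b1, b = off)), "alignment error")
})

test_that("MESS reproduces the hand-computed reference cases", {
  ref_table <- structure(data.frame(point_id = 1:5, x = 1:5, y = 1:5,
                                    response = c(1, 1, 1, 0, 0),
                                    v = c(2, 4, 6, 8, 10),
                                    w = c(0, 25, 50, 75, 100)),
                         class = c("design_table", "data.frame"))
  mk <- function(vals) raster_grid(matrix(vals, 1, 3), c(0, 0), 90)
  stack <- raster_stack(list(v = mk(c(6, 1, 12)), w = mk(c(50, 50, 50))))
  ms <- mess_surface(stack, ref_table)
  sim_v <- as.vector(ms$per_variable_similarity$v$values)
  expect_equal(sim_v, c(80, -12.5, -25))   # f=40 -> 2f; below min; above max
  # mess = min over variables: w at 50 has f=40 -> 80
  expect_equal(as.vector(ms$mess$values), c(80, -12.5, -25))
})

test_that("MESS is <= 100, equals 100 only at f = 50, negative iff novel", {
  ref_table <- structure(data.frame(point_id = 1:4, x = 1:4, y = 1:4,
                                    response = c(1, 1, 0, 0),
                                    g = c(1, 2, 3, 4)),
                         class = c("design_table", "data.frame"))
  # gradient layer sweeping through and beyond the reference range
  vals <- seq(-1, 6, by = 0.25)
  stack <- raster_stack(list(g = raster_grid(matrix(vals, 1, length(vals)),
                                             c(0, 0), 90)))
  ms <- mess_surface(stack, ref_table)
  sim <- as.vector(ms$mess$values)
  expect_true(all(sim <= 100))
  # f=50 holds exactly where two of the four references lie strictly below
  expect_equal(vals[sim == 100], c(2.25, 2.5, 2.75, 3))
  expect_equal(sim < 0, vals < 1 | vals > 4)
  # degenerate reference variable is excluded with a warning
  ref_table$flat <- 7
  stack2 <- raster_stack(c(stack$layers,
                           list(flat = raster_grid(matrix(0, 1, length(vals)),
                                                   c(0, 0), 90))))
  expect_warning(ms2 <- mess_surface(stack2, ref_table), "degenerate")
  expect_equal(ms2$excluded, "flat")
})

test_that("permutation importance ranks the driving variable first", {
  w <- recovery_world()
  m <- fit_model(model_spec("rf", settings = list(n_trees = 300), seed = 9),
                 w$table)
  imp <- permutation_importance(m, w$table, n_permutations = 3, seed = 13)
  expect_setequal(imp$per_variable$variable[1:2], c("x1", "x2"))
  # noise variables sit near zero (the rf memorizes a little training noise,
  # so its bar is loose; the smooth maxent-style model gets the tight band)
  expect_lt(max(abs(imp$per_variable$delta_auc[
    imp$per_variable$variable %in% c("x3", "x4")])), 0.1)
  m2 <- fit_model(model_spec("maxent_like", seed = 9), w$table)
  imp2 <- permutation_importance(m2, w$table, n_permutations = 3, seed = 13)
  # band widened from the asymptotic +/-0.02 to 0.03 at this reduced n
  expect_lt(max(abs(imp2$per_variable$delta_auc[
    imp2$per_variable$variable %in% c("x3", "x4")])), 0.03)
  # single permutation, fixed seed: exact reproducibility
  i1 <- permutation_importance(m, w$table, n_permutations = 1, seed = 2)
  i2 <- permutation_importance(m, w$table, n_permutations = 1, seed = 2)
  expect_identical(i1$per_variable, i2$per_variable)
  # percent contributions over positive deltas sum to 100
  expect_equal(sum(imp$per_variable$percent_contribution), 100,
               tolerance = 1e-9)
})
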