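test_that("parc_harmonize is identity on the template geometry (idempotent)", {
  g <- raster_grid(matrix(rnorm(16), 4, 4), c(0, 0), 90)
  out <- parc_harmonize(g, g)
  expect_identical(out$values, g$values)
  expect_identical(parc_harmonize(out, g)$values, out$values)
})

test_that("parc_harmonize takes the nearest source cell center", {
  # fine source: 4x4 at cell 45 over [0,180]^2; coarse template: 2x2 at 90
  src <- raster_grid(matrix(1:16, 4, 4, byrow = TRUE), c(0, 0), 45)
  template <- raster_grid(matrix(0, 2, 2), c(0, 0), 90)
  out <- parc_harmonize(src, template)
  # template centers (45,135),(135,135),(45,45),(135,45) fall in src cells
  # (r2,c2),(r2,c4),(r4,c2),(r4,c4) -> values 6,8,14,16
  expect_equal(out$values, matrix(c(6, 8, 14, 16), 2, 2, byrow = TRUE))
  # nodata propagates
  src$values[2, 2] <- NA
  expect_true(is.na(parc_harmonize(src, template)$values[1, 1]))
  # disjoint bounds -> coverage error
  far <- raster_grid(matrix(0, 2, 2), c(1e6, 1e6), 90)
  expect_error(parc_harmonize(src, far), "coverage error")
})

test_that("extract_design_table builds labelled rows and drops nodata", {
  stack <- toy_stack(4, 4, 90, c("a", "b"))
  stack$layers$a$values[1, 3] <- NA
  pres <- cbind(c(45, 225, 315), c(315, 315, 315))   # third is on the NA cell
  bg <- cbind(seq(45, 315, length.out = 5), rep(45, 5))
  t <- extract_design_table(stack, pres, bg)
  expect_equal(sum(t$response), 2)
  expect_equal(nrow(t), 7)
  expect_equal(unname(attr(t, "drop_log")["presence_dropped"]), 1)
  # value read from the containing cell: presence 1 in cell (1,1): a=1, b=2
  expect_equal(t$a[1], 1)
  expect_equal(t$b[1], 2)
  # fully out-of-bounds points error out only when nothing is left
  expect_error(extract_design_table(stack, cbind(1e6, 1e6), cbind(1e6, 1e6)),
               "extraction error")
})

test_that("kendall_tau_b matches the base-R oracle on random data", {
  withr_seed(5, {
    for (i in 1:10) {
      n <- sample(10:60, 1)
      x <- sample(1:8, n, replace = TRUE)    # heavy ties
      y <- sample(1:8, n, replace = TRUE)
      expect_equal(kendall_tau_b(x, y),
                   suppressWarnings(cor(x, y, method = "kendall")),
                   tolerance = 1e-12)
    }
  })
})

test_that("max_correlation_matrix takes the max of the three coefficients", {
  t <- structure(data.frame(point_id = 1:5, x = 1:5, y = 1:5,
                            response = c(1, 1, 0, 0, 0),
                            u = c(-2, -1, 0, 1, 2),
                            v = c(-2, -1, 0, 1, 2) * 2,
                            w = c(-8, -1, 0, 1, 8)),
                 class = c("design_table", "data.frame"))
  scr <- max_correlation_matrix(t, c("u", "v", "w"))
  expect_equal(unname(scr$pairwise_max_r["u", "v"]), 1)  # linear: all three 1
  # u vs w = x^3: Spearman/Kendall 1 dominate Pearson < 1
  expect_lt(unname(scr$per_coefficient$pearson["u", "w"]), 1)
  expect_equal(unname(scr$pairwise_max_r["u", "w"]), 1)
  # symmetry, unit diagonal, and max >= each coefficient
  expect_equal(scr$pairwise_max_r, t(scr$pairwise_max_r))
  expect_equal(unname(diag(scr$pairwise_max_r)), rep(1, 3))
  for (co in scr$per_coefficient)
    expect_true(all(scr$pairwise_max_r >= co - 1e-12))
})

test_that("independent noise correlates weakly; zero variance is flagged", {
  withr_seed(9, {
    t <- structure(data.frame(point_id = 1:1000, x = 1:1000, y = 1:1000,
                              response = rep(c(1, 0), 500),
                              a = rnorm(1000), b = rnorm(1000),
                              c = rep(3, 1000)),
                   class = c("design_table", "data.frame"))
  })
  scr <- max_correlation_matrix(t, c("a", "b", "c"))
  expect_lt(unname(scr$pairwise_max_r["a", "b"]), 0.1)
  expect_equal(scr$zero_variance, "c")
  expect_equal(unname(scr$pairwise_max_r["a", "c"]), 0)
})

test_that("select_uncorrelated honors priority and the auto rule", {
  fake_screen <- function(m, threshold = 0.7) {
    structure(list(pairwise_max_r = m, threshold = threshold,
                   per_coefficient = list(), zero_variance = character(),
                   retained = character(), removed = list()),
              class = "correlation_screen")
  }
  m <- matrix(c(1, 1, 1, 1), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  s <- select_uncorrelated(fake_screen(m), priority = c("A", "B"))
  expect_equal(s$retained, "A")
  expect_equal(names(s$removed), "B")

  # A-B 0.9, B-C 0.9, A-C 0.1: auto removes B (largest mean |r|)
  m <- matrix(c(1, .9, .1, .9, 1, .9, .1, .9, 1), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  s <- select_uncorrelated(fake_screen(m), priority = "auto")
  expect_setequal(s$retained, c("A", "C"))
  expect_equal(names(s$removed), "B")

  # nothing above threshold: nothing removed
  m <- diag(3) * 0.4 + 0.6 * diag(3)
  dimnames(m) <- list(c("A", "B", "C"), c("A", "B", "C"))
  diag(m) <- 1
  s <- select_uncorrelated(fake_screen(m))
  expect_length(s$removed, 0)
})

test_that("after selection no retained pair exceeds the threshold", {
  withr_seed(31, {
    for (i in 1:10) {
      p <- sample(3:8, 1)
      base <- matrix(rnorm(200 * p), 200, p)
      # induce some collinearity
      base[, 1] <- base[, 2] * 0.95 + rnorm(200, sd = 0.1)
      colnames(base) <- paste0("v", seq_len(p))
      t <- structure(data.frame(point_id = 1:200, x = 1:200, y = 1:200,
                                response = rep(c(1, 0), 100), base),
                     class = c("design_table", "data.frame"))
      s <- select_uncorrelated(max_correlation_matrix(t))
      sub <- s$pairwise_max_r[s$retained, s$retained, drop = FALSE]
      diag(sub) <- 0
      expect_lte(max(sub), 0.7)
    }
  })
})
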