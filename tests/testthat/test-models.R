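# shared separable toy: presences at sig > 0.8, background at sig < 0.2
separable_table <- function(n1 = 25, n0 = 40, seed = 55) {
  withr_seed(seed, {
    structure(data.frame(
      point_id = seq_len(n1 + n0), x = runif(n1 + n0), y = runif(n1 + n0),
      response = rep(c(1L, 0L), c(n1, n0)),
      sig = c(runif(n1, 0.8, 1), runif(n0, 0, 0.2)),
      noise = rnorm(n1 + n0)),
      class = c("design_table", "data.frame"))
  })
}

test_that("every algorithm separates the separable toy (train AUC 1)", {
  t <- separable_table()
  for (alg in c("glm_stepwise", "mars", "brt", "rf", "maxent_like")) {
    m <- fit_model(model_spec(alg, seed = 7), t)
    expect_equal(m$train_auc, 1, info = alg)
    s <- predict_scores(m, t)
    expect_true(all(s >= 0 & s <= 1), info = alg)
  }
})

test_that("stepwise GLM stays near chance on pure noise", {
  withr_seed(91, {
    t <- structure(data.frame(
      point_id = 1:200, x = runif(200), y = runif(200),
      response = rep(c(1L, 0L), 100),
      a = rnorm(200), b = rnorm(200), c = rnorm(200)),
      class = c("design_table", "data.frame"))
  })
  m <- fit_model(model_spec("glm_stepwise", seed = 1), t)
  expect_gte(m$train_auc, 0.4)
  expect_lte(m$train_auc, 0.75)
})

test_that("stepwise GLM recovers a strong single-variable effect", {
  withr_seed(92, {
    x1 <- rnorm(300)
    noise <- rnorm(300)
    y <- rbinom(300, 1, plogis(3 * x1))
    y[1:2] <- c(1L, 0L)
    t <- structure(data.frame(point_id = 1:300, x = runif(300),
                              y = runif(300), response = y,
                              x1 = x1, noise = noise),
                   class = c("design_table", "data.frame"))
  })
  m <- fit_model(model_spec("glm_stepwise", seed = 1), t)
  expect_true("x1" %in% m$variables_used)
})

test_that("fits are seed-deterministic and row-order invariant", {
  t <- separable_table(30, 60, seed = 66)
  probe <- t[seq(1, 90, 3), ]
  withr_seed(101, perm <- sample(nrow(t)))
  t_perm <- t[perm, ]
  class(t_perm) <- class(t)
  for (alg in c("glm_stepwise", "mars", "brt", "rf", "maxent_like")) {
    spec <- model_spec(alg, seed = 11)
    m1 <- fit_model(spec, t)
    m2 <- fit_model(spec, t)          # same seed, same table
    m3 <- fit_model(spec, t_perm)     # same rows, shuffled
    expect_identical(m1$variables_used, m2$variables_used, info = alg)
    expect_equal(predict_scores(m1, probe), predict_scores(m2, probe),
                 tolerance = 1e-12, info = alg)
    expect_equal(predict_scores(m1, probe), predict_scores(m3, probe),
                 tolerance = 1e-10, info = alg)
  }
})

test_that("fit_model validates its inputs", {
  t <- separable_table()
  t_one <- t[t$response == 1, ]
  class(t_one) <- class(t)
  expect_error(fit_model(model_spec("rf"), t_one), "class error")
  t_few <- t[c(1:5, 30:60), ]
  class(t_few) <- class(t)
  expect_error(fit_model(model_spec("rf"), t_few), "class error")
  expect_error(model_spec("rf", settings = list(bogus = 1)),
               "unknown setting")
})

test_that("predict_raster matches pointwise scoring and propagates nodata", {
  w <- recovery_world()
  m <- fit_model(model_spec("brt", settings = list(n_trees_max = 200),
                            seed = 3), w$table)
  stack <- w$stack
  stack$layers$x1$values[3, 5] <- NA
  r <- predict_raster(m, stack)
  expect_true(is.na(r$values[3, 5]))
  # spot-check 100 random cells against the pointwise scorer
  withr_seed(44, idx <- sample(64 * 64, 100))
  centers <- cell_centers(stack$layers$x1)[idx, , drop = FALSE]
  vals <- sapply(stack$layers, function(l) extract_values(l, centers))
  keep <- stats::complete.cases(vals)
  df <- as.data.frame(vals[keep, , drop = FALSE])
  expect_equal(extract_values(r, centers)[keep],
               unname(predict_scores(m, df)), tolerance = 1e-12)
  # constant rasters give the constant scorer value
  const <- raster_stack(lapply(stack$layers, function(l) {
    l$values[] <- 0.3; l
  }))
  rc <- predict_raster(m, const)
  one <- predict_scores(m, as.data.frame(as.list(
    stats::setNames(rep(0.3, length(names(const))), names(const)))))
  expect_true(all(abs(rc$values - one) < 1e-12))
  # missing layer errors by name
  expect_error(predict_raster(m, raster_stack(stack$layers[1:2])),
               "schema error.*x3")
})

test_that("gates flag overfitting and drop weak models", {
  m <- structure(list(train_auc = 0.99, cv_auc = 0.90,
                      gates = list()), class = "fitted_model")
  g <- apply_gates(m)
  expect_true(g$gates$overfit_flag)    # gap 0.09 > 0.05
  expect_false(g$gates$dropped)
  m$train_auc <- 0.72; m$cv_auc <- 0.65
  g <- apply_gates(m)
  expect_true(g$gates$dropped)         # cv 0.65 < 0.7
  m$train_auc <- 0.95; m$cv_auc <- 0.93
  g <- apply_gates(m)
  expect_false(g$gates$overfit_flag)
  expect_false(g$gates$dropped)
  # still-overfit after retune forces the drop
  m$train_auc <- 0.99; m$cv_auc <- 0.90
  g <- apply_gates(m, still_overfit = TRUE)
  expect_true(g$gates$dropped)
  m$cv_auc <- NA_real_
  expect_error(apply_gates(m), "ordering error")
})

test_that("retune_spec strengthens regularization per algorithm", {
  s <- retune_spec(model_spec("glm_stepwise"))
  expect_false(s$settings$squared)
  expect_false(s$settings$interactions)
  s <- retune_spec(model_spec("mars"))
  expect_equal(s$settings$gcv_penalty, 4)
  s <- retune_spec(model_spec("brt"))
  expect_equal(s$settings$learning_rate, 0.005)
  expect_equal(s$settings$tree_depth, 2)
  s <- retune_spec(model_spec("rf"))
  expect_equal(s$settings$min_node, 20)
  s <- retune_spec(model_spec("maxent_like"))
  expect_equal(s$settings$reg_multiplier, 4)
})
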