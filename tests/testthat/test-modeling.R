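test_that("stratified split yields 80/30 with every variety in both sets", {
  ds <- simulate_tea_dataset(seed = 6, cubes = FALSE)
  sp <- stratified_split(ds$truth, seed = 10)
  expect_length(sp$calibration_ids, 80)
  expect_length(sp$validation_ids, 30)
  expect_length(intersect(sp$calibration_ids, sp$validation_ids), 0)
  expect_setequal(c(sp$calibration_ids, sp$validation_ids),
                  ds$truth$sample_id)
  for (v in unique(ds$truth$variety)) {
    ids <- ds$truth$sample_id[ds$truth$variety == v]
    expect_gt(length(intersect(ids, sp$calibration_ids)), 0)
    expect_equal(length(intersect(ids, sp$validation_ids)), 3)
  }
  expect_identical(stratified_split(ds$truth, seed = 10), sp)
  tiny <- data.frame(sample_id = c("a", "b", "c"),
                     variety = "x", stringsAsFactors = FALSE)
  expect_error(stratified_split(tiny), "fewer than 4")
})

test_that("min-max normalization is train-anchored and invertible", {
  train <- data.frame(sample_id = c("a", "b", "c"), x = c(0, 5, 10),
                      stringsAsFactors = FALSE)
  sc <- minmax_fit(train)
  expect_equal(minmax_apply(sc, train)$x, c(0, 0.5, 1))
  # applied values outside the training range are not clipped
  new <- data.frame(sample_id = "d", x = 12, stringsAsFactors = FALSE)
  expect_equal(minmax_apply(sc, new)$x, 1.2)
  # random table round-trips through invert to 1e-12
  set.seed(3)
  tab <- data.frame(sample_id = sprintf("s%02d", 1:30),
                    u = rnorm(30), v = runif(30, -5, 5),
                    stringsAsFactors = FALSE)
  sc2 <- minmax_fit(tab)
  back <- minmax_invert(sc2, minmax_apply(sc2, tab))
  expect_equal(back$u, tab$u, tolerance = 1e-12)
  expect_equal(back$v, tab$v, tolerance = 1e-12)
  # constant feature maps to 0 with a warning
  tab$w <- 7
  expect_warning(sc3 <- minmax_fit(tab), "constant")
  expect_equal(minmax_apply(sc3, tab)$w, rep(0, 30))
})

test_that("hyperparameter grids stay inside the searched ranges", {
  for (alg in c("gridsvr", "rf", "xgboost")) {
    for (gr in c("default", "coarse")) {
      g <- model_grid(alg, gr)
      expect_gt(nrow(g), 1)
      expect_silent(teafuse:::validate_grid(alg, g))
    }
  }
  bad <- model_grid("xgboost", "coarse")
  bad$learning_rate[1] <- 2  # outside [0.1, 1]
  expect_error(teafuse:::validate_grid("xgboost", bad), "outside")
  expect_error(tp_train(make_linear_table(20), "xgboost", grid = bad),
               "outside")
})

test_that("all three regressors learn a noiseless linear target", {
  tab <- make_linear_table(n = 60, p = 1, noise_sd = 0, seed = 2)
  for (alg in c("gridsvr", "rf", "xgboost")) {
    m <- tp_train(tab, alg, grid = model_grid(alg, "coarse"), seed = 1)
    r2 <- teafuse:::r_squared(tab$TP_percent, predict(m, tab))
    expect_gt(r2, 0.99)
    # winning parameters are members of the declared grid
    expect_true(any(apply(m$grid, 1, function(row)
      all(abs(row - unlist(m$best_params)) < 1e-12))))
  }
})

test_that("grid search is deterministic under a fixed seed", {
  tab <- make_linear_table(n = 50, noise_sd = 0.5, seed = 4)
  for (alg in c("gridsvr", "rf", "xgboost")) {
    m1 <- tp_train(tab, alg, grid = model_grid(alg, "coarse"), seed = 3)
    m2 <- tp_train(tab, alg, grid = model_grid(alg, "coarse"), seed = 3)
    expect_identical(m1$best_params, m2$best_params, info = alg)
    expect_identical(m1$cv_rmse, m2$cv_rmse, info = alg)
    expect_identical(predict(m1, tab), predict(m2, tab), info = alg)
  }
})

test_that("model objects expose the standard S3 surface", {
  tab <- make_linear_table(n = 40, noise_sd = 0.2, seed = 5)
  m <- tp_train(tab, "xgboost", grid = model_grid("xgboost", "coarse"),
                seed = 2)
  expect_s3_class(m, "tp_model")
  expect_output(print(m), "xgboost")
  expect_output(print(summary(m)), "calibration fit")
  expect_named(coef(m), names(model_grid("xgboost", "coarse")))
  expect_length(fitted(m), 40)
  expect_equal(residuals(m), tab$TP_percent - fitted(m))
})

test_that("evaluation reports R2, adjusted R2 and RMSE coherently", {
  expect_equal(adjusted_r_squared(0.9, 30, 26), 1 - 0.1 * 29 / 3,
               tolerance = 1e-12)
  expect_equal(round(adjusted_r_squared(0.9, 30, 26), 4), 0.0333)
  expect_error(adjusted_r_squared(0.9, 10, 9), "undefined")
  # mean prediction has R2 exactly 0; perfect prediction exactly 1
  y <- c(10, 14, 22, 30)
  expect_equal(teafuse:::r_squared(y, rep(mean(y), 4)), 0)
  expect_equal(teafuse:::r_squared(y, y), 1)

  tab <- make_linear_table(n = 60, noise_sd = 0.3, seed = 7)
  cal <- tab[1:40, ]; val <- tab[41:60, ]
  m <- tp_train(cal, "gridsvr", grid = model_grid("gridsvr", "coarse"),
                seed = 1)
  ev <- evaluate_model(m, cal, val)
  expect_s3_class(ev, "tp_evaluation")
  expect_equal(ev$set, c("calibration", "validation"))
  expect_true(all(ev$RMSE >= 0))
  expect_true(all(ev$adjusted_R2 <= ev$R2))
  expect_equal(ev$n, c(40, 20))
  expect_equal(ev$p, c(3, 3))
  # predictions are name-keyed: permuting feature columns changes nothing
  perm <- val[, c("sample_id", "x3", "x1", "x2", "TP_percent")]
  expect_equal(predict(m, perm), predict(m, val))
  expect_equal(evaluate_model(m, cal, perm)$RMSE, ev$RMSE)
})
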