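# Stratified split, min-max normalization, grid-searched regressors
# (epsilon-SVR, random forest, gradient boosting), and evaluation.

#' Stratified calibration/validation split
#'
#' Splits samples within each tea variety, holding out 3 validation
#' samples per variety of the reference design (7/3 for 10-sample
#' varieties, 12/3 for 15-sample varieties — the per-variety allocation
#' closest to a global 7:3 that reproduces 80/30 totals on the default
#' 110-sample design). Other variety sizes fall back to holding out
#' `max(1, floor(0.3 n))`. Assignment within a variety is random under
#' the seed.
#'
#' @param truth data.frame with `sample_id` and `variety`.
#' @param seed Integer seed.
#' @return A `split_plan`: list with `calibration_ids`, `validation_ids`,
#'   `allocation` (per-variety counts).
#' @export
stratified_split <- function(truth, seed = 1L) {
  stop_if(!all(c("sample_id", "variety") %in% names(truth)),
          "truth needs sample_id and variety columns")
  counts <- table(truth$variety)
  stop_if(any(counts < 4), "variety with fewer than 4 samples: ",
          paste(names(counts)[counts < 4], collapse = ", "))
  cal <- character(0); val <- character(0)
  alloc <- list()
  varieties <- unique(truth$variety)
  with_seed(seed, {
    for (v in varieties) {
      ids <- truth$sample_id[truth$variety == v]
      n <- length(ids)
      n_val <- if (n %in% c(10L, 15L)) 3L else max(1L, floor(0.3 * n))
      pick <- sample(ids, n_val)
      val <- c(val, pick)
      cal <- c(cal, setdiff(ids, pick))
      alloc[[v]] <- data.frame(variety = v, n = n,
                               calibration = n - n_val, validation = n_val,
                               stringsAsFactors = FALSE)
    }
  })
  structure(list(calibration_ids = cal, validation_ids = val,
                 allocation = do.call(rbind, alloc)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan>", length(x$calibration_ids), "calibration /",
      length(x$validation_ids), "validation samples across",
      nrow(x$allocation), "varieties\n")
  invisible(x)
}

#' Min-max normalization fitted on a training table
#'
#' Maps each feature to `(V - Vmin) / (Vmax - Vmin)` with the extrema
#' taken from the training table only; training output lies in [0, 1],
#' values of other tables may fall outside (they are not clipped). A
#' constant training feature is mapped to 0 with a warning.
#'
#' @param train Feature table the extrema are estimated from.
#' @param features Feature names to normalize; default all.
#' @return A `minmax_scaler`: list with `min` and `max` named vectors.
#' @export
minmax_fit <- function(train, features = feature_names(train)) {
  validate_feature_table(train)
  stop_if(nrow(train) == 0, "empty training table")
  mins <- vapply(features, function(f) min(train[[f]]), numeric(1))
  maxs <- vapply(features, function(f) max(train[[f]]), numeric(1))
  const <- names(mins)[maxs == mins]
  if (length(const) > 0) {
    warning("constant training feature(s) mapped to 0: ",
            paste(const, collapse = ", "))
  }
  structure(list(min = mins, max = maxs), class = "minmax_scaler")
}

#' @rdname minmax_fit
#' @param scaler A `minmax_scaler`.
#' @param table Feature table to transform.
#' @export
minmax_apply <- function(scaler, table) {
  out <- table
  for (f in names(scaler$min)) {
    stop_if(!f %in% names(table), "table lacks feature ", f)
    denom <- scaler$max[[f]] - scaler$min[[f]]
    out[[f]] <- if (denom == 0) rep(0, nrow(table))
                else (table[[f]] - scaler$min[[f]]) / denom
  }
  out
}

#' @rdname minmax_fit
#' @export
minmax_invert <- function(scaler, table) {
  out <- table
  for (f in names(scaler$min)) {
    denom <- scaler$max[[f]] - scaler$min[[f]]
    out[[f]] <- table[[f]] * denom + scaler$min[[f]]
  }
  out
}

#' Hyperparameter grids of the three regressors
#'
#' Search grids confined to the published ranges:
#' \describe{
#'   \item{gridsvr}{epsilon-SVR with RBF kernel (libsvm convention:
#'     `c` = cost in (0, 20], `g` = RBF gamma in (0, 10], `s = 3` is the
#'     epsilon-SVR type code, `p` = epsilon tube in [0.001, 1]).}
#'   \item{rf}{random forest: `n_estimators` in [100, 2000], `max_depth`
#'     in [1, 10]; permutation importance computed once; bootstrap off
#'     (every tree sees the full calibration set, randomness enters via
#'     feature subsampling).}
#'   \item{xgboost}{`learning_rate` in [0.1, 1], `n_estimators` in
#'     [100, 1000], `max_depth` in [1, 10], `gamma` in [0.1, 1],
#'     `subsample` in [0.1, 1], `min_child_weight` in [3, 10].}
#' }
#' `granularity = "coarse"` gives a reduced ladder for repeated
#' simulation studies; every grid includes the published optimum of its
#' parameter.
#'
#' @param algorithm One of `"gridsvr"`, `"rf"`, `"xgboost"`.
#' @param granularity `"default"` or `"coarse"`.
#' @return data.frame of parameter combinations (one row per candidate).
#' @export
model_grid <- function(algorithm = c("gridsvr", "rf", "xgboost"),
                       granularity = c("default", "coarse")) {
  algorithm <- match.arg(algorithm)
  granularity <- match.arg(granularity)
  g <- switch(algorithm,
    gridsvr = if (granularity == "default") {
      expand.grid(cost = c(0.25, 0.5, 1, 2, 4, 8, 15, 20),
                  gamma = c(0.01, 0.05, 0.1, 0.5, 1, 2, 5, 10),
                  epsilon = c(0.001, 0.01, 0.05, 0.1, 0.5))
    } else {
      expand.grid(cost = c(1, 4, 15), gamma = c(0.05, 0.5, 5),
                  epsilon = c(0.01, 0.1))
    },
    rf = if (granularity == "default") {
      expand.grid(n_estimators = c(100, 500, 1000, 2000),
                  max_depth = c(1, 3, 5, 10))
    } else {
      expand.grid(n_estimators = c(500, 1000), max_depth = c(3, 10))
    },
    xgboost = if (granularity == "default") {
      expand.grid(learning_rate = c(0.1, 0.5), n_estimators = c(100, 400),
                  max_depth = c(3, 5, 10), gamma = 0.1, subsample = 0.9,
                  min_child_weight = c(3, 5))
    } else {
      expand.grid(learning_rate = 0.1, n_estimators = c(100, 400),
                  max_depth = c(3, 5), gamma = 0.1, subsample = 0.9,
                  min_child_weight = 5)
    }
  )
  validate_grid(algorithm, g)
  g
}

grid_ranges <- list(
  gridsvr = list(cost = c(0, 20), gamma = c(0, 10), epsilon = c(0.001, 1)),
  rf = list(n_estimators = c(100, 2000), max_depth = c(1, 10)),
  xgboost = list(learning_rate = c(0.1, 1), n_estimators = c(100, 1000),
                 max_depth = c(1, 10), gamma = c(0.1, 1),
                 subsample = c(0.1, 1), min_child_weight = c(3, 10))
)

validate_grid <- function(algorithm, grid) {
  ranges <- grid_ranges[[algorithm]]
  stop_if(!all(names(ranges) %in% names(grid)),
          algorithm, " grid needs parameters: ",
          paste(names(ranges), collapse = ", "))
  for (p in names(ranges)) {
    v <- grid[[p]]
    stop_if(any(v < ranges[[p]][1] | v > ranges[[p]][2]),
            algorithm, " grid value for ", p, " outside the searched range [",
            ranges[[p]][1], ", ", ranges[[p]][2], "]")
  }
  invisible(grid)
}

# Fit one candidate model on (x, y); returns an object with a matching
# predictor in predict_fit().
fit_one <- function(algorithm, params, x, y, seed) {
  switch(algorithm,
    gridsvr = e1071::svm(x = x, y = y, type = "eps-regression",
                         kernel = "radial", cost = params$cost,
                         gamma = params$gamma, epsilon = params$epsilon,
                         scale = FALSE),
    rf = ranger::ranger(
      x = as.data.frame(x), y = y,
      num.trees = params$n_estimators, max.depth = params$max_depth,
      replace = FALSE, sample.fraction = 1,
      importance = "permutation", num.threads = 1, seed = seed
    ),
    xgboost = with_seed(seed, {
      dm <- xgboost::xgb.DMatrix(as.matrix(x), label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(eta = params$learning_rate,
                      max_depth = params$max_depth, gamma = params$gamma,
                      subsample = params$subsample,
                      min_child_weight = params$min_child_weight,
                      nthread = 1, seed = seed),
        data = dm, nrounds = params$n_estimators, verbose = 0
      )
    })
  )
}

predict_fit <- function(algorithm, fit, x) {
  switch(algorithm,
    gridsvr = as.numeric(predict(fit, x)),
    rf = as.numeric(predict(fit, data = as.data.frame(x),
                            num.threads = 1)$predictions),
    xgboost = as.numeric(predict(fit, xgboost::xgb.DMatrix(as.matrix(x),
                                                           nthread = 1)))
  )
}

cv_folds <- function(n, folds, seed) {
  with_seed(seed, {
    f <- rep(seq_len(folds), length.out = n)
    sample(f)
  })
}

#' Fit a grid-searched polyphenol regressor
#'
#' Normalizes the calibration features to [0, 1] (min-max, fitted on the
#' calibration table only), then selects hyperparameters by k-fold
#' cross-validated RMSE over the candidate grid (first minimum wins, in
#' grid order) and refits the winner on the full calibration set.
#'
#' @param train Feature table with `TP_percent` target.
#' @param algorithm `"gridsvr"` (epsilon-SVR, RBF kernel), `"rf"`
#'   (random forest), or `"xgboost"` (gradient-boosted trees).
#' @param grid Candidate grid, default [model_grid()] for the algorithm.
#' @param features Feature names used; default all feature columns.
#' @param seed Integer seed (folds, tree fits).
#' @param folds CV folds (default 5).
#' @param normalize Apply min-max scaling (default TRUE).
#' @return A `tp_model` with methods [predict.tp_model()],
#'   [print.tp_model()], [summary.tp_model()], [coef.tp_model()] (winning
#'   hyperparameters), [fitted.tp_model()] and [residuals.tp_model()].
#' @export
#' @examples
#' set.seed(1)
#' tab <- data.frame(sample_id = sprintf("s%02d", 1:40),
#'                   a = runif(40), b = runif(40))
#' tab$TP_percent <- 15 + 8 * tab$a + rnorm(40, 0, 0.2)
#' m <- tp_train(tab, "gridsvr",
#'               grid = model_grid("gridsvr", "coarse"), seed = 1)
#' print(m)
tp_train <- function(train, algorithm = c("xgboost", "gridsvr", "rf"),
                     grid = NULL, features = NULL, seed = 1L, folds = 5,
                     normalize = TRUE) {
  algorithm <- match.arg(algorithm)
  validate_feature_table(train)
  stop_if(!("TP_percent" %in% names(train)), "train lacks TP_percent target")
  features <- features %||% feature_names(train)
  if (is.null(grid)) grid <- model_grid(algorithm)
  validate_grid(algorithm, grid)
  x_raw <- train[, c("sample_id", features), drop = FALSE]
  stop_if(any(!is.finite(as.matrix(train[, features]))),
          "non-finite feature values")
  scaler <- if (normalize) minmax_fit(x_raw, features) else NULL
  xdf <- if (normalize) minmax_apply(scaler, x_raw) else x_raw
  x <- as.matrix(xdf[, features, drop = FALSE])
  y <- train$TP_percent
  fold_id <- cv_folds(length(y), folds, child_seed(seed, 1))
  cv_rmse <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    params <- as.list(grid[gi, , drop = FALSE])
    sq <- 0
    for (k in seq_len(folds)) {
      tr <- fold_id != k
      fit <- fit_one(algorithm, params, x[tr, , drop = FALSE], y[tr],
                     seed = child_seed(seed, 100 + k))
      pred <- predict_fit(algorithm, fit, x[!tr, , drop = FALSE])
      sq <- sq + sum((y[!tr] - pred)^2)
    }
    cv_rmse[gi] <- sqrt(sq / length(y))
  }
  best <- which.min(cv_rmse)
  best_params <- as.list(grid[best, , drop = FALSE])
  fit <- fit_one(algorithm, best_params, x, y, seed = child_seed(seed, 2))
  structure(list(algorithm = algorithm, best_params = best_params,
                 cv_rmse = cv_rmse, grid = grid, fit = fit,
                 scaler = scaler, features = features, seed = seed,
                 folds = folds, train_ids = train$sample_id,
                 train_pred = predict_fit(algorithm, fit, x),
                 train_y = y),
            class = "tp_model")
}

model_matrix_from_table <- function(object, newdata) {
  missing <- setdiff(object$features, names(newdata))
  stop_if(length(missing) > 0,
          "newdata lacks model features: ", paste(missing, collapse = ", "))
  if (!is.null(object$scaler)) newdata <- minmax_apply(object$scaler, newdata)
  as.matrix(newdata[, object$features, drop = FALSE])
}

#' Predict polyphenol content from a fitted model
#'
#' @param object A `tp_model`.
#' @param newdata Feature table (raw scale; the model's stored min-max
#'   scaler is applied).
#' @param ... Unused.
#' @return Numeric vector of predicted TP (%).
#' @export
predict.tp_model <- function(object, newdata, ...) {
  predict_fit(object$algorithm, object$fit,
              model_matrix_from_table(object, newdata))
}

#' @export
print.tp_model <- function(x, ...) {
  cat("<tp_model>", x$algorithm, "-", length(x$features), "features,",
      length(x$train_y), "calibration samples\n")
  cat("  winning parameters:",
      paste(names(x$best_params), unlist(x$best_params),
            sep = "=", collapse = ", "), "\n")
  cat("  CV RMSE:", format(min(x$cv_rmse), digits = 4), "(best of",
      nrow(x$grid), "candidates,", x$folds, "folds)\n")
  invisible(x)
}

#' @export
summary.tp_model <- function(object, ...) {
  res <- residuals(object)
  structure(list(model = object,
                 train_rmse = sqrt(mean(res^2)),
                 train_r2 = r_squared(object$train_y, object$train_pred)),
            class = "summary.tp_model")
}

#' @export
print.summary.tp_model <- function(x, ...) {
  print(x$model)
  cat("  calibration fit: R2 =", format(x$train_r2, digits = 4),
      " RMSE =", format(x$train_rmse, digits = 4), "\n")
  invisible(x)
}

#' @export
coef.tp_model <- function(object, ...) {
  unlist(object$best_params)
}

#' @export
fitted.tp_model <- function(object, ...) {
  object$train_pred
}

#' @export
residuals.tp_model <- function(object, ...) {
  object$train_y - object$train_pred
}

r_squared <- function(y, pred) {
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' Adjusted coefficient of determination
#'
#' \deqn{R^2_{adj} = 1 - (1 - R^2)\frac{n - 1}{n - p - 1}} with `n` the
#' sample count and `p` the number of predictors.
#'
#' @param r2 Plain R-squared.
#' @param n Sample count.
#' @param p Predictor count.
#' @return Adjusted R-squared.
#' @export
adjusted_r_squared <- function(r2, n, p) {
  stop_if(n - p - 1 <= 0, "adjusted R2 undefined for n <= p + 1")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Evaluate a fitted model on calibration and validation tables
#'
#' Computes R-squared, adjusted R-squared (with `p` = number of model
#' features) and RMSE on each set.
#'
#' @param model A `tp_model`.
#' @param cal,val Feature tables with `TP_percent`.
#' @return A `tp_evaluation`: data.frame with rows `calibration` and
#'   `validation`, columns `n`, `p`, `R2`, `adjusted_R2`, `RMSE`.
#' @export
evaluate_model <- function(model, cal, val) {
  one <- function(tab, set) {
    pred <- predict(model, tab)
    y <- tab$TP_percent
    r2 <- r_squared(y, pred)
    n <- length(y); p <- length(model$features)
    data.frame(set = set, n = n, p = p, R2 = r2,
               adjusted_R2 = if (n - p - 1 > 0)
                 adjusted_r_squared(r2, n, p) else NA_real_,
               RMSE = sqrt(mean((y - pred)^2)),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one(cal, "calibration"), one(val, "validation"))
  class(out) <- c("tp_evaluation", "data.frame")
  out
}

#' @export
print.tp_evaluation <- function(x, ...) {
  cat("<tp_evaluation>\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
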