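#' Fit an ordinary least squares body-weight regression
#'
#' Regresses scale body weight on the biometric features by least squares.
#' The design must be full rank; collinear columns are named in the error.
#'
#' @param data Data frame with the response and feature columns, no missing
#'   values in either.
#' @param response Name of the response column (scale body weight, kg).
#' @param features Character vector of feature column names.
#' @return A `bw_model` (kind `"ols"`).
#' @examples
#' d <- tibble::tibble(v = 1:10, bw = 2 * (1:10) + 5)
#' fit_bw_ols(d, "bw", "v")
#' @export
fit_bw_ols <- function(data, response = "scale_bw",
                       features = c("dorsal_length", "abdominal_width",
                                    "height", "volume")) {
  check_bw_data(data, response, features)
  if (nrow(data) <= length(features) + 1)
    abort("need more observations than features + 1.")
  X <- as.matrix(data[features])
  qrX <- qr(cbind(`(Intercept)` = 1, X))
  if (qrX$rank < ncol(X) + 1) {
    bad <- colnames(qrX$qr)[qrX$pivot[-seq_len(qrX$rank)]]
    abort(paste0("rank-deficient design; collinear columns: ",
                 paste(bad, collapse = ", ")))
  }
  fml <- stats::reformulate(features, response)
  fit <- lm(fml, data = data)
  structure(list(kind = "ols", fit = fit, features = features,
                 response = response),
            class = "bw_model")
}

#' Fit a random-forest body-weight regression
#'
#' Bootstrap-aggregated regression trees with per-split random feature
#' subsetting. Only the feature-subset size (`mtry`) is tuned, by seeded
#' k-fold cross-validation minimizing RMSE; the ensemble is then refit on all
#' rows at the selected `mtry`. Deterministic given `seed`.
#'
#' @inheritParams fit_bw_ols
#' @param folds Number of cross-validation folds.
#' @param num_trees Trees in the ensemble.
#' @param min_node Minimum node size.
#' @param seed Integer seed controlling fold assignment and tree growing.
#' @return A `bw_model` (kind `"rf"`) whose `cv` element is the tuning table
#'   (`mtry`, `rmse`).
#' @export
fit_bw_rf <- function(data, response = "scale_bw",
                      features = c("dorsal_length", "abdominal_width",
                                   "height", "volume"),
                      folds = 5, num_trees = 500, min_node = 5, seed = 1) {
  check_bw_data(data, response, features)
  n <- nrow(data)
  if (n < folds) abort("need at least as many rows as folds.")
  X <- as.data.frame(data[features])
  y <- data[[response]]
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  cv <- purrr::map_dfr(seq_along(features), function(mtry) {
    sse <- 0
    for (k in seq_len(folds)) {
      tr <- fold_id != k
      set.seed(seed + 1000L * mtry + k)
      rf <- randomForest::randomForest(
        x = X[tr, , drop = FALSE], y = y[tr],
        ntree = num_trees, mtry = mtry, nodesize = min_node
      )
      pred <- predict(rf, X[!tr, , drop = FALSE])
      sse <- sse + sum((y[!tr] - pred)^2)
    }
    tibble(mtry = mtry, rmse = sqrt(sse / n))
  })
  best <- cv$mtry[which.min(cv$rmse)]
  set.seed(seed)
  fit <- randomForest::randomForest(x = X, y = y, ntree = num_trees,
                                    mtry = best, nodesize = min_node)
  structure(list(kind = "rf", fit = fit, features = features,
                 response = response, cv = cv, mtry = best, seed = seed),
            class = "bw_model")
}

check_bw_data <- function(data, response, features) {
  miss <- setdiff(c(response, features), names(data))
  if (length(miss))
    abort(paste0("missing columns: ", paste(miss, collapse = ", ")))
  if (anyNA(data[c(response, features)]))
    abort("missing values in response or features.")
  invisible(TRUE)
}

#' @export
print.bw_model <- function(x, ...) {
  cat(sprintf("<bw_model:%s> %s ~ %s (n = %d)\n", x$kind, x$response,
              paste(x$features, collapse = " + "),
              length(stats::fitted(x$fit))))
  invisible(x)
}

#' Predict body weight
#'
#' @param object A `bw_model`.
#' @param newdata Data frame containing the feature columns.
#' @param ... Unused.
#' @return Numeric vector of predicted body weights (kg).
#' @export
predict.bw_model <- function(object, newdata, ...) {
  unname(predict(object$fit, newdata))
}

#' @export
tidy.bw_model <- function(x, ...) {
  if (x$kind == "ols") {
    s <- summary(x$fit)$coefficients
    tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
           statistic = s[, 3], p.value = s[, 4])
  } else {
    x$cv
  }
}

#' @export
glance.bw_model <- function(x, ...) {
  y <- if (x$kind == "ols") stats::model.response(stats::model.frame(x$fit))
       else x$fit$y
  yhat <- if (x$kind == "ols") stats::fitted(x$fit)
          else predict(x$fit, newdata = NULL)
  dplyr::mutate(evaluate_bw(y, yhat), kind = x$kind, .before = 1)
}

#' Goodness-of-fit metrics for predicted body weight
#'
#' Coefficient of determination `R2 = 1 - SS_res / SS_tot` and mean absolute
#' percentage error `MAPE = (100 / n) * sum(|y - yhat| / y)`, with the
#' scale-based weight `y` as reference and denominator.
#'
#' @param y Observed (scale-based) body weights; strictly positive.
#' @param yhat Predicted (image-based) body weights, same length.
#' @return One-row tibble: `r2`, `mape` (percent), `n`.
#' @examples
#' evaluate_bw(c(100, 120), c(110, 120))   # r2 = 0.5, mape = 5
#' @export
evaluate_bw <- function(y, yhat) {
  if (length(y) != length(yhat)) abort("y and yhat must have equal length.")
  if (length(y) < 2) abort("need at least two observations.")
  if (any(y == 0)) abort("MAPE undefined: some y are zero.")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) abort("R2 undefined: y is constant.")
  tibble(r2 = 1 - sum((y - yhat)^2) / ss_tot,
         mape = 100 / length(y) * sum(abs(y - yhat) / y),
         n = length(y))
}

#' Seeded train/test fit of a body-weight model
#'
#' Random 80/20 split (seeded), fit on the training part, metrics on both
#' parts, predictions for every row (used downstream as image-based BW).
#'
#' @inheritParams fit_bw_ols
#' @param method `"ols"` or `"rf"`.
#' @param prop Training proportion.
#' @param seed Split (and RF) seed.
#' @param ... Passed to the fitting function.
#' @return List: `model`, `metrics` (tibble with `split` in
#'   `c("train", "test")`), `predictions` (input data plus `.pred`).
#' @export
fit_bw_holdout <- function(data, method = c("ols", "rf"),
                           response = "scale_bw",
                           features = c("dorsal_length", "abdominal_width",
                                        "height", "volume"),
                           prop = 0.8, seed = 1, ...) {
  method <- match.arg(method)
  set.seed(seed)
  n <- nrow(data)
  tr <- sort(sample.int(n, floor(prop * n)))
  train <- data[tr, , drop = FALSE]
  test <- data[-tr, , drop = FALSE]
  model <- if (method == "ols") fit_bw_ols(train, response, features, ...)
           else fit_bw_rf(train, response, features, seed = seed, ...)
  pred_all <- predict(model, data)
  metrics <- dplyr::bind_rows(
    dplyr::mutate(evaluate_bw(train[[response]], pred_all[tr]),
                  split = "train", .before = 1),
    dplyr::mutate(evaluate_bw(test[[response]], pred_all[-tr]),
                  split = "test", .before = 1)
  )
  list(model = model,
       metrics = metrics,
       predictions = dplyr::mutate(data, .pred = pred_all,
                                   .split = ifelse(seq_len(n) %in% tr,
                                                   "train", "test")))
}
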