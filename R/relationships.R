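#' Simple linear regression fit
#'
#' Ordinary least squares of `y` on `x` with the usual two-sided t test on
#' the slope (n - 2 df). `r_squared` equals the squared Pearson
#' correlation.
#'
#' @param x,y numeric vectors of equal length, n >= 3; `x` non-constant.
#' @param predictor,response names carried into the result.
#' @return An object of class `soilqual_regression`: list with
#'   `predictor`, `response`, `slope`, `intercept`, `r_squared`,
#'   `p_slope`, `n`.
#' @examples
#' linear_fit(1:5, 2 * (1:5) + 1)   # slope 2, intercept 1, R^2 = 1
#' @export
linear_fit <- function(x, y, predictor = "x", response = "y") {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant predictor: slope undefined", call. = FALSE)
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  structure(list(predictor = predictor, response = response,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = s$r.squared,
                 p_slope = unname(s$coefficients[2, 4]),
                 n = length(x)),
            class = "soilqual_regression")
}

#' @export
print.soilqual_regression <- function(x, ...) {
  cat(sprintf("%s ~ %s: slope %.4g (p = %.4g), intercept %.4g, R^2 = %.3f, n = %d\n",
              x$response, x$predictor, x$slope, x$p_slope, x$intercept,
              x$r_squared, x$n))
  invisible(x)
}

#' Random-forest permutation importance (%IncMSE)
#'
#' Fits a regression random forest (bootstrap size n, `n_trees` trees,
#' `ceiling(p/3)` candidate features per split unless overridden) and
#' measures each feature's importance as the mean over trees of the
#' relative increase in out-of-bag mean squared error when that feature's
#' out-of-bag values are permuted:
#' mean_t (MSE_oob_permuted - MSE_oob) / MSE_oob x 100.
#'
#' Randomisation scheme: features are reordered by name before the forest
#' is fitted and before permutations are drawn (feature-major, then tree),
#' so with a fixed seed the result does not depend on the column order of
#' the input. Forest fitting uses the `randomForest` package.
#'
#' With very few plots (a 9-plot trial, say) permutation importance is
#' high-variance; prefer reporting means over several seeds.
#'
#' @param features data.frame or matrix, plots x properties (>= 2
#'   features).
#' @param target numeric response (e.g. grain yield).
#' @param n_trees number of trees (default 500).
#' @param seed integer seed; the result is reproducible given
#'   (`seed`, `n_trees`).
#' @param mtry candidate features per split; default `ceiling(p/3)`.
#' @return An object of class `soilqual_importance`: list with `table`
#'   (data.frame feature/importance, sorted by decreasing importance) and
#'   `settings` (n_trees, mtry, seed).
#' @export
rf_importance <- function(features, target, n_trees = 500, seed = 1,
                          mtry = NULL) {
  features <- as.data.frame(features)
  if (ncol(features) < 2) stop("need at least 2 features", call. = FALSE)
  if (!is.numeric(n_trees) || n_trees < 1) {
    stop("n_trees must be a positive integer", call. = FALSE)
  }
  n <- nrow(features)
  if (n != length(target)) stop("features and target sizes differ", call. = FALSE)
  if (n < 5) {
    warning("fewer than 5 observations: out-of-bag importance will be unstable")
  }
  features <- features[, order(colnames(features)), drop = FALSE]
  p <- ncol(features)
  mtry <- mtry %||% ceiling(p / 3)

  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(x = features, y = target,
                                   ntree = as.integer(n_trees), mtry = mtry,
                                   keep.forest = TRUE, keep.inbag = TRUE)
  ind <- stats::predict(rf, features, predict.all = TRUE)$individual
  oob <- lapply(seq_len(ncol(ind)), function(t) which(rf$inbag[, t] == 0))
  base_mse <- vapply(seq_along(oob), function(t) {
    if (!length(oob[[t]])) return(NA_real_)
    mean((ind[oob[[t]], t] - target[oob[[t]]])^2)
  }, numeric(1))
  valid <- which(!is.na(base_mse) & base_mse > 0)
  if (!length(valid)) {
    stop("no usable out-of-bag samples: too few observations", call. = FALSE)
  }

  imp <- stats::setNames(numeric(p), colnames(features))
  for (j in seq_len(p)) {
    inc <- vapply(valid, function(t) {
      rows <- oob[[t]]
      Xp <- features[rows, , drop = FALSE]
      Xp[[j]] <- Xp[[j]][sample.int(length(rows))]
      pred <- stats::predict(rf, Xp, predict.all = TRUE)$individual[, t]
      (mean((pred - target[rows])^2) - base_mse[t]) / base_mse[t] * 100
    }, numeric(1))
    imp[j] <- mean(inc)
  }

  tab <- data.frame(feature = names(imp), importance = as.numeric(imp),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$importance, tab$feature), ]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 settings = list(n_trees = as.integer(n_trees), mtry = mtry,
                                 seed = as.integer(seed))),
            class = "soilqual_importance")
}

#' @export
print.soilqual_importance <- function(x, ...) {
  cat(sprintf("Permutation importance (%%IncMSE), %d trees, mtry %d, seed %d\n",
              x$settings$n_trees, x$settings$mtry, x$settings$seed))
  print(x$table, ...)
  invisible(x)
}
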