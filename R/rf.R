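#' Fit a random-forest classifier with OOB error and permutation importance
#'
#' Thin, seed-disciplined wrapper around the `randomForest` package (the
#' standard Breiman/Cutler implementation): `n_trees` trees grown on
#' bootstrap resamples with `mtry` random candidate features per split,
#' out-of-bag misclassification as the error estimate, and permutation
#' (mean-decrease-in-accuracy) importance per feature.
#'
#' @param x Numeric samples x features matrix.
#' @param y Two-level class labels.
#' @param n_trees Number of trees (default 1000).
#' @param mtry Candidate features per split; default `floor(sqrt(p))`.
#' @param seed Integer seed (forest growth is stochastic).
#' @return An `rf_model`: the fitted forest, `oob_error`, `importance`
#'   tibble, `mtry`, `n_trees`, `seed`.
#' @export
fit_rf <- function(x, y, n_trees = 1000, mtry = NULL, seed = 1L) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) != 2) stop("y must have exactly two classes", call. = FALSE)
  if ("PD" %in% levels(y)) {   # PD is always the positive class
    y <- stats::relevel(y, ref = setdiff(levels(y), "PD"))
  }
  if (anyNA(x)) stop("x contains missing values", call. = FALSE)
  p <- ncol(x)
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(p)))
  if (mtry < 1 || mtry > p) stop("mtry out of [1, p]", call. = FALSE)
  set.seed(seed)
  fit <- randomForest::randomForest(x, y, ntree = n_trees, mtry = mtry,
                                    importance = TRUE)
  imp <- randomForest::importance(fit, type = 1, scale = FALSE)
  structure(list(
    forest = fit,
    oob_error = unname(fit$err.rate[n_trees, "OOB"]),
    importance = tibble::tibble(id = rownames(imp),
                                importance = unname(imp[, 1])) |>
      dplyr::arrange(dplyr::desc(importance)),
    mtry = mtry, n_trees = n_trees, seed = seed,
    levels = levels(y)
  ), class = "rf_model")
}

#' @export
print.rf_model <- function(x, ...) {
  cat("<rf_model> ", x$n_trees, " trees, mtry = ", x$mtry,
      ", OOB error = ", sprintf("%.3f", x$oob_error), "\n", sep = "")
  invisible(x)
}

#' Predict positive-class probability from a random forest
#'
#' @param object An `rf_model`.
#' @param newdata Samples x features matrix.
#' @param ... Unused.
#' @return Vector of positive-class (second level) vote fractions.
#' @export
predict.rf_model <- function(object, newdata, ...) {
  pr <- stats::predict(object$forest, newdata, type = "prob")
  unname(pr[, object$levels[2]])
}

#' Tune mtry by out-of-bag error
#'
#' Fits one forest per candidate `mtry` and returns the value with the
#' lowest OOB misclassification rate; ties break toward smaller `mtry`.
#' The default grid is `{floor(sqrt(p)/2), floor(sqrt(p)), 2*floor(sqrt(p))}`.
#'
#' @param x,y As in [fit_rf()].
#' @param grid Candidate `mtry` values; `NULL` for the default grid.
#' @param n_trees Trees per candidate forest.
#' @param seed Integer seed (one derived seed per candidate).
#' @return List: `mtry` (selected), `oob` (named errors per candidate).
#' @export
tune_mtry <- function(x, y, grid = NULL, n_trees = 1000, seed = 1L) {
  p <- ncol(x)
  if (is.null(grid)) {
    r <- max(1, floor(sqrt(p)))
    grid <- unique(pmin(pmax(c(floor(r / 2), r, 2 * r), 1), p))
  }
  if (length(grid) == 0) stop("empty mtry grid", call. = FALSE)
  grid <- sort(unique(grid))
  oob <- vapply(seq_along(grid), function(i) {
    fit_rf(x, y, n_trees = n_trees, mtry = grid[i], seed = seed + i)$oob_error
  }, numeric(1))
  names(oob) <- grid
  list(mtry = grid[which.min(oob)], oob = oob)
}

#' Tidy a random-forest model: permutation importance per feature
#'
#' @param x An `rf_model`.
#' @param ... Unused.
#' @return Tibble (`id`, `importance`), decreasing.
#' @export
tidy.rf_model <- function(x, ...) x$importance

#' Model-level summary of a random forest
#'
#' @param x An `rf_model`.
#' @param ... Unused.
#' @return One-row tibble: trees, mtry, OOB error.
#' @export
glance.rf_model <- function(x, ...) {
  tibble::tibble(n_trees = x$n_trees, mtry = x$mtry,
                 oob_error = x$oob_error)
}
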