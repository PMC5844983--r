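#' Fit a two-class PLS-DA model (NIPALS, single response)
#'
#' Partial least squares reduces the metabolite space to a small set of
#' mutually orthogonal latent components with maximal covariance to the
#' class label, then regresses the label on those components. Predictors are
#' autoscaled (centered, unit variance; constant features dropped with a
#' warning) and the two-level class is coded 0/1 and centered. Components
#' are extracted by NIPALS deflation; for a single response each component
#' is closed-form: `w_a = X'y / |X'y|`.
#'
#' @param x Numeric samples x features matrix, no missing values.
#' @param y Two-level factor or vector of class labels; the second level
#'   (e.g. `"PD"`) is the positive class coded 1.
#' @param n_components Number of latent components A,
#'   `1 <= A <= min(n - 1, p)`.
#' @return A `pls_model`: unit-norm X-weights `W` (p x A), X-loadings `P`,
#'   y-loadings `q`, X-scores `T` (orthogonal columns), per-component
#'   explained response sum of squares `ssy`, the centering/scaling vectors
#'   and the class coding.
#' @export
fit_pls <- function(x, y, n_components = 2) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) != 2) stop("y must have exactly two classes", call. = FALSE)
  if ("PD" %in% levels(y)) {   # PD is always the positive (coded-1) class
    y <- stats::relevel(y, ref = setdiff(levels(y), "PD"))
  }
  if (anyNA(x)) stop("x contains missing values", call. = FALSE)
  if (any(table(y) == 0)) stop("a class is empty", call. = FALSE)
  n <- nrow(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  const <- sdv <= 1e-12
  if (any(const)) {
    warning(sum(const), " constant feature(s) dropped")
    x <- x[, !const, drop = FALSE]
    mu <- mu[!const]
    sdv <- sdv[!const]
  }
  p <- ncol(x)
  A <- n_components
  if (A < 1 || A > min(n - 1, p)) {
    stop("n_components must be in [1, min(n - 1, p)]", call. = FALSE)
  }
  xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  y01 <- as.numeric(y) - 1
  ybar <- mean(y01)
  yc <- y01 - ybar

  W <- matrix(0, p, A)
  P <- matrix(0, p, A)
  Tm <- matrix(0, n, A)
  q <- numeric(A)
  ssy <- numeric(A)
  Xd <- xs
  yd <- yc
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      # response fully deflated; truncate
      A <- a - 1
      break
    }
    w <- w / nw
    t_ <- drop(Xd %*% w)
    tt <- sum(t_^2)
    pl <- drop(crossprod(Xd, t_)) / tt
    qa <- sum(yd * t_) / tt
    Xd <- Xd - outer(t_, pl)
    yd <- yd - qa * t_
    W[, a] <- w
    P[, a] <- pl
    Tm[, a] <- t_
    q[a] <- qa
    ssy[a] <- qa^2 * tt
  }
  if (A == 0) stop("degenerate fit: response orthogonal to predictors",
                   call. = FALSE)
  keep <- seq_len(A)
  structure(list(
    n_components = A,
    W = W[, keep, drop = FALSE],
    P = P[, keep, drop = FALSE],
    q = q[keep],
    T = Tm[, keep, drop = FALSE],
    ssy = ssy[keep],
    means = mu, scales = sdv,
    feature_ids = colnames(x),
    levels = levels(y),
    ybar = ybar
  ), class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model> ", x$n_components, " component(s), ",
      length(x$feature_ids), " features; positive class '",
      x$levels[2], "'\n", sep = "")
  invisible(x)
}

#' Predict class scores from a PLS-DA model
#'
#' Projects new samples onto the model's latent components
#' (`T = X_scaled W (P'W)^{-1}`), applies the component regression, maps
#' back from the centered 0/1 coding, and clips to \[0, 1\]. A threshold of
#' 0.5 yields class labels.
#'
#' @param object A `pls_model`.
#' @param newdata Samples x features matrix carrying at least the training
#'   features (matched by column name when present).
#' @param n_components Use only the first A components (default: all).
#' @param ... Unused.
#' @return Numeric vector of class scores in \[0, 1\] (probability-like
#'   score for the positive class).
#' @export
predict.pls_model <- function(object, newdata, n_components = NULL, ...) {
  m <- object
  x <- as.matrix(newdata)
  if (!is.null(colnames(x))) {
    missing <- setdiff(m$feature_ids, colnames(x))
    if (length(missing) > 0) {
      stop("newdata lacks training features: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    x <- x[, m$feature_ids, drop = FALSE]
  } else if (ncol(x) != length(m$feature_ids)) {
    stop("newdata has ", ncol(x), " features; model expects ",
         length(m$feature_ids), call. = FALSE)
  }
  A <- if (is.null(n_components)) m$n_components else n_components
  stopifnot(A >= 1, A <= m$n_components)
  ks <- seq_len(A)
  xs <- sweep(sweep(x, 2, m$means), 2, m$scales, "/")
  R <- m$W[, ks, drop = FALSE] %*%
    solve(crossprod(m$P[, ks, drop = FALSE], m$W[, ks, drop = FALSE]))
  Tn <- xs %*% R
  raw <- drop(Tn %*% m$q[ks]) + m$ybar
  pmin(pmax(raw, 0), 1)
}

#' Variable importance in projection (VIP) scores
#'
#' `VIP_j = sqrt(p * sum_a ssy_a w_ja^2 / sum_a ssy_a)` with unit-norm
#' weight columns; the mean square of the VIPs is exactly 1
#' (`sum_j VIP_j^2 = p`), so features with VIP > 1 contribute more than
#' average to the class separation.
#'
#' @param model A `pls_model`.
#' @return Tibble (`id`, `vip`) sorted by decreasing VIP.
#' @export
vip_scores <- function(model) {
  ssy <- model$ssy
  if (sum(ssy) <= 0) stop("degenerate fit: no explained response variance",
                          call. = FALSE)
  p <- nrow(model$W)
  w2 <- model$W^2        # columns already unit norm
  vip <- sqrt(p * drop(w2 %*% ssy) / sum(ssy))
  tibble::tibble(id = model$feature_ids, vip = vip) |>
    dplyr::arrange(dplyr::desc(vip))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PLS-DA model: one row per feature
#'
#' @param x A `pls_model`.
#' @param ... Unused.
#' @return Tibble with feature id, per-component weights and VIP.
#' @export
tidy.pls_model <- function(x, ...) {
  w <- tibble::as_tibble(x$W, .name_repair = ~ paste0("w", seq_along(.x)))
  out <- dplyr::bind_cols(tibble::tibble(id = x$feature_ids), w)
  dplyr::left_join(out, vip_scores(x), by = "id")
}

#' Model-level summary of a PLS-DA fit
#'
#' @param x A `pls_model`.
#' @param ... Unused.
#' @return One-row tibble: components, features, explained response sum of
#'   squares.
#' @export
glance.pls_model <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    n_features = length(x$feature_ids),
    ssy_total = sum(x$ssy)
  )
}
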