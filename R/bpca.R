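#' Probabilistic-PCA imputation of missing matrix cells
#'
#' Fits a low-rank probabilistic PCA model `x_i = W z_i + mu + eps` by
#' expectation-maximization over the observed entries only: the E-step
#' conditions each sample's latent score on its observed coordinates, and
#' the M-step updates loadings, mean and residual variance from observed
#' cells, so missing cells never influence the fit. Automatic relevance
#' determination places a per-component precision on the columns of `W`,
#' shrinking uninformative latent dimensions toward zero (the Bayesian-PCA
#' flavour of missing-value estimation), so the candidate dimensionality
#' only needs to be an upper bound. Missing cells are returned as their
#' conditional expectation `mu_j + w_j' E[z_i]`; observed cells are never
#' altered.
#'
#' @param x Numeric matrix with `NA` marking missing cells.
#' @param n_components Candidate latent dimensionality; default
#'   `min(dim(x)) - 1` capped at 20. Must be < `min(dim(x))`.
#' @param maxit Maximum EM iterations.
#' @param tol Convergence tolerance: largest absolute change in imputed
#'   values between iterations, relative to the observed-value SD.
#' @param ard Apply automatic relevance shrinkage (default `TRUE`); `FALSE`
#'   gives plain fixed-rank PPCA-EM.
#' @return The completed matrix.
#' @export
bpca_impute <- function(x, n_components = NULL, maxit = 150, tol = 1e-7,
                        ard = TRUE) {
  n <- nrow(x)
  p <- ncol(x)
  if (is.null(n_components)) n_components <- min(n - 1, p - 1, 20)
  if (n_components >= min(n, p)) {
    stop("n_components must be < min(samples, features)", call. = FALSE)
  }
  if (n_components < 1) stop("n_components must be >= 1", call. = FALSE)
  k <- n_components
  obs <- !is.na(x)
  if (all(obs)) return(x)
  if (any(rowSums(obs) == 0) || any(colSums(obs) == 0)) {
    stop("a row or column is entirely missing", call. = FALSE)
  }
  sd_obs <- max(stats::sd(x[obs]), 1e-12)
  n_obs_col <- colSums(obs)

  # initialization: column-mean fill, SVD loadings
  mu <- colSums(x * obs, na.rm = TRUE) / n_obs_col
  x0 <- sweep(x, 2, mu)
  x0[!obs] <- 0
  sv <- svd(x0, nu = 0, nv = k)
  W <- sv$v %*% diag(sv$d[seq_len(k)] / sqrt(n), k, k)
  sigma2 <- max(stats::var(x0[obs]) / 4, 1e-12)
  alpha <- rep(1e-12, k)

  # group samples sharing a missing pattern; store missing index per group
  pat <- apply(!obs, 1, function(r) paste(which(r), collapse = ","))
  groups <- split(seq_len(n), pat)
  miss_of <- lapply(groups, function(g) which(!obs[g[1], ]))
  group_of <- integer(n)                     # sample -> group index
  for (gi in seq_along(groups)) group_of[groups[[gi]]] <- gi
  rows_missing <- lapply(seq_len(p), function(j) which(!obs[, j]))
  miss_cells <- which(!obs)
  imp <- mu[((miss_cells - 1) %/% n) + 1]

  for (it in seq_len(maxit)) {
    WtW <- crossprod(W)
    Ez <- matrix(0, n, k)
    Stot <- matrix(0, k, k)       # sum over samples of E[z z']
    Covs <- vector("list", length(groups))
    tr_term <- 0
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      mi <- miss_of[[gi]]
      Mo <- WtW
      if (length(mi) > 0) {
        Wm <- W[mi, , drop = FALSE]
        Mo <- Mo - crossprod(Wm)
      }
      M <- Mo + diag(sigma2, k)
      Minv <- tryCatch(chol2inv(chol(M)), error = function(e) solve(M))
      Xg <- x0[g, , drop = FALSE]   # centered, missing already zeroed
      Ez[g, ] <- (Xg %*% W) %*% Minv
      Cg <- sigma2 * Minv
      Covs[[gi]] <- Cg
      Stot <- Stot + length(g) * Cg
      tr_term <- tr_term + length(g) * sum(Mo * Cg)
    }
    Stot <- Stot + crossprod(Ez)

    # M-step: per-feature normal equations S_j w_j = b_j with
    # S_j = Stot - sum over samples missing j of E[z z']_i
    B <- crossprod(x0, Ez)          # p x k, missing cells contribute 0
    A <- if (ard) diag(sigma2 * alpha, k, k) else diag(0, k, k)
    Wnew <- matrix(0, p, k)
    has_miss <- unique(((miss_cells - 1) %/% n) + 1)
    complete <- setdiff(seq_len(p), has_miss)
    if (length(complete) > 0) {
      Wnew[complete, ] <- t(solve(Stot + A,
                                  t(B[complete, , drop = FALSE])))
    }
    for (j in has_miss) {
      Sj <- Stot
      for (i in rows_missing[[j]]) {
        Sj <- Sj - (Covs[[group_of[i]]] + tcrossprod(Ez[i, ]))
      }
      Wnew[j, ] <- solve(Sj + A, B[j, ])
    }
    W <- Wnew

    # mean and residual variance from observed entries
    fit <- Ez %*% t(W)
    mu <- colSums((x - fit) * obs, na.rm = TRUE) / n_obs_col
    x0 <- sweep(x, 2, mu)
    x0[!obs] <- 0
    resid2 <- sum(((x0 - fit)[obs])^2)
    sigma2 <- max((resid2 + tr_term) / sum(obs), 1e-12)
    if (ard) alpha <- n / (colSums(W^2) + 1e-12)

    new_imp <- (mu[((miss_cells - 1) %/% n) + 1] + fit[miss_cells])
    delta <- max(abs(new_imp - imp))
    imp <- new_imp
    if (delta < tol * sd_obs) break
  }
  out <- x
  out[miss_cells] <- imp
  out
}
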