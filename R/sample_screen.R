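#' Robust PCA sample distances (ROBPCA-style)
#'
#' Fits a robust k-dimensional principal subspace to the biological samples
#' and reports, per sample, the orthogonal distance (Euclidean distance to
#' the subspace) and the score distance (robust Mahalanobis distance within
#' it). The subspace comes from projection-pursuit initialization — a
#' least-outlying subset of fraction `h` selected by Stahel–Donoho
#' outlyingness over random directions through sample pairs — refined by a
#' reweighted covariance step on the orthogonal-distance inliers.
#'
#' Cutoffs: orthogonal distances use the Wilson–Hilferty normal
#' approximation of OD^(2/3), `(median + mad * z_0.975)^(3/2)`; score
#' distances use `sqrt(chi^2_{k, 0.975})`. Only the orthogonal distance
#' drives flagging (outliers orthogonal to the projection plane); score
#' flags are reported but not acted on.
#'
#' @param ft A `feature_table` (biological samples are screened).
#' @param k Subspace dimension; `NULL` (default) picks the smallest k
#'   explaining 80% of the robust variance, capped at 10.
#' @param h Coverage fraction of the least-outlying subset (default 0.75).
#' @param n_dir Number of projection-pursuit directions.
#' @param log Operate on natural-log intensities (default `TRUE`; peak
#'   heights carry multiplicative noise).
#' @param seed Seed for the random directions.
#' @return An `outlier_report` tibble (`id`, `orthogonal_distance`,
#'   `score_distance`, `od_flag`, `sd_flag`, `flagged`) with attributes
#'   `k`, `od_cutoff`, `sd_cutoff`.
#' @export
robust_pca_distances <- function(ft, k = NULL, h = 0.75, n_dir = 250,
                                 log = TRUE, seed = 1L) {
  bi <- bio_idx(ft)
  fx <- setdiff(seq_len(ncol(ft$intensities)), is_idx(ft))
  x <- ft$intensities[bi, fx, drop = FALSE]
  if (anyNA(x)) stop("screen after imputation: missing cells present",
                     call. = FALSE)
  if (log) x <- safe_log(x)
  n <- nrow(x)
  if (!is.null(k) && n < k + 2) {
    stop("need at least k + 2 biological samples", call. = FALSE)
  }
  set.seed(seed)

  # Stahel-Donoho outlyingness over directions through random sample pairs
  xc <- sweep(x, 2, apply(x, 2, stats::median))
  outl <- rep(0, n)
  for (d in seq_len(n_dir)) {
    ij <- sample.int(n, 2)
    v <- x[ij[1], ] - x[ij[2], ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) next
    z <- drop(xc %*% (v / nv))
    s <- stats::mad(z)
    if (s < 1e-12) next
    o <- abs(z - stats::median(z)) / s
    outl <- pmax(outl, o)
  }
  hn <- max(floor(h * n), 2)
  subset0 <- order(outl)[seq_len(hn)]

  fit_subspace <- function(rows, k) {
    mu <- colMeans(x[rows, , drop = FALSE])
    xs <- sweep(x[rows, , drop = FALSE], 2, mu)
    sv <- svd(xs, nu = 0)
    ev <- sv$d^2 / (length(rows) - 1)
    if (is.null(k)) {
      pos <- which(ev > max(ev[1], 0) * 1e-12)
      evp <- ev[pos]
      cum <- cumsum(evp) / sum(evp)
      k80 <- which(cum >= 0.8)[1]
      # scree cut at the largest eigenvalue gap, so a flat noise spectrum
      # cannot inflate k to the cap (p > n leaves no 80% elbow to find)
      J <- min(10, length(evp) - 1)
      k_gap <- if (J >= 1) which.max(evp[seq_len(J)] / evp[seq_len(J) + 1])
               else 1
      k <- max(1, min(k80, k_gap, 10))
    }
    k <- min(k, sum(sv$d > 1e-10), n - 2)
    list(mu = mu, V = sv$v[, seq_len(k), drop = FALSE],
         ev = ev[seq_len(k)], k = k)
  }
  dists <- function(fit) {
    xc2 <- sweep(x, 2, fit$mu)
    T <- xc2 %*% fit$V
    od <- sqrt(pmax(rowSums(xc2^2) - rowSums(T^2), 0))
    sd_ <- sqrt(rowSums(sweep(T^2, 2, fit$ev, "/")))
    list(od = od, sd = sd_)
  }
  od_cut <- function(od) {
    z <- od^(2 / 3)
    (stats::median(z) + stats::mad(z) * stats::qnorm(0.975))^(3 / 2)
  }

  fit0 <- fit_subspace(subset0, k)
  d0 <- dists(fit0)
  keep <- which(d0$od <= od_cut(d0$od))
  if (length(keep) > fit0$k + 1) {
    fit <- fit_subspace(keep, fit0$k)
  } else {
    fit <- fit0
  }
  dd <- dists(fit)
  odc <- od_cut(dd$od)
  # numerical floor: exact low-rank data has OD ~ machine noise; such
  # residuals are never outliers regardless of their relative spread
  odc <- max(odc, 1e-6 * sqrt(sum(apply(x, 2, stats::var))))
  sdc <- sqrt(stats::qchisq(0.975, df = fit$k))

  out <- tibble::tibble(
    id = ft$samples$id[bi],
    orthogonal_distance = dd$od,
    score_distance = dd$sd,
    od_flag = dd$od > odc,
    sd_flag = dd$sd > sdc,
    flagged = dd$od > odc
  )
  class(out) <- c("outlier_report", class(out))
  attr(out, "k") <- fit$k
  attr(out, "od_cutoff") <- odc
  attr(out, "sd_cutoff") <- sdc
  out
}

#' Drop flagged outlier samples
#'
#' @param ft The `feature_table` the report was computed on.
#' @param report An `outlier_report` from [robust_pca_distances()].
#' @return A `feature_table` without the flagged biological samples;
#'   attribute `"removed"` logs ids and distances.
#' @export
drop_outliers <- function(ft, report) {
  if (!all(report$id %in% ft$samples$id)) {
    stop("report does not match this table", call. = FALSE)
  }
  bad <- report$id[report$flagged]
  keep <- setdiff(ft$samples$id, bad)
  out <- ft_subset(ft, sample_ids = keep)
  attr(out, "removed") <- report[report$flagged, ]
  out
}

# vectorized per-feature OLS of a feature matrix on a single covariate;
# returns slope, its two-sided p, and the centered covariate
.ols_screen <- function(y, x) {
  if (stats::sd(x) == 0) stop("constant covariate", call. = FALSE)
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- drop(crossprod(xc, y)) / sxx
  fitted <- outer(xc, slope) + rep(colMeans(y), each = n)
  rss <- colSums((y - fitted)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  t <- slope / se
  p <- 2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
  list(slope = slope, p = p, xc = xc)
}

#' Remove significant linear age trends from metabolite levels
#'
#' Per feature, ordinary least squares of intensity on age over all
#' biological samples (PD and controls pooled). Features whose slope is
#' significant at `alpha` (two-sided) are normalized to slope zero:
#' `intensity - slope * (age - mean age)`. Other features are unchanged.
#'
#' @param ft A `feature_table` with ages for all biological samples.
#' @param alpha Significance level (default 0.05).
#' @return A `feature_table`; attribute `"corrected"` is a tibble of
#'   corrected feature ids with slopes and p-values.
#' @export
correct_age <- function(ft, alpha = 0.05) {
  bi <- bio_idx(ft)
  age <- ft$samples$age[bi]
  if (anyNA(age)) stop("age missing for a biological sample", call. = FALSE)
  y <- ft$intensities[bi, , drop = FALSE]
  if (anyNA(y)) stop("impute before age correction", call. = FALSE)
  fit <- .ols_screen(y, age)
  sig <- which(fit$p <= alpha)
  out <- ft
  if (length(sig) > 0) {
    y[, sig] <- y[, sig, drop = FALSE] - outer(fit$xc, fit$slope[sig])
    out$intensities[bi, ] <- pmax(y, 0)
  }
  attr(out, "corrected") <- tibble::tibble(
    id = ft$features$id[sig],
    slope = unname(fit$slope[sig]),
    p = unname(fit$p[sig])
  )
  out
}

#' Equalize male and female mean metabolite levels
#'
#' Per feature, the male and female biological-sample means are shifted
#' additively onto the pooled mean, so the post-correction sex difference in
#' means is exactly zero.
#'
#' @param ft A `feature_table` with sex labels on biological samples.
#' @return A `feature_table`; attribute `"shifts"` records the applied
#'   per-sex shifts.
#' @export
correct_gender <- function(ft) {
  bi <- bio_idx(ft)
  sex <- ft$samples$sex[bi]
  m <- which(sex == "M")
  f <- which(sex == "F")
  if (length(m) == 0 || length(f) == 0) {
    warning("a sex class has no samples; gender correction skipped")
    return(ft)
  }
  y <- ft$intensities[bi, , drop = FALSE]
  pooled <- colMeans(y)
  mm <- colMeans(y[m, , drop = FALSE])
  mf <- colMeans(y[f, , drop = FALSE])
  y[m, ] <- sweep(y[m, , drop = FALSE], 2, pooled - mm, "+")
  y[f, ] <- sweep(y[f, , drop = FALSE], 2, pooled - mf, "+")
  out <- ft
  out$intensities[bi, ] <- pmax(y, 0)
  attr(out, "shifts") <- tibble::tibble(
    id = ft$features$id,
    shift_male = unname(pooled - mm),
    shift_female = unname(pooled - mf)
  )
  out
}

#' Screen metabolite levels against levodopa dose (LEDD)
#'
#' Per-feature OLS of intensity on LEDD over PD samples only. A report-only
#' screen for medication bias: no correction is applied; features with
#' p <= 0.05 are flagged.
#'
#' @param ft A `feature_table` with LEDD for at least 3 PD samples.
#' @return Tibble (`id`, `slope`, `p`, `flagged`).
#' @export
screen_ledd <- function(ft) {
  bi <- bio_idx(ft)
  pd <- bi[ft$samples$group[bi] == "PD" & !is.na(ft$samples$ledd[bi])]
  if (length(pd) < 3) stop("need >= 3 PD samples with LEDD", call. = FALSE)
  fit <- .ols_screen(ft$intensities[pd, , drop = FALSE],
                     ft$samples$ledd[pd])
  tibble::tibble(
    id = ft$features$id,
    slope = unname(fit$slope),
    p = unname(fit$p),
    flagged = unname(fit$p) <= 0.05
  )
}

#' Pairwise covariate interaction screen (ANOVA)
#'
#' Per feature, fits `intensity ~ age * sex + age * ledd + sex * ledd` on the
#' PD samples (LEDD exists only there) and reports the p-value of each
#' pairwise interaction term. Used to confirm that age, sex and dose act
#' additively before correcting them separately.
#'
#' @param ft A `feature_table`.
#' @return Tibble (`id`, `p_age_sex`, `p_age_ledd`, `p_sex_ledd`).
#' @export
interaction_screen <- function(ft) {
  bi <- bio_idx(ft)
  pd <- bi[ft$samples$group[bi] == "PD" & !is.na(ft$samples$ledd[bi])]
  df <- data.frame(age = ft$samples$age[pd],
                   sex = factor(ft$samples$sex[pd]),
                   ledd = ft$samples$ledd[pd])
  if (nrow(df) < 7) {
    stop("too few PD samples for the interaction model (need >= 7)",
         call. = FALSE)
  }
  if (nlevels(df$sex) < 2) stop("collinear design: sex is constant",
                                call. = FALSE)
  res <- matrix(NA_real_, ncol(ft$intensities), 3,
                dimnames = list(NULL, c("p_age_sex", "p_age_ledd",
                                        "p_sex_ledd")))
  terms <- c("age:sexM", "age:ledd", "sexM:ledd")
  for (j in seq_len(ncol(ft$intensities))) {
    df$y <- ft$intensities[pd, j]
    fit <- stats::lm(y ~ age * sex + age * ledd + sex * ledd, data = df)
    cf <- stats::coef(fit)
    if (anyNA(cf)) {
      stop("collinear design: term(s) ",
           paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
    }
    sm <- summary(fit)$coefficients
    res[j, ] <- sm[terms, "Pr(>|t|)"]
  }
  tibble::tibble(id = ft$features$id,
                 p_age_sex = res[, 1],
                 p_age_ledd = res[, 2],
                 p_sex_ledd = res[, 3])
}
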