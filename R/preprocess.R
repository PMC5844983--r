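#' Remove features below a minimum detectable intensity
#'
#' Drops features whose maximum present intensity across biological samples
#' falls below `threshold` (default 2000, the usual minimum detectable
#' peak-height cutoff for QTOF peak tables). Samples are untouched.
#'
#' @param ft A `feature_table`.
#' @param threshold Minimum detectable intensity, >= 0.
#' @return A `feature_table` with attribute `"removed"`: tibble of removed
#'   feature ids and their maximum biological intensity.
#' @export
filter_min_intensity <- function(ft, threshold = 2000) {
  stopifnot(threshold >= 0)
  bi <- bio_idx(ft)
  x <- ft$intensities[bi, , drop = FALSE]
  mx <- suppressWarnings(apply(x, 2, max, na.rm = TRUE))
  mx[!is.finite(mx)] <- -Inf  # all-missing feature
  drop <- which(mx < threshold)
  keep_ids <- ft$features$id[setdiff(seq_along(mx), drop)]
  out <- ft_subset(ft, feature_ids = keep_ids)
  attr(out, "removed") <- tibble::tibble(
    id = ft$features$id[drop],
    max_biological_intensity = ifelse(is.finite(mx[drop]), mx[drop], NA_real_)
  )
  out
}

#' Remove features dominated by blank (extraction solvent) signal
#'
#' A feature is removed iff, in EVERY biological group separately (PD and
#' control), its median intensity is less than or equal to its median blank
#' intensity. Medians are taken over present values only; missing cells do
#' not enter them.
#'
#' @param ft A `feature_table` containing at least one blank sample.
#' @return A `feature_table` with attribute `"removed"`: tibble of removed
#'   ids with per-group and blank medians.
#' @export
filter_blank <- function(ft) {
  bl <- which(ft$samples$role == "blank")
  if (length(bl) == 0) stop("no blank samples in table", call. = FALSE)
  bi <- bio_idx(ft)
  groups <- unique(ft$samples$group[bi])
  med <- function(rows) apply(ft$intensities[rows, , drop = FALSE], 2,
                              stats::median, na.rm = TRUE)
  m_blank <- med(bl)
  m_group <- vapply(groups, function(g) med(bi[ft$samples$group[bi] == g]),
                    numeric(ncol(ft$intensities)))
  # removal requires every group median <= blank median (NA medians keep);
  # internal standards are spiked into blanks too and are exempt
  below <- m_group <= m_blank
  below[is.na(below)] <- FALSE
  below[is_idx(ft), ] <- FALSE
  drop <- which(rowSums(below) == length(groups))
  keep_ids <- ft$features$id[setdiff(seq_len(ncol(ft$intensities)), drop)]
  out <- ft_subset(ft, feature_ids = keep_ids)
  rem <- tibble::tibble(id = ft$features$id[drop],
                        blank_median = unname(m_blank[drop]))
  for (g in groups) rem[[paste0("median_", g)]] <- unname(m_group[drop, g])
  attr(out, "removed") <- rem
  out
}

#' Impute sporadically missing peaks by Bayesian PCA
#'
#' Features missing in at most `max_missing_fraction` of biological samples
#' are completed with a probabilistic-PCA low-rank model ([bpca_impute()])
#' fitted on the biological samples' natural-log intensities; features
#' exceeding the threshold are dropped (the conservative reading of
#' "missing peaks <= 10% were imputed"). Blank and QC cells are left as
#' they are. Observed cells are never altered; imputed intensities are
#' strictly positive by construction.
#'
#' @param ft A `feature_table`.
#' @param max_missing_fraction Per-feature tolerated missing fraction over
#'   biological samples, in (0, 1). Default 0.10.
#' @param n_components Candidate latent dimensionality for [bpca_impute()].
#' @param ... Further arguments to [bpca_impute()].
#' @return A `feature_table` with no missing biological cells; attribute
#'   `"removed"` lists features dropped for excess missingness.
#' @export
impute_missing <- function(ft, max_missing_fraction = 0.10,
                           n_components = NULL, ...) {
  stopifnot(max_missing_fraction > 0, max_missing_fraction < 1)
  bi <- bio_idx(ft)
  x <- ft$intensities[bi, , drop = FALSE]
  miss_frac <- colMeans(is.na(x))
  drop <- which(miss_frac > max_missing_fraction)
  keep <- setdiff(seq_len(ncol(x)), drop)
  out <- ft_subset(ft, feature_ids = ft$features$id[keep])
  x <- out$intensities[bi, , drop = FALSE]
  if (anyNA(x)) {
    lx <- suppressWarnings(log(x))      # zeros: excluded from the fit below
    lx[!is.na(x) & x <= 0] <- NA        # can't log; treated as unobserved
    filled <- bpca_impute(lx, n_components = n_components, ...)
    imp <- is.na(x)
    x[imp] <- exp(filled[imp])
    out$intensities[bi, ] <- x
  }
  attr(out, "removed") <- tibble::tibble(
    id = ft$features$id[drop],
    missing_fraction = unname(miss_frac[drop])
  )
  out
}

# log-intensity matrices split into internal standards and the rest,
# for the biological (and optionally qc) samples; errors per preconditions
.is_norm_parts <- function(ft) {
  isx <- is_idx(ft)
  if (length(isx) < 2) {
    stop("internal-standard normalization needs >= 2 IS features",
         call. = FALSE)
  }
  bi <- bio_idx(ft)
  S <- ft$intensities[bi, isx, drop = FALSE]
  if (anyNA(S)) {
    stop("internal standards carry missing values in biological samples",
         call. = FALSE)
  }
  list(bi = bi, qi = which(ft$samples$role == "qc"),
       isx = isx, fx = setdiff(seq_len(ncol(ft$intensities)), isx))
}

#' Normalize by multiple internal standards (NOMIS or CCMN)
#'
#' Removes sample-wise technical variation using the spiked internal
#' standards, on the natural-log scale.
#'
#' `method = "nomis"`: each non-IS feature's log intensity is adjusted by
#' subtracting its least-squares projection onto the column-centered log-IS
#' matrix — all variation explainable by the standards is removed.
#'
#' `method = "ccmn"`: variation correlated with the group design is first
#' removed from the log-IS matrix (residuals of the IS regressed on the
#' centered case/control indicator), principal components of those residuals
#' are extracted, and each feature's projection onto those components is
#' subtracted — so group signal carried by the standards cannot be removed
#' from the features.
#'
#' The model is fitted on biological samples and applied to biological and
#' QC samples (QC internal standards are centered with the biological IS
#' means); blanks are untouched. IS features are returned unchanged.
#'
#' @param ft A `feature_table` with >= 2 internal standards, complete in
#'   biological samples.
#' @param method `"nomis"` or `"ccmn"`.
#' @param n_pc Number of IS-residual principal components used by CCMN;
#'   default: components explaining 90% of the residual variance.
#' @return A normalized `feature_table`.
#' @export
normalize_internal_standards <- function(ft, method = c("nomis", "ccmn"),
                                         n_pc = NULL) {
  method <- match.arg(method)
  parts <- .is_norm_parts(ft)
  bi <- parts$bi
  x <- ft$intensities
  if (anyNA(x[bi, parts$fx])) {
    stop("biological samples carry missing values; impute before IS ",
         "normalization", call. = FALSE)
  }
  S <- log(x[bi, parts$isx, drop = FALSE])
  s_means <- colMeans(S)
  Sc <- sweep(S, 2, s_means)
  L <- safe_log(x[bi, parts$fx, drop = FALSE])

  if (method == "nomis") {
    reg <- Sc
  } else {
    y <- as.numeric(ft$samples$group[bi] == "PD")
    yc <- y - mean(y)
    denom <- sum(yc^2)
    Sr <- if (denom > 0) Sc - outer(yc, drop(crossprod(yc, Sc)) / denom) else Sc
    pc <- svd(Sr, nu = 0)
    if (is.null(n_pc)) {
      v <- pc$d^2
      n_pc <- if (sum(v) > 0) which(cumsum(v) / sum(v) >= 0.9)[1] else 1
    }
    n_pc <- min(n_pc, ncol(Sr))
    reg <- Sr %*% pc$v[, seq_len(n_pc), drop = FALSE]
  }

  # least-squares projection via thin SVD (tolerant of rank deficiency)
  proj <- function(Rc, Y) {
    sv <- svd(Rc)
    pos <- sv$d > max(sv$d[1], 0) * 1e-10
    if (!any(pos)) return(list(fit = Y * 0, beta = NULL, sv = sv, pos = pos))
    U <- sv$u[, pos, drop = FALSE]
    fit <- U %*% crossprod(U, sweep(Y, 2, colMeans(Y)))
    list(fit = fit, sv = sv, pos = pos)
  }
  pr <- proj(reg, L)
  x[bi, parts$fx] <- exp(L - pr$fit)

  qi <- parts$qi
  if (length(qi) > 0 && !anyNA(x[qi, parts$isx]) && any(pr$pos)) {
    Sq <- sweep(log(x[qi, parts$isx, drop = FALSE]), 2, s_means)
    regq <- if (method == "nomis") Sq else {
      # same design-orthogonal rotation as fitted on biological samples
      Sq %*% svd(if (exists("Sr")) Sr else Sc, nu = 0)$v[, seq_len(ncol(reg)),
                                                         drop = FALSE]
    }
    sv <- pr$sv
    # coefficients of L on reg in the fitted basis
    Dinv <- 1 / sv$d[pr$pos]
    B <- sv$v[, pr$pos, drop = FALSE] %*%
      (Dinv * crossprod(sv$u[, pr$pos, drop = FALSE],
                        sweep(L, 2, colMeans(L))))
    Lq <- safe_log(x[qi, parts$fx, drop = FALSE])
    ok <- !is.na(rowSums(Sq))
    if (any(ok)) {
      x[qi[ok], parts$fx] <- exp(Lq[ok, , drop = FALSE] -
                                   regq[ok, , drop = FALSE] %*% B)
    }
  }
  out <- ft
  out$intensities <- x
  validate_feature_table(out)
  out
}

#' Mean total-ion-chromatogram (TIC) normalization
#'
#' Scales each sample so its summed intensity over present
#' non-internal-standard features equals the grand mean of the biological
#' sample sums. QC and blank samples are scaled to the same target using
#' their own sums. After normalization all biological sample sums are equal
#' to within 1e-9 relative tolerance.
#'
#' @param ft A `feature_table` in which every biological sample has at
#'   least one present intensity.
#' @return A `feature_table`.
#' @export
normalize_tic <- function(ft) {
  fx <- setdiff(seq_len(ncol(ft$intensities)), is_idx(ft))
  sums <- rowSums(ft$intensities[, fx, drop = FALSE], na.rm = TRUE)
  bi <- bio_idx(ft)
  zero <- which(sums == 0)
  if (length(zero) > 0) {
    stop("zero-sum sample: ", ft$samples$id[zero[1]], call. = FALSE)
  }
  target <- mean(sums[bi])
  out <- ft
  out$intensities <- ft$intensities * (target / sums)
  out
}

#' Per-feature relative standard deviation over QC replicates
#'
#' RSD_f = 100 * sd_f / mean_f over the pooled-QC samples; the replicate RSD
#' of periodically injected QCs measures technical precision (acceptable
#' tables show a median below 15%).
#'
#' @param ft A `feature_table` with >= 2 QC samples.
#' @return Tibble (`id`, `qc_mean`, `qc_sd`, `rsd_percent`) with attribute
#'   `"median_rsd_percent"`.
#' @export
qc_rsd_report <- function(ft) {
  qi <- which(ft$samples$role == "qc")
  if (length(qi) < 2) stop("need >= 2 QC samples", call. = FALSE)
  x <- ft$intensities[qi, , drop = FALSE]
  m <- colMeans(x, na.rm = TRUE)
  s <- apply(x, 2, stats::sd, na.rm = TRUE)
  out <- tibble::tibble(
    id = ft$features$id,
    qc_mean = unname(m),
    qc_sd = unname(s),
    rsd_percent = unname(100 * s / m)
  )
  attr(out, "median_rsd_percent") <-
    stats::median(out$rsd_percent, na.rm = TRUE)
  out
}

#' Run the fixed preprocessing chain with a provenance log
#'
#' Applies, in order: minimum-intensity filter, blank filter, missing-value
#' imputation (dropping features > `max_missing` missing), internal-standard
#' normalization (one or more methods, applied sequentially), and TIC
#' normalization. The provenance attribute records the feature count after
#' each stage.
#'
#' @param ft A `feature_table`.
#' @param min_intensity Minimum detectable intensity threshold.
#' @param max_missing Per-feature tolerated missing fraction.
#' @param is_norm Character vector drawn from `c("nomis", "ccmn")`, applied
#'   in the given order; `character(0)` skips IS normalization.
#' @param tic Apply TIC normalization last?
#' @param n_components Latent dimensionality for imputation.
#' @return A `feature_table` with attribute `"provenance"`: tibble
#'   (`stage`, `features_before`, `features_after`).
#' @export
preprocess <- function(ft, min_intensity = 2000, max_missing = 0.10,
                       is_norm = c("nomis", "ccmn"), tic = TRUE,
                       n_components = NULL) {
  prov <- list()
  note <- function(stage, before, after) {
    prov[[length(prov) + 1]] <<- tibble::tibble(
      stage = stage, features_before = before, features_after = after)
  }
  n0 <- ncol(ft$intensities)
  ft <- filter_min_intensity(ft, min_intensity)
  note("min_intensity", n0, ncol(ft$intensities))
  n0 <- ncol(ft$intensities)
  if (any(ft$samples$role == "blank")) {
    ft <- filter_blank(ft)
    note("blank_filter", n0, ncol(ft$intensities))
  }
  n0 <- ncol(ft$intensities)
  ft <- impute_missing(ft, max_missing_fraction = max_missing,
                       n_components = n_components)
  note("imputation", n0, ncol(ft$intensities))
  for (m in is_norm) {
    ft <- normalize_internal_standards(ft, method = m)
    note(paste0("is_norm_", m), ncol(ft$intensities), ncol(ft$intensities))
  }
  if (tic) {
    ft <- normalize_tic(ft)
    note("tic", ncol(ft$intensities), ncol(ft$intensities))
  }
  attr(ft, "provenance") <- dplyr::bind_rows(prov)
  ft
}
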