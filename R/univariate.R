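#' Log2 fold difference between group means
#'
#' `log2(mean_case / mean_control)` — the effect measure reported per
#' metabolite (PD vs control).
#'
#' @param mean_case,mean_control Group mean intensities, both > 0.
#' @return log2 ratio (vectorized).
#' @export
log2_fold_difference <- function(mean_case, mean_control) {
  if (any(mean_case <= 0) || any(mean_control <= 0)) {
    stop("group means must be > 0", call. = FALSE)
  }
  log2(mean_case / mean_control)
}

#' Normality-gated two-sample test
#'
#' Shapiro-Wilk is applied per group at `alpha_normality`; if BOTH groups
#' look normal (p > alpha) the groups are compared with a two-sided Welch
#' t-test, otherwise with the two-sided Wilcoxon rank-sum test. The result
#' records which branch ran.
#'
#' @param values_case,values_control Numeric vectors, >= 3 each.
#' @param alpha_normality Normality gate (default 0.05).
#' @return One-row tibble (`test`, `p`).
#' @export
group_test <- function(values_case, values_control, alpha_normality = 0.05) {
  if (length(values_case) < 3 || length(values_control) < 3) {
    stop("need >= 3 values per group", call. = FALSE)
  }
  if (stats::sd(values_case) == 0 && stats::sd(values_control) == 0 &&
      values_case[1] == values_control[1]) {
    warning("both groups constant and equal; p = 1")
    return(tibble::tibble(test = "welch", p = 1))
  }
  sw_ok <- function(v) {
    if (stats::sd(v) == 0) return(FALSE)
    stats::shapiro.test(v)$p.value > alpha_normality
  }
  if (sw_ok(values_case) && sw_ok(values_control)) {
    p <- stats::t.test(values_case, values_control)$p.value
    tibble::tibble(test = "welch", p = p)
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(values_case, values_control, exact = FALSE)$p.value)
    tibble::tibble(test = "wilcoxon", p = p)
  }
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjusted p-values (monotone, order-preserving, capped at 1),
#' via `stats::p.adjust`.
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @return Adjusted p-values, same order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Univariate AUC with bootstrap confidence interval
#'
#' Point AUC by the Mann-Whitney formulation using the raw intensities as
#' scores; the 95% CI is the 2.5/97.5 percentile interval of the AUC over
#' `n_boot` stratified bootstrap resamples (resampling within each class,
#' preserving class sizes).
#'
#' @param values_case,values_control Numeric vectors, >= 2 each.
#' @param n_boot Bootstrap resamples (default 500).
#' @param seed Integer seed.
#' @return One-row tibble (`auc`, `ci_lower`, `ci_upper`).
#' @export
bootstrap_auc <- function(values_case, values_control, n_boot = 500,
                          seed = 1L) {
  stopifnot(length(values_case) >= 2, length(values_control) >= 2)
  lab <- c(rep(TRUE, length(values_case)), rep(FALSE, length(values_control)))
  point <- roc_auc(lab, c(values_case, values_control))
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(i) {
    vc <- sample(values_case, replace = TRUE)
    v0 <- sample(values_control, replace = TRUE)
    roc_auc(lab, c(vc, v0))
  }, numeric(1))
  qs <- stats::quantile(reps, c(0.025, 0.975), names = FALSE)
  tibble::tibble(auc = point, ci_lower = qs[1], ci_upper = qs[2])
}

#' Per-metabolite summary table for a selected panel
#'
#' One row per panel metabolite in the layout of a biomarker results table:
#' group means, RSD over all biological samples, log2 fold difference
#' (PD/control), the normality-gated test p-value with BH-FDR correction
#' (across the panel), univariate bootstrap AUC with 95% CI, the PLS VIP
#' rank, and the RF importance rank with a "RF selected" flag for features
#' inside the top `rf_top`.
#'
#' @param ft A preprocessed, imputed `feature_table`.
#' @param panel_ids Character vector of selected feature ids.
#' @param pls_ranking Optional character vector: all feature ids in PLS-VIP
#'   rank order.
#' @param rf_ranking Optional character vector: all feature ids in RF
#'   importance rank order.
#' @param rf_top RF rank cutoff for the `rf_selected` flag (default 22).
#' @param n_boot,seed Bootstrap parameters for the AUC CIs.
#' @return Tibble of `univariate_result` rows.
#' @export
table_report <- function(ft, panel_ids, pls_ranking = NULL,
                         rf_ranking = NULL, rf_top = 22, n_boot = 500,
                         seed = 1L) {
  if (length(panel_ids) == 0) {
    return(tibble::tibble(
      id = character(0), annotation = character(0),
      mean_control = numeric(0), mean_case = numeric(0),
      rsd_percent = numeric(0), log2_fd = numeric(0), test = character(0),
      p = numeric(0), p_fdr = numeric(0), auc = numeric(0),
      ci_lower = numeric(0), ci_upper = numeric(0),
      pls_rank = integer(0), rf_rank = integer(0), rf_selected = logical(0)))
  }
  bi <- bio_idx(ft)
  grp <- ft$samples$group[bi]
  rows <- purrr::map(seq_along(panel_ids), function(i) {
    fid <- panel_ids[i]
    v <- ft$intensities[bi, fid]
    vc <- v[grp == "PD"]
    v0 <- v[grp == "control"]
    gt <- group_test(vc, v0)
    ba <- bootstrap_auc(vc, v0, n_boot = n_boot, seed = seed + i)
    tibble::tibble(
      id = fid,
      annotation = ft$features$annotation[ft$features$id == fid],
      mean_control = mean(v0),
      mean_case = mean(vc),
      rsd_percent = 100 * stats::sd(v) / mean(v),
      log2_fd = log2_fold_difference(mean(vc), mean(v0)),
      test = gt$test,
      p = gt$p,
      auc = ba$auc,
      ci_lower = ba$ci_lower,
      ci_upper = ba$ci_upper
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_fdr <- bh_fdr(out$p)
  out$pls_rank <- if (!is.null(pls_ranking))
    match(out$id, pls_ranking) else NA_integer_
  out$rf_rank <- if (!is.null(rf_ranking))
    match(out$id, rf_ranking) else NA_integer_
  out$rf_selected <- !is.na(out$rf_rank) & out$rf_rank <= rf_top
  dplyr::relocate(out, "p_fdr", .after = "p")
}
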