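#' Describe a synthetic case/control cohort
#'
#' A `cohort_design` holds every parameter of the synthetic feature-table
#' generator. Defaults mirror the plasma arm of an early-PD biomarker study
#' design: 80 cases vs 76 controls, 334 features of which 20 carry planted
#' group effects at |log2 fold difference| in \[0.05, 0.5\], spiked internal
#' standards, blanks, pooled-QC replicates, sporadic missingness, and linear
#' age/sex covariate effects.
#'
#' @param n_case,n_control Biological sample counts per group.
#' @param n_features Total feature count (internal standards included).
#' @param n_discriminative Features carrying a planted group effect.
#' @param effect_log2fd_range Interval of |log2 fold difference| (PD/control)
#'   for planted effects; the sign is random.
#' @param base_log_mean_range Interval of per-feature baseline natural-log
#'   mean intensity.
#' @param biological_cv Biological coefficient of variation (fraction).
#' @param technical_rsd Target relative standard deviation of pooled-QC
#'   replicates (fraction).
#' @param sample_factor_sd SD (log units) of the per-sample multiplicative
#'   technical factor, shared with internal standards so internal-standard
#'   normalization can remove it.
#' @param missing_rate Missing-completely-at-random rate over biological
#'   non-internal-standard cells, in \[0, 0.3\].
#' @param missing_mode `"mcar"` (default) or `"censor"` (low intensities
#'   preferentially missing).
#' @param n_internal_standards,n_blanks,n_qc Counts of spiked internal
#'   standards, blank (extraction solvent) samples, and pooled-QC replicates.
#' @param blank_signal_fraction Fraction of the biological median intensity
#'   carried by blanks for ordinary features.
#' @param n_contaminant_features Features HIGHER in blanks than in biology
#'   (planted contaminants that blank filtering should remove).
#' @param age_range Years, uniform in both groups (age-matched design).
#' @param n_age_affected Features with a linear age effect.
#' @param age_slope_sd Scale of planted age slopes, expressed per year as a
#'   multiple of the feature's own biological intensity SD.
#' @param n_sex_affected Features with a male/female mean shift.
#' @param sex_shift_sd Scale of planted sex shifts, as a multiple of the
#'   feature's biological intensity SD.
#' @param matrix `"plasma"` or `"csf"` label stamped on samples.
#' @param seed Integer seed; identical design + seed gives a bit-identical
#'   table.
#'
#' @return A `cohort_design` (list with class attribute).
#' @seealso [generate_cohort()], [plasma_design()], [csf_design()]
#' @export
cohort_design <- function(n_case = 80, n_control = 76, n_features = 334,
                          n_discriminative = 20,
                          effect_log2fd_range = c(0.05, 0.5),
                          base_log_mean_range = c(log(2.5e3), log(8e5)),
                          biological_cv = 0.25, technical_rsd = 0.12,
                          sample_factor_sd = 0.15,
                          missing_rate = 0.05, missing_mode = "mcar",
                          n_internal_standards = 8, n_blanks = 6, n_qc = 10,
                          blank_signal_fraction = 0.05,
                          n_contaminant_features = 5,
                          age_range = c(45, 85), n_age_affected = 30,
                          age_slope_sd = 0.08, n_sex_affected = 20,
                          sex_shift_sd = 0.5, matrix = "plasma", seed = 1L) {
  d <- structure(as.list(environment()), class = "cohort_design")
  stopifnot(
    d$n_case >= 0, d$n_control >= 0, d$n_features > 0,
    d$n_internal_standards >= 2, d$n_blanks >= 0, d$n_qc >= 0,
    d$missing_rate >= 0, d$missing_rate <= 0.3,
    d$blank_signal_fraction >= 0, d$blank_signal_fraction <= 1,
    d$biological_cv >= 0, d$technical_rsd >= 0,
    d$missing_mode %in% c("mcar", "censor"),
    d$matrix %in% c("plasma", "csf")
  )
  n_free <- d$n_features - d$n_internal_standards
  if (d$n_discriminative > n_free) {
    stop("n_discriminative (", d$n_discriminative,
         ") exceeds non-internal-standard features (", n_free, ")",
         call. = FALSE)
  }
  if (d$n_contaminant_features + d$n_discriminative > n_free) {
    stop("too many contaminant + discriminative features for n_features",
         call. = FALSE)
  }
  d
}

#' Plasma-scale and CSF-scale study designs
#'
#' Presets matching the two cohort arms the generator emulates: 80/76
#' biological samples with 334 features and 20 planted markers (plasma), and
#' 40/37 samples with 302 features and 14 planted markers (CSF).
#'
#' @param ... Overrides passed to [cohort_design()].
#' @return A `cohort_design`.
#' @export
plasma_design <- function(...) {
  args <- utils::modifyList(
    list(n_case = 80, n_control = 76, n_features = 334,
         n_discriminative = 20, matrix = "plasma"),
    list(...))
  do.call(cohort_design, args)
}

#' @rdname plasma_design
#' @export
csf_design <- function(...) {
  args <- utils::modifyList(
    list(n_case = 40, n_control = 37, n_features = 302,
         n_discriminative = 14, matrix = "csf"),
    list(...))
  do.call(cohort_design, args)
}

#' Generate a synthetic case/control feature table with ground truth
#'
#' Intensities follow a log-normal model: a per-feature baseline log-mean is
#' drawn from `base_log_mean_range`; discriminative features multiply the
#' case-group mean by `2^log2fd` with `|log2fd|` uniform in
#' `effect_log2fd_range` and random sign; biological noise is log-normal at
#' `biological_cv`; a per-sample multiplicative technical factor is shared
#' with the internal standards (so IS normalization can remove it); QC
#' samples are replicates of the pooled biological mean at `technical_rsd`;
#' blanks carry `blank_signal_fraction` of the biological median except for
#' planted contaminants (higher in blanks); MCAR missingness applies to
#' biological non-IS cells only; age and sex effects are added linearly on
#' the intensity scale, scaled to each feature's biological SD.
#'
#' @param design A [cohort_design()].
#' @param feature_ids Optional character vector of `n_features` feature ids
#'   (the trailing `n_internal_standards` ids are the internal standards);
#'   defaults to `M0001...` plus `IS1...`.
#' @return List with elements `table` (a [feature_table()]) and `truth`
#'   (a `ground_truth`: tibbles of planted discriminative/age/sex effects,
#'   contaminant ids and outlier sample ids).
#' @export
generate_cohort <- function(design, feature_ids = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  d <- design
  set.seed(d$seed)
  n_bio <- d$n_case + d$n_control
  n_is <- d$n_internal_standards
  n_free <- d$n_features - n_is

  if (is.null(feature_ids)) {
    feature_ids <- c(sprintf("M%04d", seq_len(n_free)),
                     sprintf("IS%d", seq_len(n_is)))
  }
  stopifnot(length(feature_ids) == d$n_features,
            !anyDuplicated(feature_ids))
  free_ids <- feature_ids[seq_len(n_free)]
  is_ids <- feature_ids[n_free + seq_len(n_is)]

  # planted feature roles: discriminative, contaminant, age, sex
  disc <- if (d$n_discriminative > 0) sample(free_ids, d$n_discriminative)
          else character(0)
  contam_pool <- setdiff(free_ids, disc)
  contam <- if (d$n_contaminant_features > 0)
    sample(contam_pool, d$n_contaminant_features) else character(0)
  cov_pool <- setdiff(free_ids, c(disc, contam))
  age_ids <- if (d$n_age_affected > 0)
    sample(cov_pool, min(d$n_age_affected, length(cov_pool))) else character(0)
  sex_pool <- setdiff(cov_pool, age_ids)
  sex_ids <- if (d$n_sex_affected > 0)
    sample(sex_pool, min(d$n_sex_affected, length(sex_pool))) else character(0)

  log2fd <- stats::setNames(rep(0, n_free), free_ids)
  if (length(disc) > 0) {
    mag <- stats::runif(length(disc), d$effect_log2fd_range[1],
                        d$effect_log2fd_range[2])
    log2fd[disc] <- mag * sample(c(-1, 1), length(disc), replace = TRUE)
  }

  # sample metadata
  grp <- c(rep("PD", d$n_case), rep("control", d$n_control))
  bio_ids <- c(sprintf("PD%03d", seq_len(d$n_case)),
               sprintf("CO%03d", seq_len(d$n_control)))
  sex <- ifelse(stats::runif(n_bio) < 0.64, "M", "F")
  age <- stats::runif(n_bio, d$age_range[1], d$age_range[2])
  ledd <- ifelse(grp == "PD", stats::rlnorm(n_bio, log(208), 0.9), NA_real_)

  # baselines and noise scales (log, natural)
  m <- stats::runif(n_free, d$base_log_mean_range[1], d$base_log_mean_range[2])
  names(m) <- free_ids
  s_bio <- sqrt(log(1 + d$biological_cv^2))
  tech <- stats::rnorm(n_bio, 0, d$sample_factor_sd)  # log sample factor

  # biological block, log scale: baseline + group effect + noise + factor
  L <- matrix(stats::rnorm(n_bio * n_free, 0, s_bio), n_bio, n_free)
  L <- sweep(L, 2, m, "+")
  case_rows <- grp == "PD"
  L[case_rows, ] <- sweep(L[case_rows, , drop = FALSE], 2,
                          log(2) * log2fd, "+")
  L <- L + tech
  X_bio <- exp(L)
  colnames(X_bio) <- free_ids

  # additive covariate effects, scaled by the feature's biological SD
  sd_int <- exp(m) * d$biological_cv
  age_slope <- stats::setNames(numeric(0), character(0))
  if (length(age_ids) > 0) {
    age_slope <- stats::setNames(
      stats::rnorm(length(age_ids), 0, d$age_slope_sd) * sd_int[age_ids],
      age_ids)
    ac <- age - mean(age)
    for (f in age_ids) {
      X_bio[, f] <- pmax(X_bio[, f] + age_slope[[f]] * ac, 0)
    }
  }
  sex_shift <- stats::setNames(numeric(0), character(0))
  if (length(sex_ids) > 0) {
    sex_shift <- stats::setNames(
      stats::rnorm(length(sex_ids), 0, d$sex_shift_sd) * sd_int[sex_ids],
      sex_ids)
    sgn <- ifelse(sex == "M", 0.5, -0.5)
    for (f in sex_ids) {
      X_bio[, f] <- pmax(X_bio[, f] + sex_shift[[f]] * sgn, 0)
    }
  }

  # internal standards: constant spike + technical factor + small residual
  m_is <- stats::runif(n_is, log(5e4), log(2e5))
  IS_bio <- exp(matrix(stats::rnorm(n_bio * n_is, 0, 0.02), n_bio, n_is) +
                  rep(m_is, each = n_bio) + tech)
  X_bio <- cbind(X_bio, IS_bio)
  colnames(X_bio) <- feature_ids
  rownames(X_bio) <- bio_ids

  # pooled-QC replicates at the target technical RSD; half the log-variance
  # is a per-injection factor shared with the internal standards (so IS
  # normalization demonstrably tightens QC precision), half is per-feature
  s_qc <- sqrt(log(1 + d$technical_rsd^2))
  pool <- colMeans(X_bio)
  X_qc <- if (d$n_qc > 0) {
    f_inj <- stats::rnorm(d$n_qc, 0, s_qc / sqrt(2))
    q <- matrix(stats::rnorm(d$n_qc * d$n_features, 0, s_qc / sqrt(2)),
                d$n_qc, d$n_features)
    q[, n_free + seq_len(n_is)] <-
      matrix(stats::rnorm(d$n_qc * n_is, 0, 0.02), d$n_qc, n_is)
    sweep(exp(q + f_inj), 2, pool, "*")
  } else matrix(numeric(0), 0, d$n_features)

  # blanks: faint carry-over except planted contaminants; IS spiked as usual
  med_bio <- apply(X_bio, 2, stats::median)
  blank_level <- med_bio * d$blank_signal_fraction
  blank_level[contam] <- med_bio[contam] * 3
  blank_level[is_ids] <- exp(m_is)
  X_bl <- if (d$n_blanks > 0) {
    b <- exp(matrix(stats::rnorm(d$n_blanks * d$n_features, 0, 0.25),
                    d$n_blanks, d$n_features))
    sweep(b, 2, blank_level, "*")
  } else matrix(numeric(0), 0, d$n_features)

  # missingness on biological non-IS cells only
  if (d$missing_rate > 0 && n_bio > 0) {
    free_cols <- seq_len(n_free)
    if (d$missing_mode == "mcar") {
      mask <- matrix(stats::runif(n_bio * n_free) < d$missing_rate,
                     n_bio, n_free)
    } else {
      # left-censoring: drop probability decreasing in within-feature rank
      mask <- matrix(FALSE, n_bio, n_free)
      for (j in free_cols) {
        r <- rank(X_bio[, j], ties.method = "first") / n_bio
        p <- 2 * d$missing_rate * (1 - r)
        mask[, j] <- stats::runif(n_bio) < p
      }
    }
    X_bio[, free_cols][mask] <- NA_real_
  }

  x <- rbind(X_bio, X_bl, X_qc)
  qc_ids <- if (d$n_qc > 0) sprintf("QC%02d", seq_len(d$n_qc)) else character(0)
  bl_ids <- if (d$n_blanks > 0) sprintf("BL%02d", seq_len(d$n_blanks))
            else character(0)
  rownames(x) <- c(bio_ids, bl_ids, qc_ids)

  samples <- tibble::tibble(
    id = rownames(x),
    role = c(rep("biological", n_bio), rep("blank", d$n_blanks),
             rep("qc", d$n_qc)),
    group = c(grp, rep("none", d$n_blanks + d$n_qc)),
    sex = c(sex, rep("none", d$n_blanks + d$n_qc)),
    age = c(age, rep(NA_real_, d$n_blanks + d$n_qc)),
    ledd = c(ledd, rep(NA_real_, d$n_blanks + d$n_qc)),
    matrix = d$matrix
  )
  lvl <- sample(c("1", "2", "3", "unknown"), n_free, replace = TRUE,
                prob = c(0.15, 0.35, 0.3, 0.2))
  annot <- ifelse(stats::runif(n_free) < 0.09, "unknown",
                  paste0("met_", free_ids))
  features <- tibble::tibble(
    id = feature_ids,
    mz = round(stats::runif(d$n_features, 70, 1000), 5),
    rt = round(stats::runif(d$n_features, 0.1, 14), 2),
    annotation = c(annot, paste0("std_", is_ids)),
    is_internal_standard = c(rep(FALSE, n_free), rep(TRUE, n_is)),
    validation_level = c(lvl, rep("1", n_is))
  )

  truth <- structure(list(
    discriminative = tibble::tibble(id = names(log2fd)[log2fd != 0],
                                    log2fd = unname(log2fd[log2fd != 0])),
    log2fd = log2fd,
    age_affected = tibble::tibble(id = names(age_slope),
                                  slope = unname(age_slope)),
    sex_affected = tibble::tibble(id = names(sex_shift),
                                  shift = unname(sex_shift)),
    contaminant_ids = contam,
    internal_standard_ids = is_ids,
    outlier_sample_ids = character(0)
  ), class = "ground_truth")

  list(table = feature_table(x, samples, features), truth = truth)
}

#' Perturb samples orthogonally to the cohort's low-rank structure
#'
#' Adds, on the natural-log scale, a perturbation orthogonal to the dominant
#' principal subspace of the biological samples, scaled to `magnitude` times
#' the typical residual norm — i.e. planted orthogonal-distance outliers
#' of the kind robust PCA screening is meant to flag.
#'
#' @param ft A `feature_table`.
#' @param truth The matching `ground_truth` (outlier ids are appended).
#' @param n_outliers Number of biological samples to perturb.
#' @param magnitude Perturbation size as a multiple of the residual scale
#'   (root-mean-square residual norm of the rank-`k` fit); must be > 0.
#' @param seed Integer seed.
#' @param k Rank of the "dominant" subspace projected out (default 5).
#' @return List with the perturbed `table` and updated `truth`.
#' @export
plant_outliers <- function(ft, truth, n_outliers, magnitude, seed = 1L,
                           k = 5) {
  if (n_outliers == 0) return(list(table = ft, truth = truth))
  if (magnitude <= 0) stop("magnitude must be > 0", call. = FALSE)
  bi <- bio_idx(ft)
  if (n_outliers > length(bi)) {
    stop("n_outliers exceeds biological sample count", call. = FALSE)
  }
  set.seed(seed)
  fi <- setdiff(seq_len(ncol(ft$intensities)), is_idx(ft))
  x <- ft$intensities[bi, fi, drop = FALSE]
  obs <- !is.na(x)
  L <- safe_log(ifelse(obs, x, 1))
  # column-mean fill of missing cells for the structure fit only
  cm <- colSums(L * obs) / pmax(colSums(obs), 1)
  L[!obs] <- cm[col(L)[!obs]]
  Lc <- sweep(L, 2, colMeans(L))
  k <- min(k, nrow(Lc) - 1, ncol(Lc) - 1)
  sv <- svd(Lc, nu = 0, nv = k)
  V <- sv$v
  resid <- Lc - (Lc %*% V) %*% t(V)
  resid_scale <- sqrt(mean(rowSums(resid^2)))
  targets <- sample(seq_len(nrow(L)), n_outliers)
  out <- ft
  for (i in targets) {
    v <- stats::rnorm(ncol(L))
    v <- v - V %*% (t(V) %*% v)
    v <- v / sqrt(sum(v^2))
    li <- L[i, ] + magnitude * resid_scale * v
    newint <- exp(li)
    keep <- obs[i, ]
    out$intensities[bi[i], fi[keep]] <- newint[keep]
  }
  truth$outlier_sample_ids <- union(truth$outlier_sample_ids,
                                    ft$samples$id[bi][targets])
  list(table = out, truth = truth)
}
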