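test_that("minimum-intensity filter drops exactly the sub-threshold features", {
  x <- matrix(c(5000, 4000, 3000, 2500,   # F001 max 5000 -> keep
                1500, 1400, 1200, 1100,   # F002 max 1500 -> drop
                2000, 1900, 1800, 1700,   # F003 max 2000 -> keep (>= thr)
                900,  800,  700,  600,    # F004 max 900  -> drop
                8000, 7000, 6000, 5000),  # F005 keep
              4, 5)
  ft <- mk_ft(x)
  out <- filter_min_intensity(ft, 2000)
  expect_identical(out$features$id, c("F001", "F003", "F005"))
  expect_setequal(attr(out, "removed")$id, c("F002", "F004"))

  # all features above threshold: identity; and idempotence
  ok <- filter_min_intensity(ft, 500)
  expect_identical(ok$intensities, ft$intensities)
  twice <- filter_min_intensity(out, 2000)
  expect_identical(twice$intensities, out$intensities)
})

test_that("blank filter removes features dominated by blanks, per group", {
  # F001: clear biological signal -> kept; F002: blank-dominated -> removed
  # F003: below blank in PD only -> kept (every group must be below)
  x <- rbind(
    c(5000, 90, 50), c(5200, 110, 60),           # PD
    c(4800, 95, 5000), c(4900, 105, 5200),       # control
    c(100, 1000, 1000), c(110, 1050, 900))       # blanks
  ft <- mk_ft(x, role = c(rep("biological", 4), "blank", "blank"),
              group = c("PD", "PD", "control", "control", "none", "none"))
  out <- filter_blank(ft)
  expect_identical(out$features$id, c("F001", "F003"))
  expect_identical(attr(out, "removed")$id, "F002")

  no_blank <- mk_ft(x[1:4, ])
  expect_error(filter_blank(no_blank), "no blank samples")
})

test_that("planted contaminants are exactly the blank-removed features", {
  hits <- vapply(1:20, function(s) {
    sim <- small_cohort(seed = s, missing_rate = 0)
    out <- filter_blank(sim$table)
    removed <- attr(out, "removed")$id
    exact <- setequal(removed, sim$truth$contaminant_ids)
    false_remove <- length(setdiff(removed, sim$truth$contaminant_ids))
    c(exact, false_remove)
  }, numeric(2))
  expect_gte(mean(hits[1, ]), 0.95)
  expect_lt(sum(hits[2, ]) / (20 * 52), 0.01)  # false-removal rate < 1%
})

test_that("imputation is exact on noiseless rank-1 data, no-op when complete", {
  set.seed(1)
  u <- rlnorm(20, 2, 0.5)
  v <- rlnorm(10, 3, 0.3)
  x <- outer(u, v)
  ft_complete <- mk_ft(x)
  expect_identical(impute_missing(ft_complete)$intensities,
                   ft_complete$intensities)

  xm <- x
  xm[3, 4] <- NA
  ft <- mk_ft(xm)
  out <- impute_missing(ft, n_components = 2)
  expect_lt(abs(out$intensities[3, 4] - x[3, 4]) / x[3, 4], 1e-6)
  # observed cells never altered
  expect_identical(out$intensities[-3, ], ft$intensities[-3, ])
})

test_that("features over the missingness cap are dropped, the rest completed", {
  set.seed(2)
  x <- matrix(rlnorm(200, 8, 0.4), 20, 10)
  x[1:5, 1] <- NA           # 25% missing -> dropped
  x[1, 2] <- NA             # 5% -> imputed
  ft <- mk_ft(x)
  out <- impute_missing(ft, max_missing_fraction = 0.10, n_components = 3)
  expect_false("F001" %in% out$features$id)
  expect_identical(attr(out, "removed")$id, "F001")
  expect_false(anyNA(out$intensities))
  expect_true(all(out$intensities > 0))
})

test_that("BPCA beats mean imputation on noisy low-rank data", {
  wins <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 60; p <- 30
    Z <- matrix(rnorm(n * 3), n, 3) %*% matrix(rnorm(3 * p, 0, 1), 3, p)
    x <- Z + matrix(rnorm(n * p, 0, 0.3), n, p) + 8
    mask <- matrix(runif(n * p) < 0.05, n, p)
    xm <- x
    xm[mask] <- NA
    bp <- bpca_impute(xm, n_components = 6)
    mu <- colMeans(xm, na.rm = TRUE)
    mean_fill <- xm
    mean_fill[mask] <- mu[col(x)[mask]]
    err <- function(f) median(abs((f[mask] - x[mask]) / x[mask]))
    err(bp) < err(mean_fill)
  }, logical(1))
  expect_gte(sum(wins), 18)
})

test_that("NOMIS removes the planted sample-wise technical factor", {
  res <- vapply(1:10, function(s) {
    sim <- generate_cohort(cohort_design(
      n_case = 25, n_control = 25, n_features = 60, n_discriminative = 0,
      missing_rate = 0, n_contaminant_features = 0, n_age_affected = 0,
      n_sex_affected = 0, sample_factor_sd = 0.2, seed = s))
    cv_of <- function(ft) {
      mm <- ft_model_matrix(ft, log = FALSE)
      median(apply(mm$x, 2, function(v) sd(v) / mean(v)))
    }
    post <- normalize_internal_standards(sim$table, "nomis")
    cv_of(post) < cv_of(sim$table)
  }, logical(1))
  expect_true(all(res))
})

test_that("constant internal standards make IS normalization the identity", {
  set.seed(3)
  x <- matrix(rlnorm(80, 8, 0.3), 10, 8)
  x[, 7] <- 1e5
  x[, 8] <- 2e5
  ft <- mk_ft(x, is_flag = c(rep(FALSE, 6), TRUE, TRUE))
  out <- normalize_internal_standards(ft, "nomis")
  expect_equal(out$intensities, ft$intensities, tolerance = 1e-10)

  one_is <- mk_ft(x, is_flag = c(rep(FALSE, 7), TRUE))
  expect_error(normalize_internal_standards(one_is, "nomis"), ">= 2 IS")
})

test_that("CCMN preserves planted group effects carried by features only", {
  devs <- vapply(1:10, function(s) {
    sim <- generate_cohort(cohort_design(
      n_case = 60, n_control = 60, n_features = 80, n_discriminative = 10,
      effect_log2fd_range = c(0.3, 0.6), missing_rate = 0,
      n_contaminant_features = 0, n_age_affected = 0, n_sex_affected = 0,
      biological_cv = 0.1, sample_factor_sd = 0.1, seed = s))
    post <- normalize_internal_standards(sim$table, "ccmn")
    mm <- ft_model_matrix(post, log = FALSE)
    truth <- sim$truth$discriminative
    emp <- vapply(truth$id, function(f) {
      log2(mean(mm$x[mm$y == "PD", f]) / mean(mm$x[mm$y == "control", f]))
    }, numeric(1))
    pre <- ft_model_matrix(sim$table, log = FALSE)
    emp0 <- vapply(truth$id, function(f) {
      log2(mean(pre$x[pre$y == "PD", f]) / mean(pre$x[pre$y == "control", f]))
    }, numeric(1))
    max(abs(emp - emp0))  # group signal unchanged by the normalization
  }, numeric(1))
  expect_lt(median(devs), 0.02)
})

test_that("TIC normalization equalizes biological sample sums exactly", {
  x <- rbind(c(60, 40), c(100, 200))  # sums 100 and 300 -> both 200
  ft <- mk_ft(x)
  out <- normalize_tic(ft)
  expect_equal(unname(rowSums(out$intensities)), c(200, 200))

  sim <- small_cohort(seed = 6)
  pp <- impute_missing(filter_blank(filter_min_intensity(sim$table)))
  post <- normalize_tic(pp)
  bi <- which(post$samples$role == "biological")
  fx <- which(!post$features$is_internal_standard)
  sums <- rowSums(post$intensities[bi, fx], na.rm = TRUE)
  expect_lt(sd(sums) / mean(sums), 1e-9)

  zero <- mk_ft(rbind(c(1, 1), c(0, 0)))
  expect_error(normalize_tic(zero), "zero-sum sample: S002")
})

test_that("QC RSD report matches the hand calculation", {
  x <- rbind(c(90, 50), c(100, 50), c(110, 50))
  ft <- mk_ft(x, role = rep("qc", 3))
  rep <- qc_rsd_report(ft)
  expect_equal(rep$rsd_percent[1], 10)   # sd 10, mean 100
  expect_equal(rep$rsd_percent[2], 0)    # identical replicates
  expect_error(qc_rsd_report(mk_ft(x[1, , drop = FALSE], role = "qc")),
               ">= 2 QC")
})

test_that("the preprocessing chain logs feature counts per stage", {
  sim <- small_cohort(seed = 8)
  pp <- preprocess(sim$table)
  prov <- attr(pp, "provenance")
  expect_identical(prov$stage[1:3],
                   c("min_intensity", "blank_filter", "imputation"))
  expect_true(all(diff(prov$features_after[1:3]) <= 0))
  expect_false(anyNA(pp$intensities[which(pp$samples$role == "biological"), ]))
})
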