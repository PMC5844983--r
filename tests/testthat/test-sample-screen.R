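test_that("exact low-rank data yields zero orthogonal distances, no flags", {
  set.seed(1)
  # rank-2 structure in log space, no residual noise
  Z <- matrix(rnorm(30 * 2), 30, 2) %*% matrix(rnorm(2 * 15), 2, 15)
  ft <- mk_ft(exp(Z + 8))
  rep <- robust_pca_distances(ft, k = 2, seed = 1)
  expect_lt(max(rep$orthogonal_distance), 1e-6)
  expect_false(any(rep$flagged))
})

test_that("clean Gaussian low-rank data is rarely flagged", {
  rates <- vapply(1:10, function(s) {
    set.seed(s)
    Z <- matrix(rnorm(100 * 3), 100, 3) %*% matrix(rnorm(3 * 50, 0, 2), 3, 50)
    x <- exp((Z + matrix(rnorm(100 * 50, 0, 0.3), 100, 50)) / 4 + 8)
    mean(robust_pca_distances(mk_ft(x), seed = s)$flagged)
  }, numeric(1))
  expect_lte(mean(rates), 0.075)
})

test_that("flagging is invariant to feature permutation and rescaling", {
  sim <- small_cohort(seed = 10, missing_rate = 0)
  pl <- plant_outliers(sim$table, sim$truth, 3, magnitude = 8, seed = 2)
  ft <- pl$table
  r1 <- robust_pca_distances(ft, seed = 5)

  perm <- sample(ncol(ft$intensities))
  ftp <- ft_subset(ft, feature_ids = ft$features$id[perm])
  r2 <- robust_pca_distances(ftp, seed = 5)
  expect_identical(r1$flagged, r2$flagged)

  fts <- ft
  fts$intensities <- fts$intensities * 1000
  r3 <- robust_pca_distances(fts, seed = 5)
  expect_identical(r1$flagged, r3$flagged)
})

test_that("planted orthogonal outliers are flagged and dropped end to end", {
  hit <- vapply(1:10, function(s) {
    sim <- small_cohort(seed = s, missing_rate = 0.03)
    pl <- plant_outliers(sim$table, sim$truth, 4, magnitude = 10,
                         seed = s + 50)
    pp <- suppressWarnings(preprocess(pl$table))
    rep <- robust_pca_distances(pp, seed = s)
    out <- drop_outliers(pp, rep)
    none_left <- !any(pl$truth$outlier_sample_ids %in% out$samples$id)
    sens <- mean(pl$truth$outlier_sample_ids %in% rep$id[rep$flagged])
    c(none_left, sens)
  }, numeric(2))
  expect_gte(mean(hit[1, ]), 0.9)
  expect_gte(mean(hit[2, ]), 0.95)

  # empty flag set: identity; bookkeeping on a manual report
  sim <- small_cohort(seed = 3)
  rep <- robust_pca_distances(suppressWarnings(preprocess(sim$table)))
  rep$flagged <- rep(FALSE, nrow(rep))
  same <- drop_outliers(sim$table, rep)
  expect_identical(same$intensities, sim$table$intensities)
  rep$flagged[1:2] <- TRUE
  fewer <- drop_outliers(sim$table, rep)
  expect_identical(sum(fewer$samples$role == "biological"),
                   sum(sim$table$samples$role == "biological") - 2L)
})

test_that("age correction flattens significant slopes and is idempotent", {
  ok <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 100
    age <- runif(n, 45, 85)
    x <- cbind(10 * age + rnorm(n, 0, 10),     # strong slope
               rnorm(n, 500, 5))               # null feature
    ft <- mk_ft(x, age = age)
    out <- correct_age(ft)
    corr <- attr(out, "corrected")
    slope_gone <- if ("F001" %in% corr$id) {
      refit <- summary(lm(out$intensities[, 1] ~ age))
      refit$coefficients["age", "Pr(>|t|)"] > 0.05
    } else FALSE
    slope_gone
  }, logical(1))
  expect_gte(mean(ok), 0.9)

  # planted age effects in the generator are mostly detected
  found <- vapply(1:10, function(s) {
    sim <- generate_cohort(cohort_design(
      n_case = 60, n_control = 60, n_features = 80, n_discriminative = 0,
      n_age_affected = 20, missing_rate = 0, n_contaminant_features = 0,
      n_sex_affected = 0, seed = s))
    out <- correct_age(sim$table)
    mean(sim$truth$age_affected$id %in% attr(out, "corrected")$id)
  }, numeric(1))
  expect_gte(mean(found), 0.8)

  expect_error(correct_age(mk_ft(matrix(rlnorm(20, 8), 10, 2), age = 50)),
               "constant covariate")
})

test_that("gender correction equalizes sex means exactly and is idempotent", {
  x <- matrix(c(120, 120, 80, 80), 4, 1)
  ft <- mk_ft(x, sex = c("M", "M", "F", "F"))
  out <- correct_gender(ft)
  expect_equal(unname(out$intensities[, 1]), rep(100, 4))

  sim <- small_cohort(seed = 12, missing_rate = 0)
  once <- correct_gender(sim$table)
  twice <- correct_gender(once)
  expect_equal(once$intensities, twice$intensities, tolerance = 1e-12)
  bi <- which(once$samples$role == "biological")
  sex <- once$samples$sex[bi]
  dm <- colMeans(once$intensities[bi[sex == "M"], ]) -
    colMeans(once$intensities[bi[sex == "F"], ])
  expect_lt(max(abs(dm)), 1e-9)
})

test_that("LEDD screen flags planted dose slopes, errors on degenerate dose", {
  set.seed(9)
  n <- 60
  ledd <- rlnorm(n, log(200), 0.7)
  x <- cbind(5 * ledd + rnorm(n, 0, 100), rnorm(n, 5000, 100))
  ft <- mk_ft(x, group = rep("PD", n), ledd = ledd, age = runif(n, 50, 80))
  rep <- screen_ledd(ft)
  expect_true(rep$flagged[1])

  ft2 <- mk_ft(x, group = rep("PD", n), ledd = 200)
  expect_error(screen_ledd(ft2), "constant covariate")

  # null features: roughly uniform p-values
  set.seed(10)
  xn <- matrix(rnorm(60 * 300, 1000, 50), 60, 300)
  ftn <- mk_ft(xn, group = rep("PD", 60), ledd = ledd)
  repn <- screen_ledd(ftn)
  expect_gt(stats::ks.test(repn$p, "punif")$p.value, 0.01)
})

test_that("interaction screen isolates a planted age x sex interaction", {
  set.seed(11)
  n <- 80
  age <- runif(n, 45, 85)
  sex <- rep(c("M", "F"), n / 2)
  ledd <- rlnorm(n, log(200), 0.5)
  base <- matrix(rnorm(n * 20, 1000, 30), n, 20)
  base[, 1] <- base[, 1] + 8 * (age - 65) * (sex == "M")
  ft <- mk_ft(base, group = rep("PD", n), sex = sex, age = age, ledd = ledd)
  rep <- interaction_screen(ft)
  expect_lt(rep$p_age_sex[1], 0.01)
  # null terms reject at roughly the nominal rate
  expect_lt(mean(rep$p_age_sex[-1] <= 0.05), 0.3)
  expect_lt(mean(rep$p_age_ledd <= 0.05), 0.3)

  tiny <- mk_ft(base[1:5, , drop = FALSE], group = rep("PD", 5),
                sex = sex[1:5], age = age[1:5], ledd = ledd[1:5])
  expect_error(interaction_screen(tiny), "too few")
})
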