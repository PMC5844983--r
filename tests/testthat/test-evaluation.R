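test_that("roc_auc matches hand-counted pair concordance", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2)), 0.75)
  expect_equal(roc_auc(c(0, 1), c(0.1, 0.9)), 1.0)
  expect_equal(roc_auc(c(0, 0, 1, 1), rep(0.5, 4)), 0.5)  # all ties
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("roc_auc properties: complement, monotone invariance, pair oracle", {
  set.seed(1)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 2)  # rounding induces ties
    a <- roc_auc(y, s)
    # exhaustive pair counting oracle
    pos <- which(y == 1)
    neg <- which(y == 0)
    conc <- 0
    for (i1 in pos) for (i0 in neg) {
      conc <- conc + (s[i1] > s[i0]) + 0.5 * (s[i1] == s[i0])
    }
    expect_equal(a, conc / (length(pos) * length(neg)), tolerance = 1e-12)
    if (!any(duplicated(s))) {
      expect_equal(roc_auc(y, -s), 1 - a, tolerance = 1e-12)
    }
    expect_equal(roc_auc(y, exp(3 * s)), a, tolerance = 1e-12)
  }
})

test_that("confusion metrics follow the 2x2 arithmetic, NA when undefined", {
  # TP=3 FN=1 TN=2 FP=2
  y <- c(rep("PD", 4), rep("control", 4))
  s <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.55, 0.3, 0.1)
  cm <- confusion_metrics(y, s)
  expect_equal(cm$sensitivity, 0.75)
  expect_equal(cm$specificity, 0.5)
  expect_equal(cm$ppv, 0.6)
  expect_equal(cm$npv, 2 / 3)

  perfect <- confusion_metrics(y, c(1, 1, 1, 0.9, 0.1, 0, 0, 0),
                               threshold = 0.5)
  expect_equal(unlist(perfect[1, 1:4]), c(sensitivity = 1, specificity = 1,
                                          ppv = 1, npv = 1))
  none <- confusion_metrics(y, rep(0.1, 8))
  expect_true(is.na(none$ppv))  # no predicted positives: undefined, not 0
})

test_that("cross-validation separates separable data, is chance on null", {
  toy <- toy_separable(n = 40, p = 8, seed = 1)
  cv <- cross_validate(toy$x, toy$y, "pls", max_components = 3,
                       n_folds = 5, n_repeats = 2, seed = 1)
  expect_gte(max(cv$mean_cv_auc), 0.95)

  set.seed(2)
  xn <- matrix(rnorm(60 * 10), 60, 10)
  colnames(xn) <- paste0("f", 1:10)
  yn <- factor(rep(c("control", "PD"), 30))
  cvn <- cross_validate(xn, yn, "pls", max_components = 2,
                        n_folds = 5, n_repeats = 2, seed = 3)
  expect_lt(abs(cvn$mean_cv_auc[1] - 0.5), 0.15)

  # determinism: same seed, same folds, same AUCs
  cv2 <- cross_validate(toy$x, toy$y, "pls", max_components = 3,
                        n_folds = 5, n_repeats = 2, seed = 1)
  expect_identical(cv$mean_cv_auc, cv2$mean_cv_auc)

  expect_error(cross_validate(toy$x[1:8, ], toy$y[1:8], n_folds = 10),
               "fewer folds")
})

test_that("component selection maximizes CV AUC, ties to the smallest A", {
  toy <- toy_separable(n = 40, p = 8, seed = 4)
  sel <- select_components(toy$x, toy$y, max_components = 4, n_folds = 5,
                           n_repeats = 2, seed = 1)
  expect_identical(sel$n_components,
                   sel$cv$value[which.max(sel$cv$mean_cv_auc)])
  one <- select_components(toy$x, toy$y, max_components = 1, n_folds = 5,
                           n_repeats = 1, seed = 1)
  expect_identical(one$n_components, 1L)
})

test_that("two informative orthogonal directions select about two components", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 60
    y <- factor(rep(c("control", "PD"), each = n / 2))
    u1 <- ifelse(y == "PD", 1, -1) + rnorm(n, 0, 0.8)
    u2 <- ifelse(y == "PD", 1, -1) * rep(c(1, -1), n / 2) * 0.8 +
      rnorm(n, 0, 0.8)
    x <- cbind(outer(u1, rnorm(10)), outer(u2, rnorm(10))) +
      matrix(rnorm(n * 20, 0, 0.4), n, 20)
    colnames(x) <- paste0("f", 1:20)
    sel <- select_components(x, y, max_components = 6, n_folds = 5,
                             n_repeats = 2, seed = s)
    sel$n_components
  }, integer(1))
  expect_gte(mean(hits <= 3), 0.7)  # parsimonious: close to the true two
})

test_that("elbow selection matches exhaustive chord-distance search", {
  # idealized knee: flat top-20 then linear decay, mirroring a 20-marker panel
  vip <- c(rep(1, 20), seq(0.98, 0.2, length.out = 80))
  ranking <- tibble::tibble(id = sprintf("m%03d", 1:100), vip = sort(vip, TRUE))
  sel <- elbow_select(ranking)
  expect_identical(attr(sel, "elbow_rank"), 20L)
  expect_length(attr(sel, "selected_ids"), 20)

  # brute-force oracle on arbitrary curves
  set.seed(5)
  for (i in 1:20) {
    v <- sort(runif(50, 0, 2), decreasing = TRUE)
    r <- tibble::tibble(id = as.character(1:50), vip = v)
    sel <- elbow_select(r, top_n = 50)
    m <- 50
    vs <- (v - min(v)) / (max(v) - min(v))
    d <- vapply(1:m, function(j) {
      abs((vs[m] - vs[1]) * j - (m - 1) * vs[j] + m * vs[1] - vs[m]) /
        sqrt((vs[m] - vs[1])^2 + (m - 1)^2)
    }, numeric(1))
    if (!attr(sel, "weak_elbow")) {
      expect_identical(attr(sel, "elbow_rank"), which.max(d))
    } else {
      expect_lt(max(d), 0.05)
    }
  }

  # strictly linear decay: weak elbow flagged, interior midpoint used
  lin <- tibble::tibble(id = as.character(1:60),
                        vip = seq(2, 1, length.out = 60))
  sel <- elbow_select(lin, top_n = 60)
  expect_true(attr(sel, "weak_elbow"))
  expect_identical(attr(sel, "elbow_rank"), 30L)

  expect_error(elbow_select(tibble::tibble(id = "a", vip = 1)), "length >= 3")
  expect_error(elbow_select(tibble::tibble(id = c("a", "b", "c"),
                                           vip = c(1, 2, 3))),
               "non-increasing")
})

test_that("final holdout test is deterministic and leakage-free", {
  sim <- generate_cohort(cohort_design(
    n_case = 40, n_control = 40, n_features = 60, n_discriminative = 10,
    effect_log2fd_range = c(0.2, 0.5), missing_rate = 0, seed = 31))
  mm <- ft_model_matrix(normalize_internal_standards(sim$table, "nomis"))
  args <- list(x = mm$x, y = mm$y, models = "pls", max_components = 4,
               cv_folds = 5, cv_repeats = 2, seed = 7)
  a <- do.call(final_holdout_test, args)
  b <- do.call(final_holdout_test, args)
  expect_identical(a$auc, b$auc)
  expect_identical(attr(a, "panel_ids"), attr(b, "panel_ids"))

  # corrupting the held-out labels cannot change the selected panel
  tr <- attr(a, "train_ids")
  y_corrupt <- mm$y
  te <- setdiff(seq_along(mm$y), tr)
  y_corrupt[te] <- sample(y_corrupt[te])
  cc <- final_holdout_test(mm$x, y_corrupt, models = "pls",
                           max_components = 4, cv_folds = 5, cv_repeats = 2,
                           seed = 7, train_ids = tr)
  expect_identical(attr(cc, "panel_ids"), attr(a, "panel_ids"))

  expect_error(final_holdout_test(mm$x, mm$y, panel = "nope", models = "pls",
                                  cv_folds = 5, cv_repeats = 1, seed = 1),
               "absent")
})

test_that("repeated splits give a stable mean with a sane CI", {
  toy <- toy_separable(n = 40, p = 8, seed = 6)
  rs <- repeated_split_assessment(toy$x, toy$y, n_repeats = 8,
                                  models = "pls", max_components = 2,
                                  cv_folds = 5, cv_repeats = 1, seed = 1)
  summ <- attr(rs, "summary")
  expect_identical(nrow(rs), 8L)
  expect_true(summ$ci_lower <= summ$mean_auc &
                summ$mean_auc <= summ$ci_upper)
  expect_gte(summ$mean_auc, 0.9)
  expect_true(summ$initial_split_quantile >= 0 &
                summ$initial_split_quantile <= 1)
})

test_that("MCCV accuracy plateaus once the informative features are in", {
  set.seed(8)
  n <- 60
  y <- factor(rep(c("control", "PD"), each = n / 2))
  x <- matrix(rnorm(n * 20, 0, 1), n, 20)
  x[, 1] <- x[, 1] + ifelse(y == "PD", 3, -3)
  x[, 2] <- x[, 2] + ifelse(y == "PD", 3, -3)
  colnames(x) <- paste0("f", 1:20)
  mc <- mccv_validate(x, y, n_iterations = 30, panel_sizes = c(2, 5, 10, 20),
                      seed = 2)
  expect_gte(mc$mean_auc[1], 0.9)
  expect_true(all(abs(mc$mean_auc[-1] - mc$mean_auc[1]) < 0.1))
  # reproducible
  mc2 <- mccv_validate(x, y, n_iterations = 30,
                       panel_sizes = c(2, 5, 10, 20), seed = 2)
  expect_identical(mc$mean_auc, mc2$mean_auc)
})

test_that("many equally weak markers need the full panel for peak MCCV AUC", {
  sim <- generate_cohort(cohort_design(
    n_case = 60, n_control = 60, n_features = 40, n_discriminative = 14,
    effect_log2fd_range = c(0.12, 0.18), missing_rate = 0,
    n_contaminant_features = 0, n_age_affected = 0, n_sex_affected = 0,
    seed = 41))
  mm <- ft_model_matrix(normalize_internal_standards(sim$table, "nomis"))
  xp <- mm$x[, sim$truth$discriminative$id]
  mc <- mccv_validate(xp, mm$y, n_iterations = 40,
                      panel_sizes = c(2, 5, 10, 14), seed = 3)
  expect_identical(mc$panel_size[which.max(mc$mean_auc)], 14)
})
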