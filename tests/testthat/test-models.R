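test_that("first PLS component equals the dominant eigenvector oracle", {
  x <- matrix(c(1, 2, 3, 4, 5, 6,
                6, 1, 5, 2, 4, 3,
                2, 2, 4, 4, 6, 6), 6, 3)
  colnames(x) <- c("a", "b", "c")
  y <- factor(c("control", "control", "control", "PD", "PD", "PD"))
  fit <- fit_pls(x, y, n_components = 1)

  # brute force: w1 is the dominant eigenvector of Xs' y y' Xs
  xs <- scale(x)
  yc <- as.numeric(y) - 1 - mean(as.numeric(y) - 1)
  Mx <- crossprod(xs, yc) %*% crossprod(yc, xs)
  eig <- eigen(Mx)$vectors[, 1]
  eig <- eig * sign(eig[which.max(abs(eig))]) *
    sign(fit$W[which.max(abs(eig)), 1])
  expect_equal(unname(fit$W[, 1]), unname(eig), tolerance = 1e-8)
})

test_that("PLS model invariants hold: unit weights, orthogonal scores", {
  toy <- toy_separable(n = 30, p = 8, seed = 2)
  fit <- fit_pls(toy$x, toy$y, n_components = 4)
  expect_equal(unname(colSums(fit$W^2)), rep(1, 4), tolerance = 1e-9)
  G <- crossprod(fit$T)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8 * max(diag(G)))
})

test_that("separable training data is classified perfectly", {
  set.seed(3)
  y <- factor(rep(c("control", "PD"), each = 20))
  x <- matrix(rnorm(40 * 10, sd = 0.5), 40, 10)
  colnames(x) <- sprintf("F%02d", 1:10)
  x[, 1] <- x[, 1] + ifelse(y == "PD", 6, -6)
  toy <- list(x = x, y = y)
  fit <- fit_pls(toy$x, toy$y, n_components = 1)
  s <- predict(fit, toy$x)
  expect_equal(roc_auc(toy$y, s), 1.0)
  expect_gte(mean((s >= 0.5) == (toy$y == "PD")), 0.95)
  # dominant feature carries the largest weight
  expect_identical(which.max(abs(fit$W[, 1])), 1L)
})

test_that("prediction equals the matrix-arithmetic oracle and fitted values", {
  set.seed(4)
  x <- matrix(rnorm(40), 20, 2)
  colnames(x) <- c("f1", "f2")
  y <- factor(rep(c("control", "PD"), 10))
  fit <- fit_pls(x, y, n_components = 1)
  # hand computation for A = 1
  xs <- scale(x)
  yc <- as.numeric(y == "PD") - 0.5   # PD is the positive class, coded 1
  w <- drop(crossprod(xs, yc))
  w <- w / sqrt(sum(w^2))
  t1 <- drop(xs %*% w)
  q <- sum(yc * t1) / sum(t1^2)
  manual <- pmin(pmax(t1 * q + 0.5, 0), 1)
  expect_equal(predict(fit, x), manual, tolerance = 1e-10)
  # predicting the training matrix reproduces the fitted scores
  expect_equal(predict(fit, x),
               pmin(pmax(drop(fit$T %*% fit$q) + fit$ybar, 0), 1),
               tolerance = 1e-10)
})

test_that("VIP scores satisfy the normalization identity and symmetry", {
  toy <- toy_separable(n = 24, p = 6, seed = 5)
  fit <- fit_pls(toy$x, toy$y, n_components = 3)
  v <- vip_scores(fit)
  expect_equal(sum(v$vip^2), 6, tolerance = 1e-9 * 6)
  expect_identical(v$id[1], "F01")
  expect_gt(v$vip[1], 1)

  # A = 1 with perfectly symmetric features: all VIP = 1
  set.seed(6)
  z <- rnorm(30)
  x <- cbind(z, z, z, z) + matrix(rnorm(120, 0, 1e-8), 30, 4)
  colnames(x) <- paste0("s", 1:4)
  y <- factor(ifelse(z > 0, "PD", "control"))
  f1 <- fit_pls(x, y, 1)
  expect_equal(vip_scores(f1)$vip, rep(1, 4), tolerance = 1e-3)

  # VIP agrees with a direct evaluation of the formula
  p <- nrow(fit$W)
  direct <- sqrt(p * drop(fit$W^2 %*% fit$ssy) / sum(fit$ssy))
  expect_equal(sort(v$vip, decreasing = TRUE),
               sort(direct, decreasing = TRUE), tolerance = 1e-12)
})

test_that("PLS is invariant to affine rescaling of input features", {
  toy <- toy_separable(n = 30, p = 6, seed = 7)
  f1 <- fit_pls(toy$x, toy$y, 2)
  x2 <- toy$x
  x2[, 3] <- x2[, 3] * 1e4 + 77
  f2 <- fit_pls(x2, toy$y, 2)
  expect_equal(f1$T, f2$T, tolerance = 1e-8)
  expect_equal(vip_scores(f1)$vip, vip_scores(f2)$vip, tolerance = 1e-8)
})

test_that("PLS matches an independent implementation (mixOmics)", {
  skip_if_not_installed("mixOmics")
  toy <- toy_separable(n = 40, p = 12, seed = 8)
  fit <- fit_pls(toy$x, toy$y, 2)
  ref <- mixOmics::pls(toy$x, as.numeric(toy$y == "PD"), ncomp = 2,
                       mode = "regression", scale = TRUE)
  for (a in 1:2) {
    cc <- abs(cor(fit$T[, a], ref$variates$X[, a]))
    expect_gt(cc, 0.999)
  }
})

test_that("degenerate PLS inputs error or drop as documented", {
  x <- matrix(rnorm(20), 10, 2)
  colnames(x) <- c("a", "b")
  expect_error(fit_pls(x, factor(rep("PD", 10)), 1), "two classes")
  x2 <- cbind(x, c = 5)
  expect_warning(fit_pls(x2, factor(rep(c("PD", "control"), 5)), 1),
                 "constant feature")
  expect_error(fit_pls(x, factor(rep(c("PD", "control"), 5)), 99),
               "n_components")
})

test_that("random forest: null labels give chance OOB, separable near zero", {
  set.seed(20)
  oob_null <- vapply(1:5, function(s) {
    x <- matrix(rnorm(100 * 10), 100, 10)
    colnames(x) <- paste0("f", 1:10)
    y <- factor(rep(c("control", "PD"), 50))
    fit_rf(x, y, n_trees = 300, seed = s)$oob_error
  }, numeric(1))
  expect_lt(abs(mean(oob_null) - 0.5), 0.07)

  toy <- toy_separable(n = 60, p = 10, seed = 21)
  fit <- fit_rf(toy$x, toy$y, n_trees = 300, seed = 1)
  expect_lte(fit$oob_error, 0.05)
  # deterministic for a fixed seed
  fit2 <- fit_rf(toy$x, toy$y, n_trees = 300, seed = 1)
  expect_identical(fit$oob_error, fit2$oob_error)
  # noise features have importance centered at zero
  imp <- fit$importance
  noise_imp <- imp$importance[imp$id != "F01"]
  expect_lt(abs(mean(noise_imp)), 2 * sd(noise_imp) / sqrt(length(noise_imp)) + 0.02)
})

test_that("mtry tuning returns the argmin OOB with ties toward smaller", {
  toy <- toy_separable(n = 40, p = 10, seed = 22)
  one <- tune_mtry(toy$x, toy$y, grid = 3, n_trees = 100, seed = 1)
  expect_identical(one$mtry, 3)

  tuned <- tune_mtry(toy$x, toy$y, grid = c(2, 3, 5), n_trees = 200,
                     seed = 4)
  expect_identical(unname(tuned$mtry),
                   c(2, 3, 5)[which.min(tuned$oob)])
  # default grid follows the sqrt(p) heuristic
  d <- tune_mtry(toy$x, toy$y, n_trees = 50, seed = 2)
  expect_setequal(as.integer(names(d$oob)), c(1, 3, 6))
})
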