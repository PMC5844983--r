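#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' `AUC = (concordant pairs + 0.5 * ties) / (n1 * n0)`: the probability that
#' a random positive sample scores above a random negative one, identical
#' to trapezoidal integration of the ROC curve.
#'
#' @param labels Two-level factor/vector; the second factor level (or 1, or
#'   `"PD"`) is the positive class.
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  pos <- .positive_mask(labels)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.positive_mask <- function(labels) {
  if (is.factor(labels)) {
    pos <- if ("PD" %in% levels(labels)) "PD" else levels(labels)[2]
    return(labels == pos)
  }
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels == max(labels))
  u <- sort(unique(as.character(labels)))
  if ("PD" %in% u) return(as.character(labels) == "PD")
  as.character(labels) == u[length(u)]
}

#' Confusion-table metrics at a score threshold
#'
#' Standard 2x2 ratios with the positive class (PD) predicted when
#' `score >= threshold`. Cells with a zero denominator yield `NA`
#' (undefined), never 0.
#'
#' @inheritParams roc_auc
#' @param threshold Score cutoff (default 0.5).
#' @return One-row tibble: `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `threshold`.
#' @export
confusion_metrics <- function(labels, scores, threshold = 0.5) {
  pos <- .positive_mask(labels)
  if (!any(pos) || all(pos)) stop("both classes must be present",
                                  call. = FALSE)
  pred <- scores >= threshold
  tp <- sum(pred & pos)
  fn <- sum(!pred & pos)
  tn <- sum(!pred & !pos)
  fp <- sum(pred & !pos)
  rat <- function(a, b) if (a + b == 0) NA_real_ else a / (a + b)
  tibble::tibble(
    sensitivity = rat(tp, fn),
    specificity = rat(tn, fp),
    ppv = rat(tp, fp),
    npv = rat(tn, fn),
    threshold = threshold
  )
}

# stratified fold assignment: within each class, shuffle and deal round-robin
make_folds <- function(y, n_folds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# stratified train/test split; returns train indices
stratified_split <- function(y, train_fraction, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  unlist(lapply(unique(y), function(cl) {
    idx <- which(y == cl)
    sample(idx, round(train_fraction * length(idx)))
  }), use.names = FALSE)
}

#' Repeated stratified k-fold cross-validated AUC
#'
#' For PLS, fits one maximal model per fold and scores the held fold at
#' every component count `1..max_components`; held-out scores are pooled
#' within each repeat, the AUC computed per repeat, and repeats averaged.
#' For RF, one forest per fold per `mtry` candidate.
#'
#' @param x,y Samples x features matrix and two-level labels.
#' @param model `"pls"` or `"rf"`.
#' @param max_components PLS: largest component count assessed.
#' @param mtry_grid RF: candidate `mtry` values (default grid of
#'   [tune_mtry()]).
#' @param n_folds,n_repeats Stratified folds and repeats (default 10 x 10).
#' @param n_trees RF trees per fit.
#' @param seed Integer seed; identical seeds give identical folds and AUCs.
#' @return Tibble (`hyperparameter`, `value`, `mean_cv_auc`) with attribute
#'   `"per_repeat"` (repeat-level AUCs).
#' @export
cross_validate <- function(x, y, model = c("pls", "rf"), max_components = 20,
                           mtry_grid = NULL, n_folds = 10, n_repeats = 10,
                           n_trees = 1000, seed = 1L) {
  model <- match.arg(model)
  y <- factor(y)
  if (min(table(y)) < n_folds) {
    stop("smallest class (", min(table(y)), ") < n_folds (", n_folds,
         "); use fewer folds", call. = FALSE)
  }
  n <- nrow(x)
  if (model == "pls") {
    amax <- min(max_components, n - ceiling(n / n_folds) - 1, ncol(x))
    vals <- seq_len(amax)
  } else {
    if (is.null(mtry_grid)) {
      r <- max(1, floor(sqrt(ncol(x))))
      mtry_grid <- unique(pmin(pmax(c(floor(r / 2), r, 2 * r), 1), ncol(x)))
    }
    vals <- sort(unique(mtry_grid))
  }
  per_repeat <- matrix(NA_real_, n_repeats, length(vals))
  set.seed(seed)
  for (r in seq_len(n_repeats)) {
    fold <- make_folds(y, n_folds)
    scores <- matrix(NA_real_, n, length(vals))
    for (f in seq_len(n_folds)) {
      te <- which(fold == f)
      tr <- setdiff(seq_len(n), te)
      if (model == "pls") {
        a_tr <- min(length(vals), length(tr) - 1)
        fit <- suppressWarnings(fit_pls(x[tr, , drop = FALSE], y[tr],
                                        n_components = a_tr))
        for (vi in seq_along(vals)) {
          a <- min(vals[vi], fit$n_components)
          scores[te, vi] <- predict(fit, x[te, , drop = FALSE],
                                    n_components = a)
        }
      } else {
        for (vi in seq_along(vals)) {
          fit <- fit_rf(x[tr, , drop = FALSE], y[tr], n_trees = n_trees,
                        mtry = vals[vi],
                        seed = seed * 1000L + r * 100L + f * 10L + vi)
          scores[te, vi] <- predict(fit, x[te, , drop = FALSE])
        }
      }
    }
    per_repeat[r, ] <- apply(scores, 2, function(s) roc_auc(y, s))
  }
  out <- tibble::tibble(
    hyperparameter = if (model == "pls") "n_components" else "mtry",
    value = vals,
    mean_cv_auc = colMeans(per_repeat)
  )
  attr(out, "per_repeat") <- per_repeat
  out
}

#' Select the PLS component count by cross-validated AUC
#'
#' `A = argmax` over `1..max_components` of the mean CV AUC; ties break
#' toward the smallest A.
#'
#' @inheritParams cross_validate
#' @return List: `n_components` (best A), `cv` (the [cross_validate()]
#'   table).
#' @export
select_components <- function(x, y, max_components = 20, n_folds = 10,
                              n_repeats = 10, seed = 1L) {
  cv <- cross_validate(x, y, model = "pls", max_components = max_components,
                       n_folds = n_folds, n_repeats = n_repeats, seed = seed)
  best <- cv$value[which.max(cv$mean_cv_auc)]  # which.max takes first = smallest
  list(n_components = best, cv = cv)
}

#' Repeated 70/30 split robustness assessment
#'
#' Repeats a stratified train/test split `n_repeats` times; per repeat the
#' model is tuned by cross-validation on the training 70% and its training
#' AUC recorded (the cross-validated AUC at the selected hyperparameter by
#' default — set `auc_type = "resubstitution"` for refit-on-train scores).
#' Reports per-repeat values, their mean and a 95% t-interval, and the
#' quantile position of the first ("initial") split within the
#' distribution.
#'
#' @inheritParams cross_validate
#' @param models Character subset of `c("pls", "rf")`.
#' @param n_repeats Number of random splits (200 in the emulated design).
#' @param train_fraction Training fraction (0.70).
#' @param cv_folds,cv_repeats Cross-validation design inside each training
#'   set.
#' @param auc_type `"cv"` or `"resubstitution"`.
#' @return Tibble (`repeat`, `model`, `auc`) with attribute `"summary"`
#'   (per-model mean, 95% CI, quantile of repeat 1).
#' @export
repeated_split_assessment <- function(x, y, n_repeats = 200,
                                      train_fraction = 0.70,
                                      models = c("pls", "rf"),
                                      max_components = 20, cv_folds = 10,
                                      cv_repeats = 10, n_trees = 1000,
                                      auc_type = c("cv", "resubstitution"),
                                      seed = 1L) {
  auc_type <- match.arg(auc_type)
  y <- factor(y)
  rows <- list()
  for (r in seq_len(n_repeats)) {
    tr <- stratified_split(y, train_fraction, seed = seed + r)
    xt <- x[tr, , drop = FALSE]
    yt <- y[tr]
    for (m in models) {
      if (m == "pls") {
        sel <- select_components(xt, yt, max_components = max_components,
                                 n_folds = cv_folds, n_repeats = cv_repeats,
                                 seed = seed + r)
        a <- if (auc_type == "cv") {
          max(sel$cv$mean_cv_auc)
        } else {
          fit <- suppressWarnings(fit_pls(xt, yt, sel$n_components))
          roc_auc(yt, predict(fit, xt))
        }
      } else {
        tuned <- tune_mtry(xt, yt, n_trees = n_trees, seed = seed + r)
        fit <- fit_rf(xt, yt, n_trees = n_trees, mtry = tuned$mtry,
                      seed = seed + r)
        a <- if (auc_type == "cv") {
          # OOB votes are the forest's internal cross-validation
          roc_auc(yt, unname(fit$forest$votes[, fit$levels[2]]))
        } else {
          roc_auc(yt, predict(fit, xt))
        }
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        repeat_id = r, model = m, auc = a)
    }
  }
  out <- dplyr::bind_rows(rows)
  summ <- out |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      mean_auc = mean(.data$auc),
      ci_lower = if (dplyr::n() > 1)
        mean(.data$auc) - stats::qt(0.975, dplyr::n() - 1) *
          stats::sd(.data$auc) / sqrt(dplyr::n()) else NA_real_,
      ci_upper = if (dplyr::n() > 1)
        mean(.data$auc) + stats::qt(0.975, dplyr::n() - 1) *
          stats::sd(.data$auc) / sqrt(dplyr::n()) else NA_real_,
      initial_split_quantile = mean(.data$auc <= .data$auc[1]),
      .groups = "drop")
  attr(out, "summary") <- summ
  out
}

#' Select a biomarker panel at the elbow of the VIP curve
#'
#' The top `top_n` VIP scores are min-max scaled to \[0, 1\] and the elbow
#' taken as the rank maximizing the perpendicular distance to the chord
#' from the first to the last point (the point where the slope flattens);
#' ties break toward the smaller rank. When no rank is farther than
#' `weak_threshold` from the chord (a near-linear decay), the selection is
#' flagged `weak_elbow` and the interior rank nearest the chord midpoint is
#' used.
#'
#' @param vip_ranking Tibble (`id`, `vip`) sorted by non-increasing VIP
#'   (as returned by [vip_scores()]), length >= 3.
#' @param top_n Curve length considered (default 100).
#' @param weak_threshold Scaled-distance floor below which the elbow is
#'   declared weak (default 0.05).
#' @return A `panel_selection`: tibble of the ranked curve (`rank`, `id`,
#'   `vip`, `vip_scaled`, `chord_distance`, `selected`) with attributes
#'   `elbow_rank`, `selected_ids`, `weak_elbow`.
#' @export
elbow_select <- function(vip_ranking, top_n = 100, weak_threshold = 0.05) {
  v <- vip_ranking$vip
  if (length(v) < 3) stop("ranking must have length >= 3", call. = FALSE)
  if (any(diff(v) > 1e-9)) {
    stop("VIP ranking must be non-increasing", call. = FALSE)
  }
  m <- min(top_n, length(v))
  v <- v[seq_len(m)]
  ids <- vip_ranking$id[seq_len(m)]
  rng <- max(v) - min(v)
  vs <- if (rng > 0) (v - min(v)) / rng else rep(0, m)
  # perpendicular distance from (r, vs_r) to the chord (1, vs_1)-(m, vs_m)
  x1 <- 1; y1 <- vs[1]; x2 <- m; y2 <- vs[m]
  r <- seq_len(m)
  dist <- abs((y2 - y1) * r - (x2 - x1) * vs + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  weak <- max(dist) < weak_threshold
  elbow <- if (weak) {
    max(2, min(m - 1, round((1 + m) / 2)))
  } else {
    which.max(dist)  # first maximum = smaller rank on ties
  }
  out <- tibble::tibble(
    rank = r, id = ids, vip = v, vip_scaled = vs, chord_distance = dist,
    selected = r <= elbow
  )
  class(out) <- c("panel_selection", class(out))
  attr(out, "elbow_rank") <- as.integer(elbow)
  attr(out, "selected_ids") <- ids[seq_len(elbow)]
  attr(out, "weak_elbow") <- weak
  out
}

#' Train-side panel selection: components, VIP ranking, elbow
#'
#' Runs the full training-portion selection procedure — component count by
#' repeated CV, PLS fit, VIP ranking, elbow cut — using ONLY the supplied
#' training samples. [final_holdout_test()] calls this on the training
#' split, so held-out labels cannot influence the panel by construction.
#'
#' @inheritParams cross_validate
#' @param top_n VIP curve length for the elbow.
#' @return List: `panel` (a `panel_selection`), `n_components`, `model`
#'   (the full-feature training `pls_model`).
#' @export
select_panel <- function(x, y, max_components = 20, n_folds = 10,
                         n_repeats = 10, top_n = 100, seed = 1L) {
  sel <- select_components(x, y, max_components = max_components,
                           n_folds = n_folds, n_repeats = n_repeats,
                           seed = seed)
  fit <- suppressWarnings(fit_pls(x, y, n_components = sel$n_components))
  panel <- elbow_select(vip_scores(fit), top_n = top_n)
  list(panel = panel, n_components = sel$n_components, model = fit)
}

#' Final held-out test of a selected biomarker panel
#'
#' Performs the single stratified 70/30 split, runs the entire selection
#' procedure ([select_panel()]) on the 70% only, refits PLS (and optionally
#' RF) on the training samples restricted to the selected panel, and scores
#' the untouched 30%.
#'
#' @inheritParams cross_validate
#' @param train_fraction Training fraction (default 0.70).
#' @param models Subset of `c("pls", "rf")`.
#' @param panel Optional pre-selected feature ids; when `NULL` the panel is
#'   selected on the training split.
#' @param cv_folds,cv_repeats CV design for component selection.
#' @param train_ids Optional integer row indices fixing the training split
#'   (default: a fresh stratified split from `seed`). With `train_ids`
#'   fixed, held-out labels and intensities provably cannot influence the
#'   panel: selection consumes the training rows only.
#' @return An `evaluation_result` tibble (`model`, `auc`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `threshold`) with attributes
#'   `panel_ids`, `n_components`, `train_ids` (row indices), `scores`.
#' @export
final_holdout_test <- function(x, y, train_fraction = 0.70,
                               models = c("pls", "rf"), panel = NULL,
                               max_components = 20, cv_folds = 10,
                               cv_repeats = 10, n_trees = 1000, seed = 1L,
                               train_ids = NULL) {
  y <- factor(y)
  tr <- if (is.null(train_ids)) {
    sort(stratified_split(y, train_fraction, seed = seed))
  } else {
    sort(as.integer(train_ids))
  }
  te <- setdiff(seq_len(nrow(x)), tr)
  xt <- x[tr, , drop = FALSE]
  yt <- y[tr]
  if (is.null(panel)) {
    sp <- select_panel(xt, yt, max_components = max_components,
                       n_folds = cv_folds, n_repeats = cv_repeats,
                       seed = seed)
    panel <- attr(sp$panel, "selected_ids")
  }
  missing <- setdiff(panel, colnames(x))
  if (length(missing) > 0) {
    stop("selected features absent from x: ", missing[1], call. = FALSE)
  }
  xp_tr <- xt[, panel, drop = FALSE]
  xp_te <- x[te, panel, drop = FALSE]
  rows <- list()
  scores <- list()
  for (m in models) {
    if (m == "pls") {
      amax <- min(max_components, length(panel), length(tr) - 1)
      sel <- select_components(xp_tr, yt, max_components = amax,
                               n_folds = cv_folds, n_repeats = cv_repeats,
                               seed = seed)
      fit <- suppressWarnings(fit_pls(xp_tr, yt, sel$n_components))
      s <- predict(fit, xp_te)
    } else {
      tuned <- tune_mtry(xp_tr, yt, n_trees = n_trees, seed = seed)
      fit <- fit_rf(xp_tr, yt, n_trees = n_trees, mtry = tuned$mtry,
                    seed = seed)
      s <- predict(fit, xp_te)
    }
    cm <- confusion_metrics(y[te], s)
    rows[[m]] <- dplyr::bind_cols(
      tibble::tibble(model = m, auc = roc_auc(y[te], s)), cm)
    scores[[m]] <- s
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("evaluation_result", class(out))
  attr(out, "panel_ids") <- panel
  attr(out, "train_ids") <- tr
  attr(out, "scores") <- scores
  out
}

#' Monte-Carlo cross-validation of panel-size sufficiency
#'
#' Per iteration: a balanced (equal class size) subsample is drawn, split
#' 2/3 train vs 1/3 validation; the VIP ranking is computed on the 2/3; for
#' each candidate panel size the top-ranked metabolites are used to fit a
#' PLS model on the 2/3, validated on the held 1/3. Mean accuracy and AUC
#' per panel size answer whether all selected metabolites are needed.
#'
#' @param x,y Samples x features matrix (typically already restricted to a
#'   selected panel) and labels.
#' @param n_iterations Monte-Carlo iterations (default 100).
#' @param panel_sizes Candidate sizes; default `c(2, 3, 5, 10, ...)` up to
#'   all features.
#' @param n_components PLS components for ranking and refits (capped by the
#'   panel size).
#' @param seed Integer seed.
#' @return Tibble (`panel_size`, `mean_auc`, `mean_accuracy`).
#' @export
mccv_validate <- function(x, y, n_iterations = 100, panel_sizes = NULL,
                          n_components = 2, seed = 1L) {
  y <- factor(y)
  p <- ncol(x)
  if (is.null(panel_sizes)) {
    panel_sizes <- unique(pmin(c(2, 3, 5, 10, 20, 50, 100, p), p))
    panel_sizes <- panel_sizes[panel_sizes >= 2]
  }
  if (min(table(y)) < 3) stop("need >= 3 samples per class", call. = FALSE)
  acc <- auc <- matrix(NA_real_, n_iterations, length(panel_sizes))
  set.seed(seed)
  for (it in seq_len(n_iterations)) {
    nmin <- min(table(y))
    bal <- unlist(lapply(levels(y), function(cl)
      sample(which(y == cl), nmin)), use.names = FALSE)
    yb <- y[bal]
    xb <- x[bal, , drop = FALSE]
    tr <- stratified_split(yb, 2 / 3)
    te <- setdiff(seq_along(yb), tr)
    rank_fit <- suppressWarnings(
      fit_pls(xb[tr, , drop = FALSE], yb[tr],
              n_components = min(n_components, length(tr) - 1, p)))
    ranking <- vip_scores(rank_fit)$id
    for (si in seq_along(panel_sizes)) {
      ids <- ranking[seq_len(min(panel_sizes[si], length(ranking)))]
      fit <- suppressWarnings(
        fit_pls(xb[tr, ids, drop = FALSE], yb[tr],
                n_components = min(n_components, length(ids),
                                   length(tr) - 1)))
      s <- predict(fit, xb[te, ids, drop = FALSE])
      auc[it, si] <- roc_auc(yb[te], s)
      acc[it, si] <- mean((s >= 0.5) == .positive_mask(yb[te]))
    }
  }
  tibble::tibble(
    panel_size = panel_sizes,
    mean_auc = colMeans(auc),
    mean_accuracy = colMeans(acc)
  )
}
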