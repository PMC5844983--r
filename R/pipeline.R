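#' Default pipeline configuration
#'
#' Every threshold of the workflow is a configuration default, never
#' hard-coded downstream: minimum detectable intensity 2000, tolerated
#' missingness 0.10, IS normalization nomis then ccmn, 70/30 split, 200
#' robustness repeats, 10x10-fold CV, at most 20 PLS components, 1000 RF
#' trees, top-100 VIP curve, 500 bootstraps, alpha 0.05.
#'
#' @param ... Overrides (named as in the returned list).
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_intensity = 2000, max_missing = 0.10,
    is_norm = c("nomis", "ccmn"), tic = TRUE,
    robpca_k = NULL, alpha = 0.05,
    train_fraction = 0.70, n_repeats = 200,
    cv_folds = 10, cv_repeats = 10,
    max_components = 20, n_trees = 1000,
    top_vip = 100, n_boot = 500,
    run_repeated_assessment = TRUE,
    run_mccv = TRUE, mccv_iterations = 100,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config key: ", unknown[1], call. = FALSE)
  }
  utils::modifyList(cfg, over)
}

# one top-level seed fans out to per-stage seeds: seed * 100 + stage index.
# Later stages' seeds do not perturb earlier stages (each stage re-seeds).
stage_seed <- function(seed, stage) {
  stages <- c(simulate = 1L, preprocess = 2L, screen = 3L, evaluate = 4L,
              stats = 5L, enrich = 6L)
  as.integer(seed) * 100L + stages[[stage]]
}

#' Run the full biomarker-discovery workflow
#'
#' Executes, in order: simulation (or reading of input TSVs), preprocessing
#' (minimum-intensity filter, blank filter, imputation, internal-standard
#' and TIC normalization), sample screening (robust-PCA outlier removal,
#' age/sex correction, LEDD screen), evaluation (optional 70/30 repeated
#' robustness assessment, single-split panel selection with held-out test,
#' optional Monte-Carlo CV), per-metabolite univariate statistics, and
#' (when a pathway database is supplied) enrichment. Each stage draws its
#' seed deterministically from the single top-level seed.
#'
#' @param input Either a `cohort_design` (the cohort is simulated), a
#'   `feature_table`, or a named list with paths `intensity`, `samples`,
#'   `features` to TSV inputs.
#' @param config A [pipeline_config()] list.
#' @param pathways Optional `pathway_db` for the enrichment stage.
#' @param out_dir Optional directory: stage TSVs and a markdown report are
#'   written there.
#' @return A `pipeline_result` list: `table` (screened feature table),
#'   `provenance`, `outliers`, `age_corrected`, `ledd_screen`,
#'   `assessment`, `holdout`, `panel`, `mccv`, `stats`, `enrichment`,
#'   `config`.
#' @export
run_pipeline <- function(input, config = pipeline_config(),
                         pathways = NULL, out_dir = NULL) {
  cfg <- utils::modifyList(pipeline_config(), config)
  seed <- cfg$seed
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  truth <- NULL
  ft <- run_stage("simulate", {
    if (inherits(input, "cohort_design")) {
      input$seed <- stage_seed(seed, "simulate")
      sim <- generate_cohort(input)
      truth <- sim$truth
      sim$table
    } else if (inherits(input, "feature_table")) {
      input
    } else if (is.list(input) &&
               all(c("intensity", "samples", "features") %in% names(input))) {
      read_feature_table(input$intensity, input$samples, input$features)
    } else {
      stop("input must be a cohort_design, feature_table, or path list ",
           "with keys intensity/samples/features")
    }
  })

  ft <- run_stage("preprocess", preprocess(
    ft, min_intensity = cfg$min_intensity, max_missing = cfg$max_missing,
    is_norm = cfg$is_norm, tic = cfg$tic))
  provenance <- attr(ft, "provenance")

  screen <- run_stage("screen", {
    rep <- robust_pca_distances(ft, k = cfg$robpca_k,
                                seed = stage_seed(seed, "screen"))
    ft2 <- drop_outliers(ft, rep)
    ft2 <- correct_age(ft2, alpha = cfg$alpha)
    age_corrected <- attr(ft2, "corrected")
    ft2 <- correct_gender(ft2)
    ledd <- tryCatch(screen_ledd(ft2), error = function(e) NULL)
    list(table = ft2, outliers = rep, age_corrected = age_corrected,
         ledd = ledd)
  })
  ft <- screen$table

  eval_res <- run_stage("evaluate", {
    mm <- ft_model_matrix(ft)
    eseed <- stage_seed(seed, "evaluate")
    assessment <- if (isTRUE(cfg$run_repeated_assessment)) {
      repeated_split_assessment(
        mm$x, mm$y, n_repeats = cfg$n_repeats,
        train_fraction = cfg$train_fraction,
        max_components = cfg$max_components, cv_folds = cfg$cv_folds,
        cv_repeats = cfg$cv_repeats, n_trees = cfg$n_trees, seed = eseed)
    } else NULL
    holdout <- final_holdout_test(
      mm$x, mm$y, train_fraction = cfg$train_fraction,
      max_components = cfg$max_components, cv_folds = cfg$cv_folds,
      cv_repeats = cfg$cv_repeats, n_trees = cfg$n_trees, seed = eseed)
    panel <- attr(holdout, "panel_ids")
    mccv <- if (isTRUE(cfg$run_mccv) && length(panel) >= 2) {
      mccv_validate(mm$x[, panel, drop = FALSE], mm$y,
                    n_iterations = cfg$mccv_iterations, seed = eseed)
    } else NULL
    list(assessment = assessment, holdout = holdout, panel = panel,
         mccv = mccv, x = mm$x, y = mm$y)
  })

  stats_tbl <- run_stage("stats", {
    tr_fit <- suppressWarnings(fit_pls(
      eval_res$x, eval_res$y,
      n_components = min(2, nrow(eval_res$x) - 1)))
    rf_fit <- fit_rf(eval_res$x, eval_res$y,
                     n_trees = min(cfg$n_trees, 500),
                     seed = stage_seed(seed, "stats"))
    table_report(ft, eval_res$panel,
                 pls_ranking = vip_scores(tr_fit)$id,
                 rf_ranking = rf_fit$importance$id,
                 n_boot = cfg$n_boot, seed = stage_seed(seed, "stats"))
  })

  enrich <- if (!is.null(pathways)) run_stage("enrich", {
    ann <- ft$features$annotation[!ft$features$is_internal_standard]
    universe <- unique(ann[ann != "unknown"])
    panel_ann <- ft$features$annotation[
      ft$features$id %in% eval_res$panel &
        ft$features$annotation != "unknown"]
    enrichment_report(unique(panel_ann), universe, pathways)
  }) else NULL

  res <- structure(list(
    table = ft, truth = truth, provenance = provenance,
    outliers = screen$outliers, age_corrected = screen$age_corrected,
    ledd_screen = screen$ledd, assessment = eval_res$assessment,
    holdout = eval_res$holdout, panel = eval_res$panel,
    mccv = eval_res$mccv, stats = stats_tbl, enrichment = enrich,
    config = cfg
  ), class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$provenance)
  cat("outliers removed: ", sum(x$outliers$flagged), "\n", sep = "")
  cat("panel size: ", length(x$panel), "\n", sep = "")
  cat("held-out test:\n")
  print(as.data.frame(x$holdout))
  invisible(x)
}

#' Write pipeline outputs as TSVs plus a markdown report
#'
#' @param res A `pipeline_result`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the report path.
#' @export
write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    if (!is.null(df)) readr::write_tsv(df, file.path(out_dir, name), na = "NA")
  }
  wt(res$provenance, "provenance.tsv")
  wt(res$outliers, "outliers.tsv")
  wt(res$age_corrected, "age_corrections.tsv")
  wt(res$ledd_screen, "ledd_screen.tsv")
  wt(res$assessment, "auc_distribution.tsv")
  wt(tibble::tibble(id = res$panel), "panel.tsv")
  wt(tibble::as_tibble(res$holdout), "final_test.tsv")
  wt(res$mccv, "mccv.tsv")
  wt(res$stats, "stats.tsv")
  wt(res$enrichment, "enrichment.tsv")
  rp <- file.path(out_dir, "report.md")
  lines <- c(
    "# Biomarker discovery run",
    "", "## Feature counts per stage", "",
    knit_tsv(res$provenance),
    "", paste0("Outliers removed: ", sum(res$outliers$flagged)),
    "", "## Held-out test metrics", "",
    knit_tsv(tibble::as_tibble(res$holdout)),
    "", paste0("Selected panel (", length(res$panel), "): ",
               paste(res$panel, collapse = ", ")),
    "", "## Panel univariate statistics", "",
    knit_tsv(res$stats)
  )
  if (!is.null(res$enrichment)) {
    lines <- c(lines, "", "## Pathway enrichment", "",
               knit_tsv(res$enrichment))
  }
  writeLines(lines, rp)
  invisible(rp)
}

# minimal markdown table rendering
knit_tsv <- function(df) {
  if (is.null(df) || nrow(df) == 0) return("(empty)")
  fmt <- function(v) {
    if (is.numeric(v)) formatC(v, digits = 4, format = "g") else
      as.character(v)
  }
  body <- apply(vapply(df, fmt, character(nrow(df))), 1,
                paste, collapse = " | ")
  c(paste(names(df), collapse = " | "),
    paste(rep("---", ncol(df)), collapse = " | "),
    body)
}

#' Compare two completed runs (e.g. plasma vs CSF)
#'
#' Computes Venn counts of detected features and of selected panels over the
#' shared annotation space, and the per-shared-metabolite sign concordance
#' of log2 fold differences (a metabolite changing in opposite directions
#' in the two matrices is flagged discordant).
#'
#' @param run_a,run_b `pipeline_result` objects sharing feature annotations.
#' @return List: `features` (Venn counts `only_a`, `shared`, `only_b`),
#'   `panels` (same for selected panels, by annotation), `concordance`
#'   (tibble of shared panel metabolites with both log2 FDs and a
#'   `discordant` flag), `concordance_rate`.
#' @export
compare_matrices <- function(run_a, run_b) {
  ann <- function(r) {
    a <- r$table$features$annotation[!r$table$features$is_internal_standard]
    unique(a[a != "unknown"])
  }
  a <- ann(run_a)
  b <- ann(run_b)
  shared <- intersect(a, b)
  if (length(shared) == 0) {
    warning("no shared annotations between runs")
  }
  pan <- function(r) {
    fa <- r$table$features
    unique(fa$annotation[fa$id %in% r$panel & fa$annotation != "unknown"])
  }
  pa <- pan(run_a)
  pb <- pan(run_b)
  shared_panel <- intersect(pa, pb)
  conc <- if (length(shared_panel) > 0) {
    fd <- function(r, annos) {
      s <- r$stats
      fa <- r$table$features
      s$annotation <- fa$annotation[match(s$id, fa$id)]
      s[match(annos, s$annotation), "log2_fd", drop = TRUE]
    }
    tibble::tibble(
      annotation = shared_panel,
      log2_fd_a = fd(run_a, shared_panel),
      log2_fd_b = fd(run_b, shared_panel)
    ) |>
      dplyr::mutate(discordant = sign(.data$log2_fd_a) !=
                      sign(.data$log2_fd_b))
  } else {
    tibble::tibble(annotation = character(0), log2_fd_a = numeric(0),
                   log2_fd_b = numeric(0), discordant = logical(0))
  }
  list(
    features = c(only_a = length(setdiff(a, b)), shared = length(shared),
                 only_b = length(setdiff(b, a))),
    panels = c(only_a = length(setdiff(pa, pb)),
               shared = length(shared_panel),
               only_b = length(setdiff(pb, pa))),
    concordance = conc,
    concordance_rate = if (nrow(conc) > 0) mean(!conc$discordant) else
      NA_real_
  )
}
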