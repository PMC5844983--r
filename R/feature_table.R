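#' Construct a feature table
#'
#' A `feature_table` bundles a samples x features matrix of semi-quantitative
#' LC-MS peak intensities (raw peak heights, arbitrary units) with per-sample
#' and per-feature metadata. Missing peaks are encoded as `NA` and are a
#' distinct state from a measured zero. This is the object every pipeline
#' stage transforms.
#'
#' @param intensities Numeric matrix, samples in rows, features in columns.
#'   Row names are sample ids, column names feature ids. `NA` marks a missing
#'   peak; all present values must be >= 0.
#' @param samples Data frame of sample metadata with columns `id`, `role`
#'   (`"biological"`, `"blank"`, `"qc"`), `group` (`"PD"`, `"control"`,
#'   `"none"`), `sex` (`"M"`, `"F"`, `"none"`), `age` (years, may be `NA`),
#'   `ledd` (levodopa-equivalent daily dose, mg/day, may be `NA`) and
#'   `matrix` (`"plasma"` or `"csf"`).
#' @param features Data frame of feature metadata with columns `id`, `mz`
#'   (Da), `rt` (minutes), `annotation` (may be `"unknown"`),
#'   `is_internal_standard` (logical) and `validation_level`
#'   (`"1"`, `"2"`, `"3"` or `"unknown"`).
#'
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(intensities, samples, features) {
  samples <- tibble::as_tibble(samples)
  features <- tibble::as_tibble(features)
  ft <- structure(
    list(
      intensities = intensities,
      samples = samples,
      features = features
    ),
    class = "feature_table"
  )
  validate_feature_table(ft)
}

#' Validate a feature table's structural invariants
#'
#' Checks dimension/metadata agreement, id uniqueness, metadata enum levels,
#' non-negativity of present intensities, and role/group consistency
#' (biological samples must be PD or control; blanks and QCs must carry
#' group `"none"`).
#'
#' @param ft A `feature_table`.
#' @return `ft`, invisibly unchanged, if valid; otherwise an error naming the
#'   offending id or cell.
#' @export
validate_feature_table <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  x <- ft$intensities
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("intensities must be a numeric matrix", call. = FALSE)
  }
  need_s <- c("id", "role", "group", "sex", "age", "ledd", "matrix")
  need_f <- c("id", "mz", "rt", "annotation", "is_internal_standard",
              "validation_level")
  miss_s <- setdiff(need_s, names(ft$samples))
  miss_f <- setdiff(need_f, names(ft$features))
  if (length(miss_s) > 0) {
    stop("sample metadata missing columns: ", paste(miss_s, collapse = ", "),
         call. = FALSE)
  }
  if (length(miss_f) > 0) {
    stop("feature metadata missing columns: ", paste(miss_f, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x) != nrow(ft$samples)) {
    stop("intensity rows (", nrow(x), ") != sample metadata rows (",
         nrow(ft$samples), ")", call. = FALSE)
  }
  if (ncol(x) != nrow(ft$features)) {
    stop("intensity columns (", ncol(x), ") != feature metadata rows (",
         nrow(ft$features), ")", call. = FALSE)
  }
  if (anyDuplicated(ft$samples$id)) {
    stop("duplicate sample id: ",
         ft$samples$id[duplicated(ft$samples$id)][1], call. = FALSE)
  }
  if (anyDuplicated(ft$features$id)) {
    stop("duplicate feature id: ",
         ft$features$id[duplicated(ft$features$id)][1], call. = FALSE)
  }
  rn <- if (nrow(x) > 0) rownames(x) else character(0)
  cn <- if (ncol(x) > 0) colnames(x) else character(0)
  if (!identical(rn, as.character(ft$samples$id)) ||
      !identical(cn, as.character(ft$features$id))) {
    stop("intensity dimnames must equal sample/feature ids in order",
         call. = FALSE)
  }
  neg <- which(!is.na(x) & x < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop("negative intensity at sample '", rownames(x)[neg[1, 1]],
         "', feature '", colnames(x)[neg[1, 2]], "'", call. = FALSE)
  }
  if (!all(ft$samples$role %in% c("biological", "blank", "qc"))) {
    stop("sample role must be biological, blank or qc", call. = FALSE)
  }
  if (!all(ft$samples$group %in% c("PD", "control", "none"))) {
    stop("sample group must be PD, control or none", call. = FALSE)
  }
  bad <- ft$samples$role == "biological" & !ft$samples$group %in% c("PD", "control")
  if (any(bad)) {
    stop("biological sample without PD/control group: ",
         ft$samples$id[bad][1], call. = FALSE)
  }
  bad <- ft$samples$role %in% c("blank", "qc") & ft$samples$group != "none"
  if (any(bad)) {
    stop("blank/qc sample must have group 'none': ", ft$samples$id[bad][1],
         call. = FALSE)
  }
  is_lvl <- ft$features$is_internal_standard &
    as.character(ft$features$validation_level) != "1"
  if (any(is_lvl)) {
    stop("internal standard without validation level 1: ",
         ft$features$id[is_lvl][1], call. = FALSE)
  }
  invisible(ft)
}

#' @export
print.feature_table <- function(x, ...) {
  bio <- sum(x$samples$role == "biological")
  cat("<feature_table> ", nrow(x$intensities), " samples (", bio,
      " biological, ", sum(x$samples$role == "blank"), " blank, ",
      sum(x$samples$role == "qc"), " QC) x ", ncol(x$intensities),
      " features (", sum(x$features$is_internal_standard),
      " internal standards)\n", sep = "")
  cat("  missing cells: ", sum(is.na(x$intensities)), " (",
      sprintf("%.1f%%", 100 * mean(is.na(x$intensities))), ")\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

# row indices of biological samples
bio_idx <- function(ft) which(ft$samples$role == "biological")

# column indices of internal-standard features
is_idx <- function(ft) which(ft$features$is_internal_standard)

#' Subset a feature table
#'
#' @param ft A `feature_table`.
#' @param sample_ids,feature_ids Character vectors of ids to keep (default:
#'   keep all). Order of the table is preserved.
#' @return A `feature_table`.
#' @export
ft_subset <- function(ft, sample_ids = NULL, feature_ids = NULL) {
  si <- if (is.null(sample_ids)) seq_len(nrow(ft$intensities)) else {
    unknown <- setdiff(sample_ids, ft$samples$id)
    if (length(unknown) > 0) {
      stop("unknown sample id: ", unknown[1], call. = FALSE)
    }
    which(ft$samples$id %in% sample_ids)
  }
  fi <- if (is.null(feature_ids)) seq_len(ncol(ft$intensities)) else {
    unknown <- setdiff(feature_ids, ft$features$id)
    if (length(unknown) > 0) {
      stop("unknown feature id: ", unknown[1], call. = FALSE)
    }
    which(ft$features$id %in% feature_ids)
  }
  feature_table(
    ft$intensities[si, fi, drop = FALSE],
    ft$samples[si, , drop = FALSE],
    ft$features[fi, , drop = FALSE]
  )
}

#' Extract the biological-sample intensity matrix and class labels
#'
#' Convenience accessor used by the modelling stages: returns the intensity
#' matrix restricted to biological samples (optionally natural-log
#' transformed, excluding internal-standard features) together with the
#' PD/control labels.
#'
#' @param ft A `feature_table`.
#' @param log Natural-log transform intensities (`log(x)`, zeros clamped to
#'   half the smallest positive value of the feature)? Default `TRUE`.
#' @param drop_is Drop internal-standard features? Default `TRUE`.
#' @return List with `x` (matrix), `y` (factor control/PD), `sample_ids`.
#' @export
ft_model_matrix <- function(ft, log = TRUE, drop_is = TRUE) {
  bi <- bio_idx(ft)
  fi <- if (drop_is) setdiff(seq_len(ncol(ft$intensities)), is_idx(ft)) else
    seq_len(ncol(ft$intensities))
  x <- ft$intensities[bi, fi, drop = FALSE]
  if (anyNA(x)) {
    stop("model matrix contains missing cells; impute first", call. = FALSE)
  }
  if (log) x <- safe_log(x)
  y <- factor(ft$samples$group[bi], levels = c("control", "PD"))
  list(x = x, y = y, sample_ids = ft$samples$id[bi])
}

# natural log with per-feature half-minimum clamp for zeros
safe_log <- function(x) {
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    z <- which(!is.na(v) & v <= 0)
    if (length(z) > 0) {
      pos <- v[!is.na(v) & v > 0]
      repl <- if (length(pos) > 0) min(pos) / 2 else 1
      x[z, j] <- repl
    }
  }
  log(x)
}

#' Read a feature table from three TSV files
#'
#' The intensity file has feature ids in the header row and sample ids in the
#' first column (samples in rows); `NA` denotes a missing peak. Sample and
#' feature metadata files carry the columns documented in [feature_table()].
#'
#' @param intensity_path,sample_meta_path,feature_meta_path Paths to TSVs.
#' @param transpose Set `TRUE` if the intensity file has features in rows.
#' @return A validated `feature_table`.
#' @export
read_feature_table <- function(intensity_path, sample_meta_path,
                               feature_meta_path, transpose = FALSE) {
  for (p in c(intensity_path, sample_meta_path, feature_meta_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  ints <- utils::read.delim(intensity_path, check.names = FALSE,
                            row.names = 1, na.strings = "NA")
  x <- as.matrix(ints)
  storage.mode(x) <- "double"
  if (transpose) x <- t(x)
  samples <- readr::read_tsv(sample_meta_path, show_col_types = FALSE,
                             col_types = readr::cols(
                               id = "c", role = "c", group = "c", sex = "c",
                               age = "d", ledd = "d", matrix = "c"))
  features <- readr::read_tsv(feature_meta_path, show_col_types = FALSE,
                              col_types = readr::cols(
                                id = "c", mz = "d", rt = "d",
                                annotation = "c",
                                is_internal_standard = "l",
                                validation_level = "c"))
  if (!setequal(rownames(x), samples$id)) {
    off <- c(setdiff(rownames(x), samples$id), setdiff(samples$id, rownames(x)))
    stop("sample ids disagree between intensity file and metadata: ",
         off[1], call. = FALSE)
  }
  if (!setequal(colnames(x), features$id)) {
    off <- c(setdiff(colnames(x), features$id),
             setdiff(features$id, colnames(x)))
    stop("feature ids disagree between intensity file and metadata: ",
         off[1], call. = FALSE)
  }
  x <- x[samples$id, features$id, drop = FALSE]
  feature_table(x, samples, features)
}

#' Write a feature table to three TSV files
#'
#' Inverse of [read_feature_table()]: writes `intensities.tsv` (samples in
#' rows, `NA` for missing), `samples.tsv` and `features.tsv` into `out_dir`.
#'
#' @param ft A `feature_table`.
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_feature_table <- function(ft, out_dir) {
  validate_feature_table(ft)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    intensities = file.path(out_dir, "intensities.tsv"),
    samples = file.path(out_dir, "samples.tsv"),
    features = file.path(out_dir, "features.tsv")
  )
  df <- data.frame(id = rownames(ft$intensities), ft$intensities,
                   check.names = FALSE)
  utils::write.table(df, paths[["intensities"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  readr::write_tsv(ft$samples, paths[["samples"]], na = "NA")
  readr::write_tsv(ft$features, paths[["features"]], na = "NA")
  invisible(paths)
}

#' Read pathway definitions from membership and edge TSVs
#'
#' @param membership_path TSV with columns `pathway_id`, `pathway_name`
#'   (optional) and `metabolite_id`.
#' @param edges_path TSV with columns `pathway_id`, `id_a`, `id_b`
#'   (undirected edges between member metabolites). May contain zero rows.
#' @return A `pathway_db`: named list of pathways, each with `name`,
#'   `members` (character) and `edges` (2-column character matrix).
#' @export
read_pathways <- function(membership_path, edges_path) {
  mem <- readr::read_tsv(membership_path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  edg <- readr::read_tsv(edges_path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (!all(c("pathway_id", "metabolite_id") %in% names(mem))) {
    stop("membership file needs pathway_id and metabolite_id columns",
         call. = FALSE)
  }
  db <- list()
  for (pid in unique(mem$pathway_id)) {
    rows <- mem[mem$pathway_id == pid, ]
    members <- unique(rows$metabolite_id)
    if (length(members) == 0) {
      stop("pathway with empty membership: ", pid, call. = FALSE)
    }
    nm <- if ("pathway_name" %in% names(rows)) rows$pathway_name[1] else pid
    e <- edg[edg$pathway_id == pid, , drop = FALSE]
    edges <- if (nrow(e) > 0) {
      bad <- c(setdiff(e$id_a, members), setdiff(e$id_b, members))
      if (length(bad) > 0) {
        stop("edge endpoint not a member of pathway '", pid, "': ", bad[1],
             call. = FALSE)
      }
      cbind(e$id_a, e$id_b)
    } else {
      matrix(character(0), ncol = 2)
    }
    db[[pid]] <- list(name = nm, members = members, edges = edges)
  }
  extra <- setdiff(unique(edg$pathway_id), names(db))
  if (length(extra) > 0) {
    stop("edges reference unknown pathway: ", extra[1], call. = FALSE)
  }
  structure(db, class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat("<pathway_db> ", length(x), " pathways\n", sep = "")
  for (pid in names(x)) {
    cat("  ", pid, ": ", length(x[[pid]]$members), " members, ",
        nrow(x[[pid]]$edges), " edges\n", sep = "")
  }
  invisible(x)
}
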