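# Fixtures are built in code; nothing is read from disk except the
# published-table TSV and the toy pathway definitions under extdata.

# bare feature table around an intensity matrix; all-biological by default
mk_ft <- function(x, role = NULL, group = NULL, sex = NULL, age = NULL,
                  ledd = NULL, is_flag = NULL) {
  n <- nrow(x)
  p <- ncol(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("S%03d", seq_len(n))
  if (is.null(colnames(x))) colnames(x) <- sprintf("F%03d", seq_len(p))
  if (is.null(role)) role <- rep("biological", n)
  if (is.null(group)) {
    group <- ifelse(role == "biological",
                    rep(c("PD", "control"), length.out = n), "none")
  }
  if (is.null(sex)) sex <- ifelse(role == "biological",
                                  rep(c("M", "F"), length.out = n), "none")
  if (is.null(age)) age <- ifelse(role == "biological", 60, NA_real_)
  if (is.null(ledd)) ledd <- ifelse(group == "PD", 200, NA_real_)
  if (is.null(is_flag)) is_flag <- rep(FALSE, p)
  feature_table(
    x,
    tibble::tibble(id = rownames(x), role = role, group = group, sex = sex,
                   age = age, ledd = ledd, matrix = "plasma"),
    tibble::tibble(id = colnames(x), mz = 100 + seq_len(p), rt = 1,
                   annotation = paste0("met_", colnames(x)),
                   is_internal_standard = is_flag,
                   validation_level = ifelse(is_flag, "1", "2"))
  )
}

# small generated cohort shared by several tests
small_cohort <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_case = 30, n_control = 28, n_features = 60, n_discriminative = 8,
         n_contaminant_features = 3, n_age_affected = 5, n_sex_affected = 5,
         seed = seed),
    list(...))
  generate_cohort(do.call(cohort_design, args))
}

# separable toy classification problem
toy_separable <- function(n = 40, p = 10, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("control", "PD"), each = n / 2))
  x <- matrix(rnorm(n * p), n, p)
  x[, 1] <- x[, 1] + ifelse(y == "PD", 4, -4)
  colnames(x) <- sprintf("F%02d", seq_len(p))
  list(x = x, y = y)
}

extdata <- function(...) system.file("extdata", ..., package = "metabopanel")
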