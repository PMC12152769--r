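#' Construct a feature table
#'
#' The universal input container: one row per subject, positive feature
#' columns, an age/sex covariate frame, and a batch (site/study) label.
#'
#' @param features numeric matrix, subjects x features (column names required).
#' @param covariates data frame with `age` and `sex` (0 = female, 1 = male).
#' @param batch factor (or coercible) of batch labels, one per subject.
#' @param subject_id character vector of unique subject ids.
#' @param category optional named character vector mapping every feature to
#'   one of `"global"`, `"volume"`, `"thickness"`, `"surface_area"`,
#'   `"other"`; defaults to `"other"`.
#' @param provenance optional list recording source path / configuration.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(features, covariates, batch,
                          subject_id = NULL, category = NULL, provenance = list()) {
  features <- as.matrix(features)
  if (is.null(colnames(features))) stop("feature columns must be named")
  storage.mode(features) <- "double"
  validate_covariates(covariates)
  n <- nrow(features)
  if (nrow(covariates) != n) stop("covariates and features disagree on subject count")
  batch <- droplevels(as.factor(batch))
  if (length(batch) != n) stop("batch labels and features disagree on subject count")
  if (any(table(batch) < 1)) stop("every batch label must have at least one subject")
  if (is.null(subject_id)) subject_id <- sprintf("sub-%05d", seq_len(n))
  subject_id <- as.character(subject_id)
  if (anyDuplicated(subject_id)) {
    stop("duplicate subject ids: ",
         paste(unique(subject_id[duplicated(subject_id)]), collapse = ", "))
  }
  valid_cat <- c("global", "volume", "thickness", "surface_area", "other")
  if (is.null(category)) {
    category <- stats::setNames(rep("other", ncol(features)), colnames(features))
  }
  if (!all(colnames(features) %in% names(category))) {
    stop("category map must cover all feature columns")
  }
  category <- category[colnames(features)]
  if (!all(category %in% valid_cat)) {
    stop("feature categories must be one of: ", paste(valid_cat, collapse = ", "))
  }
  structure(list(features = features, covariates = covariates, batch = batch,
                 subject_id = subject_id, category = category,
                 provenance = provenance),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d subjects x %d features, %d batch(es)\n",
              nrow(x$features), ncol(x$features), nlevels(x$batch)))
  cat("  categories:", paste(sprintf("%s=%d", names(table(x$category)),
                                     table(x$category)), collapse = ", "), "\n")
  cat(sprintf("  age range: %.2f-%.2f; %.1f%% female\n",
              min(x$covariates$age), max(x$covariates$age),
              100 * mean(x$covariates$sex == 0)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$features)

#' Read a feature table from CSV/TSV
#'
#' Rows with missing values in any declared column are dropped (listwise
#' deletion) with a message reporting the count.
#'
#' @param path file path; delimiter inferred from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma).
#' @param feature_cols character vector of feature column names.
#' @param age_col,sex_col,batch_col,id_col column role declarations.
#' @param category optional named character vector (see [feature_table()]).
#' @param age_unit `"years"` or `"days"` (recorded in provenance; values are
#'   kept in the declared unit).
#' @return a `feature_table`.
#' @export
read_feature_table <- function(path, feature_cols, age_col = "age", sex_col = "sex",
                               batch_col = "batch", id_col = NULL, category = NULL,
                               age_unit = c("years", "days")) {
  age_unit <- match.arg(age_unit)
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  declared <- c(feature_cols, age_col, sex_col, batch_col, id_col)
  missing_cols <- setdiff(declared, names(df))
  if (length(missing_cols)) {
    stop("missing declared column(s): ", paste(missing_cols, collapse = ", "),
         "; available: ", paste(names(df), collapse = ", "))
  }
  for (fc in feature_cols) {
    bad <- which(!is.na(df[[fc]]) & is.na(suppressWarnings(as.numeric(df[[fc]]))))
    if (length(bad)) {
      stop(sprintf("non-numeric value in feature column '%s', row %d", fc, bad[1]))
    }
    df[[fc]] <- as.numeric(df[[fc]])
  }
  keep <- stats::complete.cases(df[, declared, drop = FALSE])
  if (any(!keep)) {
    message(sprintf("listwise deletion: dropped %d row(s) with missing values", sum(!keep)))
    df <- df[keep, , drop = FALSE]
  }
  feature_table(
    features = as.matrix(df[, feature_cols, drop = FALSE]),
    covariates = data.frame(age = df[[age_col]], sex = df[[sex_col]]),
    batch = df[[batch_col]],
    subject_id = if (is.null(id_col)) NULL else df[[id_col]],
    category = category,
    provenance = list(path = path, age_unit = age_unit)
  )
}

#' Write a feature table to CSV/TSV
#'
#' @param x a `feature_table`.
#' @param path destination; `.tsv` writes tab-separated.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- data.frame(subject_id = x$subject_id, x$covariates,
                   batch = as.character(x$batch), check.names = FALSE)
  df <- cbind(df, as.data.frame(x$features, check.names = FALSE))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' One-sided MAD quality-control filter
#'
#' Within each group, excludes values greater than
#' `median + k * MAD` (unscaled MAD, upper cut only) -- the adaptive
#' surface-quality threshold used for Euler-index style QC.
#'
#' @param values numeric vector (e.g., per-subject quality indices).
#' @param group group labels (e.g., primary study); each group needs >= 3.
#' @param k multiplier on the MAD (default 2).
#' @return logical keep mask aligned with `values`.
#' @export
mad_qc_filter <- function(values, group = rep(1L, length(values)), k = 2) {
  group <- as.factor(group)
  if (any(table(group) < 3)) stop("each QC group needs at least 3 members")
  keep <- rep(TRUE, length(values))
  for (lv in levels(group)) {
    idx <- which(group == lv)
    med <- stats::median(values[idx])
    mad0 <- stats::median(abs(values[idx] - med))
    if (mad0 == 0 && any(values[idx] > med)) {
      warning("group '", lv, "' has zero MAD; excluding all values above the median")
    }
    keep[idx] <- values[idx] <= med + k * mad0
  }
  keep
}

#' Two-sided MAD outlier guard for feature values
#'
#' Flags biologically implausible values farther than `k` (unscaled) MADs
#' from each feature's overall median.
#'
#' @param features numeric matrix or vector.
#' @param k multiplier on the MAD (default 20).
#' @return logical keep mask: for a matrix, one entry per row (a row is
#'   dropped if any feature is implausible); for a vector, per element.
#' @export
outlier_guard <- function(features, k = 20) {
  f <- as.matrix(features)
  ok <- matrix(TRUE, nrow(f), ncol(f))
  for (j in seq_len(ncol(f))) {
    med <- stats::median(f[, j])
    mad0 <- stats::median(abs(f[, j] - med))
    if (is.infinite(k) || mad0 == 0) next
    ok[, j] <- abs(f[, j] - med) <= k * mad0
  }
  if (is.matrix(features)) rowSums(!ok) == 0 else drop(ok)
}
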