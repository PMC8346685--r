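#' ROI cohorts
#'
#' A cohort couples per-subject metadata (id, group, site, age, sex) with an
#' M x N feature matrix whose columns follow a [roi_schema] exactly.
#'
#' @name roi_cohort
NULL

GROUP_LEVELS <- c("HC", "TLE-HS-L", "TLE-HS-R", "TLE-NS-L", "TLE-NS-R")

#' Construct an ROI cohort
#'
#' @param subjects Data frame with columns `subject_id`, `group`, `site`,
#'   `age`, `sex` (0/1).
#' @param X Numeric matrix, one row per subject, columns in schema order.
#' @param schema A [roi_schema].
#' @return An object of class `roi_cohort`.
#' @export
roi_cohort <- function(subjects, X, schema) {
  req <- c("subject_id", "group", "site", "age", "sex")
  if (!all(req %in% names(subjects)))
    stopf("subjects must contain columns: %s", paste(req, collapse = ", "))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(subjects) != nrow(X))
    stopf("subjects (%d rows) and X (%d rows) disagree",
          nrow(subjects), nrow(X))
  if (ncol(X) != nrow(schema))
    stopf("X has %d columns but schema defines %d features",
          ncol(X), nrow(schema))
  if (!is.null(colnames(X)) && !identical(colnames(X), schema$name))
    stopf("X column names do not follow schema order")
  colnames(X) <- schema$name
  if (any(!nzchar(as.character(subjects$site))) ||
      any(is.na(subjects$site)))
    stopf("every site label must be non-empty")
  subjects$subject_id <- as.character(subjects$subject_id)
  subjects$group <- as.character(subjects$group)
  subjects$site <- as.character(subjects$site)
  rownames(subjects) <- NULL
  structure(list(subjects = subjects, X = X, schema = schema),
            class = "roi_cohort")
}

#' @export
print.roi_cohort <- function(x, ...) {
  cat(sprintf("<roi_cohort> %d subjects x %d features (%s)\n",
              nrow(x$X), ncol(x$X), attr(x$schema, "modality")))
  cat("  groups:", paste(sprintf("%s=%d", names(table(x$subjects$group)),
                                 table(x$subjects$group)), collapse = " "),
      "\n  sites: ", length(unique(x$subjects$site)), "\n")
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort A `roi_cohort`.
#' @export
n_subjects <- function(cohort) nrow(cohort$X)

subset_cohort <- function(cohort, idx) {
  roi_cohort(cohort$subjects[idx, , drop = FALSE],
             cohort$X[idx, , drop = FALSE], cohort$schema)
}

#' Read an ROI table into a cohort
#'
#' Reads a comma- or tab-delimited table (dialect auto-detected) whose
#' header names `subject_id`, `group`, `site`, `age`, `sex` and every schema
#' feature. Feature columns may appear in any order; they are realigned to
#' schema order. Empty cells, `NA` and `NaN` are treated as missing.
#'
#' @param path Path to the delimited file.
#' @param schema A [roi_schema] the table must satisfy.
#' @param extra_columns `"ignore"` (default) drops unrecognized columns,
#'   `"error"` rejects them.
#' @return A [roi_cohort] (may still contain missing values; see
#'   [filter_complete_cases()]).
#' @export
load_cohort <- function(path, schema, extra_columns = c("ignore", "error")) {
  extra_columns <- match.arg(extra_columns)
  dt <- data.table::fread(path, na.strings = c("", "NA", "NaN"),
                          colClasses = list(character = "subject_id"),
                          data.table = FALSE, showProgress = FALSE)
  meta_cols <- c("subject_id", "group", "site", "age", "sex")
  missing_meta <- setdiff(meta_cols, names(dt))
  if (length(missing_meta))
    stopf("schema mismatch: missing required column(s): %s",
          paste(missing_meta, collapse = ", "))
  missing_feat <- setdiff(schema$name, names(dt))
  if (length(missing_feat))
    stopf("schema mismatch: missing feature column(s): %s",
          paste(head(missing_feat, 5), collapse = ", "))
  extra <- setdiff(names(dt), c(meta_cols, schema$name))
  if (length(extra) && extra_columns == "error")
    stopf("unknown extra column(s): %s", paste(extra, collapse = ", "))
  for (cn in schema$name) {
    if (!is.numeric(dt[[cn]])) {
      parsed <- suppressWarnings(as.numeric(dt[[cn]]))
      bad <- which(is.na(parsed) & !is.na(dt[[cn]]))
      if (length(bad))
        stopf("unparseable numeric cell at row %d, column '%s'",
              bad[1], cn)
      dt[[cn]] <- parsed
    }
  }
  X <- as.matrix(dt[, schema$name, drop = FALSE])
  roi_cohort(dt[, meta_cols], X, schema)
}

#' Write a cohort back to a delimited table
#'
#' @param cohort A [roi_cohort].
#' @param path Output path; `.tsv` extension selects tab separation,
#'   anything else comma.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  out <- cbind(cohort$subjects, as.data.frame(cohort$X))
  data.table::fwrite(out, path, sep = sep)
  invisible(path)
}

#' Drop subjects with any missing feature value
#'
#' Keeps only complete rows over the schema features; metadata columns are
#' required to be complete as well. Row order is preserved.
#'
#' @param cohort A [roi_cohort].
#' @param verbose Log the number of removed rows.
#' @return The filtered [roi_cohort].
#' @export
filter_complete_cases <- function(cohort, verbose = FALSE) {
  keep <- stats::complete.cases(cohort$X) &
    stats::complete.cases(cohort$subjects[c("group", "site", "age", "sex")])
  if (!any(keep))
    stopf("empty cohort: all %d rows contain missing values", length(keep))
  if (verbose)
    message(sprintf("filter_complete_cases: removed %d of %d rows",
                    sum(!keep), length(keep)))
  subset_cohort(cohort, which(keep))
}

#' Select a binary classification task from a cohort
#'
#' Keeps only subjects whose group is in `positive` (label 1) or `negative`
#' (label 0). Pooled sets are allowed, e.g. `positive = c("TLE-HS-L",
#' "TLE-HS-R")` against `negative = "HC"`, or a lateralization task
#' `positive = "TLE-HS-L"`, `negative = "TLE-HS-R"`.
#'
#' @param cohort A [roi_cohort].
#' @param positive,negative Character vectors of group labels; must be
#'   disjoint and non-empty.
#' @return A list with elements `cohort` (subset, original row order) and
#'   `labels` (integer 0/1 vector).
#' @export
select_binary_groups <- function(cohort, positive, negative) {
  if (!length(positive) || !length(negative))
    stopf("both label sets must be non-empty")
  if (length(intersect(positive, negative)))
    stopf("positive and negative group sets overlap")
  g <- cohort$subjects$group
  keep <- g %in% c(positive, negative)
  if (!any(g %in% positive) || !any(g %in% negative))
    stopf("empty selection: positive n=%d, negative n=%d",
          sum(g %in% positive), sum(g %in% negative))
  sub <- subset_cohort(cohort, which(keep))
  labels <- as.integer(sub$subjects$group %in% positive)
  list(cohort = sub, labels = labels)
}
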