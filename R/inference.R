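#' Permutation-null significance and model comparison
#'
#' The null ("non-optimal") pipeline repeats the evaluation protocol with
#' the training+validation labels randomly permuted and the grid search
#' disabled: the hyperparameters of the optimal real-label pipeline are
#' re-used, ten fold pipelines are trained, the one with the highest
#' (permuted-label) validation accuracy is selected and then evaluated on
#' the untouched test rows with their true labels. Test labels are never
#' permuted.
#'
#' @name inference
NULL

#' Run the permutation-null evaluation
#'
#' @inheritParams run_repeated_evaluation
#' @param fixed_params Hyperparameters of the optimal pipeline (e.g. from
#'   [modal_params()]); no grid search is performed.
#' @return A `null_distribution`: `metrics` (R x 6 data frame), `R`,
#'   `fixed_params`, `master_seed`.
#' @export
run_null_evaluation <- function(cohort, labels, kind = c("svc", "dlc"),
                                fixed_params, R = 1000L, master_seed = 1L,
                                k = 10L, test_fraction = 0.2) {
  kind <- match.arg(kind)
  stopifnot(is.list(fixed_params), length(fixed_params) >= 1)
  seeds <- derive_seeds(master_seed, 4L * R, salt = 23L)
  metrics <- vector("list", R)
  for (r in seq_len(R)) {
    s <- seeds[(4 * (r - 1) + 1):(4 * r)]
    bal <- balance_cohort(cohort, labels, seed = s[1])
    sp <- stratified_split(bal$labels, test_fraction, seed = s[2])
    ytr_true <- bal$labels[sp$train]
    ytr <- with_seed(s[3], sample(ytr_true))      # permute train+val only
    Xtr_all <- bal$cohort$X[sp$train, , drop = FALSE]
    fold <- stratified_folds(ytr, k, seed = s[4])
    fold_acc <- numeric(k)
    fold_pipe <- vector("list", k)
    cand <- as.data.frame(fixed_params)
    for (f in seq_len(k)) {
      tr <- fold != f
      scaler <- fit_scaler(Xtr_all[tr, , drop = FALSE])
      Xs <- apply_scaler(scaler, Xtr_all[tr, , drop = FALSE])
      clf <- fit_candidate(Xs, ytr[tr], kind, cand, s[4])
      Xva <- apply_scaler(scaler, Xtr_all[!tr, , drop = FALSE])
      fold_acc[f] <- mean(predict(clf, Xva, type = "class") == ytr[!tr])
      fold_pipe[[f]] <- structure(
        list(scaler = scaler, classifier = clf, kind = kind,
             params = fixed_params), class = "pipeline_model")
    }
    best <- which.max(fold_acc)
    ev <- evaluate_test(fold_pipe[[best]],
                        bal$cohort$X[sp$test, , drop = FALSE],
                        bal$labels[sp$test])
    metrics[[r]] <- ev$metrics
  }
  metrics <- as.data.frame(do.call(rbind, metrics))[METRIC_NAMES]
  structure(list(metrics = metrics, R = R, fixed_params = fixed_params,
                 kind = kind, master_seed = master_seed),
            class = "null_distribution")
}

#' Permutation p-value for one performance metric
#'
#' The uncorrected counting rule: the fraction of null-pipeline values
#' greater than or equal to the optimal pipeline's mean. An optimal mean
#' exceeding 980 of 1000 null values therefore gives p = 0.02. The
#' smoothed variant `(b + 1)/(R + 1)` is available by flag.
#'
#' @param optimal An `evaluation_summary`, or a single numeric mean.
#' @param null A `null_distribution`, or a numeric vector of null values.
#' @param metric One of PPV, NPV, SEN, SPC, AUC, ACC.
#' @param smoothed Use the `(b + 1)/(R + 1)` rule instead.
#' @return A list: `metric`, `optimal_mean`, `null_mean`, `null_sd`, `p`.
#' @export
compute_p <- function(optimal, null, metric = "ACC", smoothed = FALSE) {
  opt_mean <- if (inherits(optimal, "evaluation_summary")) {
    if (!metric %in% names(optimal$mean)) stopf("unknown metric: %s", metric)
    optimal$mean[[metric]]
  } else as.numeric(optimal)
  null_vals <- if (inherits(null, "null_distribution")) {
    if (!metric %in% names(null$metrics)) stopf("unknown metric: %s", metric)
    null$metrics[[metric]]
  } else as.numeric(null)
  null_vals <- null_vals[!is.na(null_vals)]
  if (!length(null_vals)) stopf("empty null distribution")
  b <- sum(null_vals >= opt_mean)
  R <- length(null_vals)
  p <- if (smoothed) (b + 1) / (R + 1) else b / R
  list(metric = metric, optimal_mean = opt_mean,
       null_mean = mean(null_vals), null_sd = sd(null_vals), p = p)
}

#' Significance report across all six metrics
#'
#' @param optimal An `evaluation_summary`.
#' @param null A `null_distribution`.
#' @param smoothed Passed to [compute_p()].
#' @return A data frame with one row per metric.
#' @export
significance_report <- function(optimal, null, smoothed = FALSE) {
  rows <- lapply(METRIC_NAMES, function(m)
    as.data.frame(compute_p(optimal, null, m, smoothed)))
  do.call(rbind, rows)
}

#' Frequency distribution comparison index (FDCI)
#'
#' Compares two accuracy distributions. The default all-pairs rule is the
#' normalized Mann-Whitney statistic: the fraction of (SVM, DL) pairs in
#' which the SVM accuracy exceeds the DL accuracy, ties counted one half.
#' 0.5 is equipoise; values near 1 mean the first model dominates. A
#' paired per-iteration variant is available.
#'
#' @param acc_svm,acc_dl Accuracy vectors (need not have equal length
#'   unless `paired`).
#' @param paired Compare iteration i against iteration i only.
#' @return A list: `fdci`, `n_svm`, `n_dl`, `ties`, `paired`.
#' @export
compute_fdci <- function(acc_svm, acc_dl, paired = FALSE) {
  if (!length(acc_svm) || !length(acc_dl)) stopf("empty accuracy vector")
  if (paired) {
    if (length(acc_svm) != length(acc_dl))
      stopf("paired comparison needs equal-length vectors")
    ties <- sum(acc_svm == acc_dl)
    fdci <- mean((acc_svm > acc_dl) + 0.5 * (acc_svm == acc_dl))
  } else {
    n1 <- length(acc_svm); n2 <- length(acc_dl)
    r <- rank(c(acc_svm, acc_dl))        # midranks give half-weight ties
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    fdci <- U / (n1 * n2)
    ties <- sum(outer_tie_count(acc_svm, acc_dl))
  }
  list(fdci = fdci, n_svm = length(acc_svm), n_dl = length(acc_dl),
       ties = ties, paired = paired)
}

outer_tie_count <- function(a, b) {
  ta <- table(a); tb <- table(b)
  shared <- intersect(names(ta), names(tb))
  if (!length(shared)) return(0L)
  sum(as.numeric(ta[shared]) * as.numeric(tb[shared]))
}
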