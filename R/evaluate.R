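#' Repeated nested cross-validated evaluation
#'
#' The four-step protocol: (1) shuffle and stratified 80/20 split; (2)
#' 10-fold stratified grid search on the 80% — per validation fold the best
#' hyperparameters by validation accuracy yield one trained pipeline; (3)
#' the fold pipeline with highest validation accuracy is selected; (4) the
#' untouched 20% is predicted and a 2x2 confusion matrix summarized into
#' PPV, NPV, SEN, SPC, AUC and ACC. The whole procedure is repeated R
#' times, re-drawing the balanced subsample each time.
#'
#' @name evaluate
NULL

#' Hyperparameter grid specification
#'
#' Default ranges: SVC regularization C from 0.1 to 2.0 in 0.05 steps; DLC
#' learning rate 0.001-0.01 (step 0.0005), epochs 100-800 (step 50),
#' hidden1 5-100 (step 5), hidden2 3-20 (step 1), L2 penalty 0.1-0.7 (step
#' 0.1), dropout 0.2-0.5 (step 0.1). The exhaustive DLC grid has ~2.9
#' million combinations, so the default search mode draws
#' `subsample_k` random candidates per fold instead.
#'
#' @param kind `"svc"` or `"dlc"`.
#' @param values For `"svc"`: numeric C candidates. For `"dlc"`: named list
#'   of candidate vectors (`learning_rate`, `epochs`, `hidden1`, `hidden2`,
#'   `l2_penalty`, `dropout_rate`).
#' @param search_mode `"exhaustive"` or `"random_subsample"`.
#' @param subsample_k Candidates drawn per fold in random mode.
#' @return A `grid_spec`.
#' @export
grid_spec <- function(kind = c("svc", "dlc"), values = NULL,
                      search_mode = c("exhaustive", "random_subsample"),
                      subsample_k = 60L) {
  kind <- match.arg(kind)
  if (is.null(values)) {
    values <- if (kind == "svc") list(C = seq(0.1, 2.0, by = 0.05))
    else list(learning_rate = seq(0.001, 0.01, by = 5e-4),
              epochs = seq(100L, 800L, by = 50L),
              hidden1 = seq(5L, 100L, by = 5L),
              hidden2 = seq(3L, 20L, by = 1L),
              l2_penalty = seq(0.1, 0.7, by = 0.1),
              dropout_rate = seq(0.2, 0.5, by = 0.1))
  }
  if (kind == "svc" && !is.list(values)) values <- list(C = values)
  search_mode <- if (missing(search_mode))
    if (kind == "svc") "exhaustive" else "random_subsample"
  else match.arg(search_mode)
  structure(list(kind = kind, values = values, search_mode = search_mode,
                 subsample_k = as.integer(subsample_k)),
            class = "grid_spec")
}

# Candidate data frame, ordered so that ties resolve to the preferred
# candidate: SVC by smaller C; DLC by fewer total hidden units, then lower
# learning rate, then remaining columns lexicographically.
grid_candidates <- function(grid, seed = NULL) {
  if (grid$kind == "svc") {
    cand <- data.frame(C = sort(unlist(grid$values$C)))
  } else {
    v <- grid$values
    if (grid$search_mode == "exhaustive") {
      cand <- expand.grid(v, KEEP.OUT.ATTRS = FALSE)
    } else {
      cand <- with_seed(seed, as.data.frame(lapply(v, function(col)
        col[sample.int(length(col), grid$subsample_k, replace = TRUE)])))
      cand <- unique(cand)
    }
    ord <- do.call(order, c(list(cand$hidden1 + cand$hidden2,
                                 cand$learning_rate),
                            cand[setdiff(names(cand),
                                         c("hidden1", "hidden2",
                                           "learning_rate"))]))
    cand <- cand[ord, , drop = FALSE]
    rownames(cand) <- NULL
  }
  cand
}

#' Stratified shuffled train/test split
#'
#' Rows are shuffled, then split per class so that class proportions are
#' preserved to within rounding.
#'
#' @param labels Integer 0/1 vector.
#' @param test_fraction Fraction assigned to the test set (default 0.2).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = 1L) {
  with_seed(seed, {
    train <- integer(0); test <- integer(0)
    for (cl in sort(unique(labels))) {
      idx <- sample(which(labels == cl))
      n_test <- round(test_fraction * length(idx))
      if (n_test < 1 || n_test >= length(idx))
        stopf("class %s too small for stratified splitting", cl)
      test <- c(test, idx[seq_len(n_test)])
      train <- c(train, idx[-seq_len(n_test)])
    }
    list(train = sample(train), test = sample(test))
  })
}

# Stratified k-fold assignment (vector of fold ids aligned with labels).
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  if (min(table(labels)) < k)
    stopf("smallest class (%d) has fewer members than k = %d folds",
          min(table(labels)), k)
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Stratified k-fold grid search
#'
#' For each of `k` validation folds, every candidate is trained on the
#' remaining folds (scaler re-fit inside the training folds) and scored by
#' validation accuracy; the per-fold winner gives one trained pipeline.
#' The fold pipeline with the highest validation accuracy is returned.
#'
#' @param X Unscaled feature matrix (train+validation rows only).
#' @param y Integer 0/1 labels.
#' @param grid A [grid_spec()].
#' @param k Number of folds (default 10).
#' @param seed Integer seed (fold assignment, candidate subsampling, DLC
#'   initialization).
#' @return List: `pipeline` (best `pipeline_model`), `params` (its
#'   hyperparameters), `fold_accuracy` (length-k), `fold_params`.
#' @export
grid_search_cv <- function(X, y, grid, k = 10L, seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"))
  fold <- stratified_folds(y, k, seed)
  fold_best <- vector("list", k)
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    cand <- grid_candidates(grid, seed = seed + f)
    scaler <- fit_scaler(X[tr, , drop = FALSE])
    Xtr <- apply_scaler(scaler, X[tr, , drop = FALSE])
    Xva <- apply_scaler(scaler, X[!tr, , drop = FALSE])
    acc <- vapply(seq_len(nrow(cand)), function(ci) {
      m <- fit_candidate(Xtr, y[tr], grid$kind, cand[ci, , drop = FALSE],
                         seed)
      mean(predict(m, Xva, type = "class") == y[!tr])
    }, numeric(1))
    best <- which.max(acc)               # candidates pre-ordered for ties
    fold_best[[f]] <- list(
      params = as.list(cand[best, , drop = FALSE]),
      pipeline = structure(list(
        scaler = scaler,
        classifier = fit_candidate(Xtr, y[tr], grid$kind,
                                   cand[best, , drop = FALSE], seed),
        kind = grid$kind, params = as.list(cand[best, , drop = FALSE])),
        class = "pipeline_model"))
    fold_acc[f] <- acc[best]
  }
  sel <- which.max(fold_acc)
  list(pipeline = fold_best[[sel]]$pipeline,
       params = fold_best[[sel]]$params,
       fold_accuracy = fold_acc,
       fold_params = lapply(fold_best, `[[`, "params"))
}

fit_candidate <- function(Xs, y, kind, cand, seed) {
  if (kind == "svc") train_svc(Xs, y, C = cand$C)
  else train_dlc(Xs, y, do.call(dlc_config, c(as.list(cand),
                                              list(seed = seed))))
}

#' Confusion matrix and metric set on a test split
#'
#' AUC uses the Mann-Whitney rank statistic on the continuous decision
#' scores with ties counted one half.
#'
#' @param pipeline A trained `pipeline_model`.
#' @param X Unscaled test matrix.
#' @param y Integer 0/1 test labels.
#' @return List with `confusion` (TP, FP, FN, TN) and `metrics` (named
#'   vector PPV, NPV, SEN, SPC, AUC, ACC).
#' @export
evaluate_test <- function(pipeline, X, y) {
  if (!length(y)) stopf("empty test set")
  pred <- predict(pipeline, X, type = "class")
  score <- predict(pipeline, X, type = "score")
  cm <- c(TP = sum(pred == 1 & y == 1), FP = sum(pred == 1 & y == 0),
          FN = sum(pred == 0 & y == 1), TN = sum(pred == 0 & y == 0))
  list(confusion = cm,
       metrics = c(confusion_metrics(cm), AUC = rank_auc(score, y)))
}

confusion_metrics <- function(cm) {
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  c(PPV = div(cm["TP"], cm["TP"] + cm["FP"]),
    NPV = div(cm["TN"], cm["TN"] + cm["FN"]),
    SEN = div(cm["TP"], cm["TP"] + cm["FN"]),
    SPC = div(cm["TN"], cm["TN"] + cm["FP"]),
    ACC = (cm[["TP"]] + cm[["TN"]]) / sum(cm)) |>
    stats::setNames(c("PPV", "NPV", "SEN", "SPC", "ACC"))
}

rank_auc <- function(score, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)                        # average ranks handle ties as 0.5
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

METRIC_NAMES <- c("PPV", "NPV", "SEN", "SPC", "AUC", "ACC")

#' Run the repeated evaluation protocol
#'
#' Each iteration re-draws the balanced majority subsample, re-splits
#' 80/20, re-runs the 10-fold grid search and re-evaluates on the untouched
#' test rows. All per-iteration seeds derive deterministically from
#' `master_seed`.
#'
#' @param cohort A harmonized [roi_cohort] restricted to the task groups.
#' @param labels Integer 0/1 task labels aligned with the cohort.
#' @param kind `"svc"` or `"dlc"`.
#' @param grid A [grid_spec()]; defaults to the standard grid for `kind`.
#' @param R Number of repetitions (study default 1000; tests use far
#'   fewer).
#' @param master_seed Integer master seed.
#' @param k Folds in the inner grid search.
#' @param test_fraction Held-out fraction per iteration.
#' @param keep_models Keep each iteration's fitted pipeline (needed for
#'   importance maps).
#' @return An `evaluation_summary`: `metrics` (R x 6 data frame), `mean`,
#'   `sd`, `params` (per-iteration selected hyperparameters), `models`
#'   (optional), `R`, `master_seed`.
#' @export
run_repeated_evaluation <- function(cohort, labels, kind = c("svc", "dlc"),
                                    grid = NULL, R = 1000L,
                                    master_seed = 1L, k = 10L,
                                    test_fraction = 0.2,
                                    keep_models = TRUE) {
  kind <- match.arg(kind)
  grid <- grid %||% grid_spec(kind)
  seeds <- derive_seeds(master_seed, 3L * R, salt = 11L)
  res <- vector("list", R)
  for (r in seq_len(R)) {
    s <- seeds[(3 * (r - 1) + 1):(3 * r)]
    bal <- balance_cohort(cohort, labels, seed = s[1])
    sp <- stratified_split(bal$labels, test_fraction, seed = s[2])
    stopifnot(length(intersect(sp$train, sp$test)) == 0)
    gs <- grid_search_cv(bal$cohort$X[sp$train, , drop = FALSE],
                         bal$labels[sp$train], grid, k = k, seed = s[3])
    ev <- evaluate_test(gs$pipeline,
                        bal$cohort$X[sp$test, , drop = FALSE],
                        bal$labels[sp$test])
    res[[r]] <- list(metrics = ev$metrics, confusion = ev$confusion,
                     params = gs$params,
                     model = if (keep_models) gs$pipeline else NULL)
  }
  metrics <- as.data.frame(do.call(rbind,
                                   lapply(res, `[[`, "metrics")))[METRIC_NAMES]
  structure(list(
    metrics = metrics,
    mean = colMeans(metrics, na.rm = TRUE),
    sd = apply(metrics, 2, sd, na.rm = TRUE),
    params = lapply(res, `[[`, "params"),
    confusion = lapply(res, `[[`, "confusion"),
    models = if (keep_models) lapply(res, `[[`, "model") else NULL,
    kind = kind, R = R, master_seed = master_seed),
    class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf("<evaluation_summary> %s, R = %d\n", x$kind, x$R))
  print(round(rbind(mean = x$mean, sd = x$sd), 4))
  invisible(x)
}

#' Most frequently selected hyperparameters of an evaluation run
#'
#' Ties are broken in favor of the parameter set whose iterations achieved
#' the higher mean test accuracy.
#'
#' @param summary An `evaluation_summary`.
#' @return A named list of hyperparameters.
#' @export
modal_params <- function(summary) {
  key <- vapply(summary$params, function(p)
    paste(names(p), unlist(p), sep = "=", collapse = ";"), character(1))
  tab <- table(key)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1) {
    accs <- vapply(top, function(kk)
      mean(summary$metrics$ACC[key == kk]), numeric(1))
    top <- top[which.max(accs)]
  }
  summary$params[[match(top, key)]]
}
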