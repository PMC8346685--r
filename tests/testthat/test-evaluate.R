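test_that("stratified split preserves class proportions and is seeded", {
  y <- rep(0:1, each = 100)
  sp <- stratified_split(y, 0.2, seed = 3)
  expect_equal(length(sp$test), 40)
  expect_equal(sum(y[sp$test]), 20)
  expect_equal(sum(y[sp$train]), 80)
  expect_equal(sort(c(sp$train, sp$test)), seq_along(y))  # exhaustive
  expect_identical(stratified_split(y, 0.2, seed = 3), sp)
  expect_false(identical(stratified_split(y, 0.2, seed = 4)$test, sp$test))

  # 60/40 proportions within one subject of exact
  y2 <- rep(0:1, c(60, 40))
  sp2 <- stratified_split(y2, 0.2, seed = 1)
  expect_lte(abs(sum(y2[sp2$test] == 0) - 12), 1)
  expect_lte(abs(sum(y2[sp2$test] == 1) - 8), 1)

  expect_error(stratified_split(rep(0:1, c(100, 2)), 0.2, seed = 1),
               "too small")
})

test_that("grid candidates respect ranges and tie-preferred ordering", {
  gs <- grid_spec("svc")
  cand <- roiclass:::grid_candidates(gs)
  expect_equal(nrow(cand), 39)
  expect_equal(range(cand$C), c(0.1, 2.0))
  expect_true(!is.unsorted(cand$C))        # smaller C wins ties

  gd <- grid_spec("dlc", subsample_k = 25)
  cd <- roiclass:::grid_candidates(gd, seed = 5)
  expect_lte(nrow(cd), 25)
  expect_true(all(cd$learning_rate >= 0.001 & cd$learning_rate <= 0.01))
  expect_true(all(cd$hidden1 %in% seq(5, 100, 5)))
  expect_true(all(cd$hidden2 %in% 3:20))
  expect_true(all(cd$dropout_rate >= 0.2 & cd$dropout_rate <= 0.5))
  tot <- cd$hidden1 + cd$hidden2
  expect_true(!is.unsorted(tot))           # fewer units first
  expect_identical(roiclass:::grid_candidates(gd, seed = 5), cd)
})

test_that("grid search returns the single candidate and rejects tiny folds", {
  cl <- gaussian_clouds(n = 30, p = 4, sep = 3, seed = 2)
  gs <- grid_search_cv(cl$X, cl$y, grid_spec("svc", values = 0.7),
                       k = 5, seed = 1)
  expect_equal(gs$params$C, 0.7)
  expect_equal(length(gs$fold_accuracy), 5)
  expect_error(grid_search_cv(cl$X, cl$y, grid_spec("svc"), k = 40,
                              seed = 1), "fewer members")
})

test_that("a degenerate candidate is never selected on separable data", {
  cl <- gaussian_clouds(n = 40, p = 4, sep = 4, seed = 12)
  gs <- grid_search_cv(cl$X, cl$y,
                       grid_spec("svc", values = c(1e-9, 1.0)),
                       k = 5, seed = 2)
  expect_equal(gs$params$C, 1.0)
  expect_true(all(vapply(gs$fold_params, `[[`, numeric(1), "C") == 1.0))
})

test_that("strong-signal data yields high validation accuracy", {
  sim <- generate_cohort(generator_config(
    d = 2, n_sites = 1, tau = 0, lambda = Inf,
    n_per_group = c(HC = 60, "TLE-HS-L" = 60), seed = 10))
  task <- select_binary_groups(sim$cohort, "TLE-HS-L", "HC")
  gs <- grid_search_cv(task$cohort$X, task$labels,
                       grid_spec("svc", values = seq(0.1, 2, 0.25)),
                       k = 10, seed = 3)
  expect_gte(max(gs$fold_accuracy), 0.85)
})

test_that("confusion metrics match the closed forms", {
  # TP=8 FP=2 FN=2 TN=8
  pipe <- structure(list(), class = "const_pipe")
  y <- rep(c(1, 0), each = 10)
  pred <- c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8))
  cm <- c(TP = 8, FP = 2, FN = 2, TN = 8)
  m <- roiclass:::confusion_metrics(cm)
  expect_equal(unname(m[c("PPV", "NPV", "SEN", "SPC", "ACC")]),
               rep(0.8, 5))
  # degenerate denominators give NA, not NaN crashes
  m0 <- roiclass:::confusion_metrics(c(TP = 0, FP = 0, FN = 5, TN = 5))
  expect_true(is.na(m0[["PPV"]]))
})

test_that("rank AUC handles perfect ranking and full ties", {
  y <- rep(0:1, each = 5)
  expect_equal(roiclass:::rank_auc(seq_len(10), y), 1.0)
  expect_equal(roiclass:::rank_auc(rev(seq_len(10)), y), 0.0)
  expect_equal(roiclass:::rank_auc(rep(1, 10), y), 0.5)
  # matches the probabilistic definition on a mixed case
  set.seed(1)
  s <- rnorm(10)
  brute <- mean(outer(s[y == 1], s[y == 0],
                      function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(roiclass:::rank_auc(s, y), brute)
})

test_that("evaluate_test wires pipeline predictions into metrics", {
  cl <- gaussian_clouds(n = 30, p = 3, sep = 5, seed = 3)
  pm <- fit_pipeline(cl$X, cl$y, "svc", list(C = 1))
  ev <- evaluate_test(pm, cl$X, cl$y)
  expect_equal(sum(ev$confusion), length(cl$y))
  expect_equal(ev$metrics[["ACC"]], 1.0)
  expect_equal(ev$metrics[["AUC"]], 1.0)
  expect_error(evaluate_test(pm, cl$X[0, ], integer(0)), "empty test")
})

test_that("repeated evaluation is reproducible and leakage-free", {
  sim <- generate_cohort(generator_config(
    d = 1.5, n_sites = 1, tau = 0, lambda = Inf,
    n_per_group = c(HC = 40, "TLE-HS-L" = 30), seed = 20))
  task <- select_binary_groups(sim$cohort, "TLE-HS-L", "HC")
  grid <- grid_spec("svc", values = c(0.5, 1))
  e1 <- run_repeated_evaluation(task$cohort, task$labels, "svc", grid,
                                R = 2, master_seed = 7, k = 5)
  e2 <- run_repeated_evaluation(task$cohort, task$labels, "svc", grid,
                                R = 2, master_seed = 7, k = 5)
  expect_identical(e1$metrics, e2$metrics)
  expect_identical(e1$params, e2$params)
  expect_equal(nrow(e1$metrics), 2)
  # summary statistics recompute exactly from the stored iterations
  expect_equal(e1$mean, colMeans(e1$metrics), tolerance = 1e-12)
  expect_equal(e1$sd, apply(e1$metrics, 2, sd), tolerance = 1e-12)
})

test_that("null data yields chance-level accuracy", {
  sim <- generate_cohort(generator_config(
    d = 0, n_sites = 1, tau = 0, lambda = Inf,
    n_per_group = c(HC = 40, "TLE-HS-L" = 40), seed = 21))
  task <- select_binary_groups(sim$cohort, "TLE-HS-L", "HC")
  ev <- run_repeated_evaluation(task$cohort, task$labels, "svc",
                                grid_spec("svc", values = c(0.1, 1)),
                                R = 20, master_seed = 5, k = 5)
  expect_lt(abs(ev$mean[["ACC"]] - 0.5), 0.1)
})

test_that("modal_params returns the most frequent selection", {
  fake <- structure(list(
    params = list(list(C = 1), list(C = 1), list(C = 2)),
    metrics = data.frame(ACC = c(0.9, 0.8, 0.7))),
    class = "evaluation_summary")
  expect_equal(modal_params(fake)$C, 1)
})
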