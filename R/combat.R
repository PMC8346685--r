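#' Empirical-Bayes multi-site harmonization (ComBat)
#'
#' Location/scale harmonization of ROI features across acquisition sites.
#' Each feature is standardized by a least-squares fit over site indicators
#' plus covariates; per-site location (gamma) and scale (delta) estimates
#' are then shrunk toward site-level priors by the parametric
#' normal/inverse-gamma empirical-Bayes iteration, and the data are
#' reconstructed with the site effects removed.
#'
#' Two conventions are fixed here and mirrored by the test oracle:
#' per-site scale estimates use the n-denominator (biased) variance so that
#' a single-site fit reconstructs its input exactly, and age is centered at
#' the fitting-sample mean before regression.
#'
#' @name combat
NULL

#' Fit a ComBat harmonization model
#'
#' @param cohort A [roi_cohort] without missing values.
#' @param covariates Subset of `c("age", "sex", "group")` whose effects are
#'   estimated during standardization. Default `c("age", "sex")`.
#' @param tol Relative-change tolerance of the empirical-Bayes iteration.
#' @param max_iter Maximum empirical-Bayes iterations per site.
#' @return A `combat_model` with per-feature intercept `alpha`, covariate
#'   coefficients `beta`, pooled SD `sigma`, per-site EB location
#'   `gamma_star` and scale `delta_star`, site priors, and iteration counts.
#' @export
fit_combat <- function(cohort, covariates = c("age", "sex"),
                       tol = 1e-4, max_iter = 100L) {
  stopifnot(inherits(cohort, "roi_cohort"))
  covariates <- if (length(covariates))
    match.arg(covariates, c("age", "sex", "group"), several.ok = TRUE)
  else character(0)
  X <- cohort$X
  if (anyNA(X)) stopf("cohort contains missing values; filter first")
  M <- nrow(X); N <- ncol(X)
  site <- factor(cohort$subjects$site)
  n_i <- table(site)
  if (any(n_i < 2))
    stopf("site(s) with fewer than 2 subjects: %s",
          paste(names(n_i)[n_i < 2], collapse = ", "))
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stopf("zero-variance feature: %s", colnames(X)[which(sds == 0)[1]])

  age_center <- mean(cohort$subjects$age)
  group_levels <- sort(unique(cohort$subjects$group))
  # explicit indicator matrix (model.matrix breaks on single-level factors)
  D_site <- vapply(levels(site), function(s) as.numeric(site == s),
                   numeric(M))
  D_cov <- build_cov_design(cohort, covariates, age_center, group_levels)
  D <- cbind(D_site, D_cov)
  qrD <- qr(D)
  if (qrD$rank < ncol(D))
    stopf("rank-deficient design (confounded site/covariates)")
  B <- qr.coef(qrD, X)                       # (n_site + n_cov) x N
  n_site <- ncol(D_site)
  B_site <- B[seq_len(n_site), , drop = FALSE]
  B_cov <- B[-seq_len(n_site), , drop = FALSE]

  w <- as.numeric(n_i) / M
  alpha <- as.numeric(crossprod(w, B_site))  # grand mean per feature
  resid <- X - D %*% B
  var_pooled <- colSums(resid^2) / M
  sigma <- sqrt(var_pooled)

  cov_part <- if (ncol(D_cov)) D_cov %*% B_cov else matrix(0, M, N)
  Z <- sweep(sweep(X - cov_part, 2, alpha, "-"), 2, sigma, "/")

  sites <- levels(site)
  gamma_hat <- t(vapply(sites, function(s) colMeans(Z[site == s, ,
                                                      drop = FALSE]),
                        numeric(N)))
  # n-denominator variance: exact identity on single-site fits
  delta_hat2 <- t(vapply(sites, function(s) {
    Zi <- Z[site == s, , drop = FALSE]
    colMeans(sweep(Zi, 2, colMeans(Zi), "-")^2)
  }, numeric(N)))

  gamma_star <- gamma_hat
  delta_star2 <- delta_hat2
  priors <- data.frame(site = sites, gamma_bar = NA_real_, tau2 = NA_real_,
                       lambda_bar = NA_real_, theta_bar = NA_real_,
                       iterations = 0L, stringsAsFactors = FALSE)
  for (k in seq_along(sites)) {
    Zi <- Z[site == sites[k], , drop = FALSE]
    eb <- eb_site(gamma_hat[k, ], delta_hat2[k, ], Zi, tol, max_iter)
    gamma_star[k, ] <- eb$gamma_star
    delta_star2[k, ] <- eb$delta_star2
    priors[k, 2:5] <- c(eb$gamma_bar, eb$tau2, eb$lambda_bar, eb$theta_bar)
    priors$iterations[k] <- eb$iterations
  }
  rownames(gamma_star) <- rownames(delta_star2) <- sites

  structure(list(
    alpha = alpha, beta = B_cov, sigma = sigma,
    gamma_star = gamma_star, delta_star = sqrt(delta_star2),
    priors = priors, covariates = covariates,
    age_center = age_center, group_levels = group_levels,
    sites = sites, features = colnames(X)),
    class = "combat_model")
}

build_cov_design <- function(cohort, covariates, age_center, group_levels) {
  cols <- list()
  if ("age" %in% covariates)
    cols$age <- cohort$subjects$age - age_center
  if ("sex" %in% covariates)
    cols$sex <- as.numeric(cohort$subjects$sex)
  if ("group" %in% covariates) {
    g <- factor(cohort$subjects$group, levels = group_levels)
    if (anyNA(g)) stopf("group label not seen at fit time")
    if (length(group_levels) > 1) {
      mm <- stats::model.matrix(~ g)[, -1, drop = FALSE]
      colnames(mm) <- paste0("group_", group_levels[-1])
      for (j in seq_len(ncol(mm))) cols[[colnames(mm)[j]]] <- mm[, j]
    }
  }
  if (!length(cols)) return(matrix(0, n_subjects(cohort), 0))
  do.call(cbind, cols)
}

# Parametric EB shrinkage for one site: normal prior on location,
# inverse-gamma prior on squared scale, iterated to joint convergence.
eb_site <- function(g_hat, d_hat2, Zi, tol, max_iter) {
  n <- nrow(Zi)
  gamma_bar <- mean(g_hat)
  tau2 <- var(g_hat)
  m <- mean(d_hat2); s2 <- var(d_hat2)
  degenerate <- !is.finite(s2) || s2 < 1e-12
  lambda_bar <- if (degenerate) NA_real_ else (2 * s2 + m^2) / s2
  theta_bar <- if (degenerate) NA_real_ else (m * s2 + m^3) / s2
  if (!is.finite(tau2) || tau2 < 1e-12) {
    # no spread across features: prior is a point mass at gamma_bar
    return(list(gamma_star = rep(gamma_bar, length(g_hat)),
                delta_star2 = d_hat2, gamma_bar = gamma_bar, tau2 = tau2,
                lambda_bar = lambda_bar, theta_bar = theta_bar,
                iterations = 0L))
  }
  g_old <- g_hat; d_old <- d_hat2
  it <- 0L; change <- Inf
  while (change > tol && it < max_iter) {
    g_new <- (n * tau2 * g_hat + d_old * gamma_bar) / (n * tau2 + d_old)
    if (degenerate) {
      d_new <- d_old
    } else {
      sum2 <- colSums(sweep(Zi, 2, g_new, "-")^2)
      d_new <- (theta_bar + 0.5 * sum2) / (n / 2 + lambda_bar - 1)
    }
    change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                  abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
    g_old <- g_new; d_old <- d_new; it <- it + 1L
  }
  list(gamma_star = g_old, delta_star2 = d_old, gamma_bar = gamma_bar,
       tau2 = tau2, lambda_bar = lambda_bar, theta_bar = theta_bar,
       iterations = it)
}

#' @export
print.combat_model <- function(x, ...) {
  cat(sprintf("<combat_model> %d features, %d sites; covariates: %s\n",
              length(x$alpha), length(x$sites),
              paste(x$covariates, collapse = ", ")))
  invisible(x)
}

#' Apply a fitted ComBat model to a cohort
#'
#' Standardizes each feature with the fitted coefficients, removes the
#' empirical-Bayes site location/scale adjustment, and reconstructs. With
#' `restore = character(0)` (default) the fitted covariate effects are
#' removed together with the site effects — site, age and sex differences
#' are all minimized. With `restore = c("age", "sex")` the classic
#' covariate-preserving behavior is obtained.
#'
#' @param model A `combat_model` from [fit_combat()].
#' @param cohort A [roi_cohort]; its sites must all have been seen at fit.
#' @param restore Subset of the fitted covariates to add back.
#' @return The harmonized [roi_cohort].
#' @export
apply_combat <- function(model, cohort, restore = character(0)) {
  stopifnot(inherits(model, "combat_model"), inherits(cohort, "roi_cohort"))
  if (!identical(colnames(cohort$X), model$features))
    stopf("cohort features do not match the fitted model")
  if (length(restore) && !all(restore %in% model$covariates))
    stopf("restore must be a subset of the fitted covariates")
  site <- as.character(cohort$subjects$site)
  unseen <- setdiff(unique(site), model$sites)
  if (length(unseen))
    stopf("site(s) not seen at fit time: %s", paste(unseen, collapse = ", "))
  X <- cohort$X
  if (anyNA(X)) stopf("cohort contains missing values; filter first")
  M <- nrow(X); N <- ncol(X)

  D_cov <- build_cov_design(cohort, model$covariates, model$age_center,
                            model$group_levels)
  cov_part <- if (ncol(D_cov)) D_cov %*% model$beta else matrix(0, M, N)
  Z <- sweep(sweep(X - cov_part, 2, model$alpha, "-"), 2, model$sigma, "/")
  idx <- match(site, model$sites)
  Zc <- (Z - model$gamma_star[idx, , drop = FALSE]) /
    model$delta_star[idx, , drop = FALSE]
  Y <- sweep(sweep(Zc, 2, model$sigma, "*"), 2, model$alpha, "+")
  if (length(restore)) {
    D_r <- build_cov_design(cohort, restore, model$age_center,
                            model$group_levels)
    keep <- colnames(D_cov) %in% colnames(D_r)
    if (is.null(colnames(D_cov))) keep <- rep(TRUE, ncol(D_cov))
    Y <- Y + D_cov[, keep, drop = FALSE] %*%
      model$beta[keep, , drop = FALSE]
  }
  roi_cohort(cohort$subjects, Y, cohort$schema)
}
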