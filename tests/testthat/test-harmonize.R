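two_site_sim <- function(seed = 21, n = 100, gamma_bar = c(0, 2), d = 0) {
  generate_cohort(generator_config(
    d = d, gamma_bar = gamma_bar, tau = 0.05, lambda = 6, theta = 5,
    n_per_group = c(HC = n / 2, "TLE-HS-L" = n / 2), seed = seed))
}

site_mean_diff <- function(cohort) {
  s <- cohort$subjects$site
  colMeans(cohort$X[s == "site01", , drop = FALSE]) -
    colMeans(cohort$X[s == "site02", , drop = FALSE])
}

test_that("single-site fit+apply with all covariates restored is identity", {
  sim <- generate_cohort(generator_config(
    n_sites = 1, tau = 0, lambda = Inf, seed = 3))
  m <- fit_combat(sim$cohort, covariates = c("age", "sex"))
  out <- apply_combat(m, sim$cohort, restore = c("age", "sex"))
  expect_lt(max(abs(out$X - sim$cohort$X)), 1e-8)
  expect_lt(max(abs(m$gamma_star)), 1e-6)
  expect_lt(max(abs(m$delta_star - 1)), 1e-6)
})

test_that("two-site shifts are recovered and removed", {
  sim <- two_site_sim()
  m <- fit_combat(sim$cohort)
  # estimated locations (z-scale) correlate with realized shifts
  gamma_true <- sweep(sim$truth$gamma, 2,
                      colMeans(sim$truth$gamma))  # identifiable part
  r <- cor(as.numeric(m$gamma_star), as.numeric(gamma_true / m$sigma[col(gamma_true)]))
  expect_gt(r, 0.9)
  harm <- apply_combat(m, sim$cohort)
  before <- abs(site_mean_diff(sim$cohort))
  after <- abs(site_mean_diff(harm))
  expect_true(all(after <= 0.1 * before))     # >= 90% shrink per feature
})

test_that("EB shrinks small-site estimates toward the site prior mean", {
  sch <- build_diffusion_schema("FA")
  set.seed(55)
  # one small site among several large ones, each with genuine
  # feature-level shifts: the prior spread tau^2 then reflects real
  # structure (comparable across sites) rather than estimation noise, and
  # shrinkage strength is governed by site size as intended
  sizes <- c(small = 14L, big = 200L, big2 = 200L, big3 = 200L)
  M <- sum(sizes)
  subjects <- data.frame(
    subject_id = sprintf("S%04d", 1:M),
    group = "HC",
    site = rep(names(sizes), sizes),
    age = runif(M, 20, 60),
    sex = rbinom(M, 1, 0.5))
  X <- matrix(rnorm(M * 41), ncol = 41, dimnames = list(NULL, sch$name))
  shift <- matrix(rnorm(4 * 41, sd = 0.5), 4, 41,
                  dimnames = list(names(sizes), NULL))
  X <- X + shift[subjects$site, ]
  co <- roi_cohort(subjects, X, sch)
  m <- fit_combat(co, covariates = character(0))
  # raw per-site location estimates, reconstructed independently
  alpha <- m$alpha; sigma <- m$sigma
  z <- sweep(sweep(X, 2, alpha), 2, sigma, "/")
  for (s in c("small", "big")) {
    gam_hat <- colMeans(z[subjects$site == s, ])
    gam_star <- m$gamma_star[s, ]
    prior <- m$priors$gamma_bar[m$priors$site == s]
    # shrinkage moves the estimate strictly toward the prior mean
    expect_true(all(abs(gam_star - prior) <= abs(gam_hat - prior) + 1e-12))
  }
  shrink <- function(s) {
    gam_hat <- colMeans(z[subjects$site == s, ])
    prior <- m$priors$gamma_bar[m$priors$site == s]
    mean(abs(m$gamma_star[s, ] - gam_hat) / pmax(abs(gam_hat - prior), 1e-9))
  }
  expect_gt(shrink("small"), shrink("big"))  # small n => stronger pull
})

test_that("group signal survives harmonization when groups are balanced", {
  sim <- two_site_sim(seed = 77, n = 500, d = 1)
  cohens_d <- function(cohort, rows = TRUE) {
    case <- cohort$subjects$group[rows] != "HC"
    v <- cohort$X[rows, 1]   # first feature is affected
    (mean(v[case]) - mean(v[!case])) /
      sqrt((var(v[case]) + var(v[!case])) / 2)
  }
  # pre-harmonization effect measured within each site (the pooled d is
  # diluted by the large between-site shift, which is what ComBat removes)
  d_within <- mean(vapply(unique(sim$cohort$subjects$site), function(s)
    cohens_d(sim$cohort, sim$cohort$subjects$site == s), numeric(1)))
  harm <- apply_combat(fit_combat(sim$cohort), sim$cohort)
  expect_lt(abs(cohens_d(harm) - d_within), 0.2)
  expect_lt(abs(cohens_d(harm) - sim$truth$d), 0.2)
})

test_that("re-fitting on harmonized output finds no residual site effect", {
  sim <- two_site_sim(seed = 9)
  harm <- apply_combat(fit_combat(sim$cohort), sim$cohort)
  m2 <- fit_combat(harm)
  expect_lt(max(abs(m2$gamma_star)), 0.05)
  expect_lt(max(abs(m2$delta_star - 1)), 0.1)
})

test_that("harmonization is deterministic and validates inputs", {
  sim <- two_site_sim(seed = 12, n = 30)
  m1 <- fit_combat(sim$cohort); m2 <- fit_combat(sim$cohort)
  expect_identical(m1$gamma_star, m2$gamma_star)

  tiny <- subset_idx <- c(which(sim$cohort$subjects$site == "site01"),
                          which(sim$cohort$subjects$site == "site02")[1])
  expect_error(fit_combat(roiclass:::subset_cohort(sim$cohort, tiny)),
               "fewer than 2")

  flat <- sim$cohort
  flat$X[, 3] <- 1.7
  expect_error(fit_combat(flat), "zero-variance feature")
  expect_error(fit_combat(flat), colnames(flat$X)[3])

  co_na <- sim$cohort; co_na$X[1, 1] <- NA
  expect_error(fit_combat(co_na), "missing")

  m <- fit_combat(sim$cohort)
  other <- sim$cohort
  other$subjects$site[1] <- "siteXX"
  expect_error(apply_combat(m, other), "not seen at fit")
})

test_that("restoring covariates adds back exactly the fitted effects", {
  sim <- two_site_sim(seed = 31)
  m <- fit_combat(sim$cohort)
  h_none <- apply_combat(m, sim$cohort)
  h_age <- apply_combat(m, sim$cohort, restore = c("age", "sex"))
  delta <- h_age$X - h_none$X
  # difference must be an affine function of age and sex per feature
  for (g in c(1, 20)) {
    fit <- stats::lm(delta[, g] ~ I(sim$cohort$subjects$age) +
                       sim$cohort$subjects$sex)
    expect_lt(max(abs(stats::residuals(fit))), 1e-10)
  }
  expect_error(apply_combat(m, sim$cohort, restore = "group"),
               "subset of the fitted")
})

test_that("agreement with the independent cross-language oracle", {
  oracle <- system.file("oracle", "combat_oracle.py", package = "roiclass")
  skip_if(oracle == "", "oracle script not installed")
  sim <- two_site_sim(seed = 66, n = 60)
  csv_in <- tempfile(fileext = ".csv")
  csv_out <- tempfile(fileext = ".csv")
  write_cohort(sim$cohort, csv_in)
  status <- suppressWarnings(
    system2("python", c(oracle, csv_in, csv_out), stdout = FALSE,
            stderr = FALSE))
  skip_if(status != 0, "python oracle not runnable")
  ours <- apply_combat(fit_combat(sim$cohort), sim$cohort)
  theirs <- as.matrix(utils::read.csv(csv_out, check.names = FALSE))
  expect_equal(dim(theirs), dim(ours$X))
  expect_lt(max(abs(ours$X - theirs)), 1e-6)
})
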