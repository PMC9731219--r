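test_that("noiseless synthetic data is recovered exactly", {
  cfg <- sim_config(
    n_subjects = 1, n_trials = 30, noise_sd = 0, subject_sd = 0.4,
    categorical_effect = list(amplitude = 1.5,
                              channels = c("E01", "E02"),
                              window = c(300, 380)),
    covariate_specs = list(list(name = "v", amplitude = 2,
                                channels = "E11", window = c(50, 100))),
    seed = 13
  )
  sim <- simulate_dataset(cfg)
  ep <- sim$epochs[[1]]
  fit <- fit_glm(ep, sim_design(ep, "v"))

  vmask <- sim$truth$masks$v
  cmask <- sim$truth$masks$categorical
  # covariate beta equals the generating amplitude inside its window
  expect_lt(max(abs(fit$betas[, , "v"][vmask] - 2)), 1e-8)
  expect_lt(max(abs(fit$betas[, , "v"][!vmask])), 1e-8)
  # signed coding splits the categorical amplitude over the two
  # columns; their difference restores it
  contrast <- compute_contrast(fit)
  expect_lt(max(abs(contrast$values[cmask] - 1.5)), 1e-8)
  expect_lt(max(abs(contrast$values[!cmask])), 1e-8)
  # perfect fit wherever any effect creates across-trial variance
  expect_lt(max(abs(fit$r2[vmask | cmask] - 1)), 1e-8)
  expect_true(all(fit$r2[!(vmask | cmask)] == 0))
})

test_that("rank-deficient dummy coding matches a full-rank reparameterization", {
  ep <- noise_epochs(n_trials = 40, n_ch = 2, n_t = 5, k = 1, seed = 14)
  z <- zscore_covariates(ep$covariates)
  d <- build_design(ep$categories, z, coding = "dummy")
  fit <- fit_glm(ep, d)
  expect_true(all(is.finite(fit$betas)))

  # independent full-rank fit via lm() per point
  Xfr <- model.matrix(~ factor(ep$categories) + z$c1)
  for (ch in 1:2) {
    for (tp in c(1, 3, 5)) {
      y <- ep$data[, ch, tp]
      ref <- lm.fit(Xfr, y)
      pred <- d$matrix %*% fit$betas[ch, tp, ]
      expect_lt(max(abs(pred - ref$fitted.values)), 1e-8)
      expect_equal(unname(fit$r2[ch, tp]),
                   1 - sum(ref$residuals^2) / sum((y - mean(y))^2),
                   tolerance = 1e-10)
    }
  }
})

test_that("pure-noise R2 sits at the closed-form random-regressor scale", {
  # one effective regressor under signed coding: E[R2] = 1/(n-1)
  n <- 100
  reps <- 40
  r2s <- numeric(reps)
  for (r in seq_len(reps)) {
    ep <- noise_epochs(n_trials = n, n_ch = 2, n_t = 10, k = 0, seed = 100 + r)
    fit <- fit_glm(ep, sim_design(ep, NULL))
    r2s[r] <- mean(fit$r2)
  }
  p <- 1
  beta_var <- (p / 2) * ((n - 1 - p) / 2) /
    (((n - 1) / 2)^2 * ((n - 1) / 2 + 1))
  se <- sqrt(beta_var / (reps * 20))
  expect_lt(abs(mean(r2s) - 1 / (n - 1)), 3 * se)
})

test_that("overfitting guard and input validation trigger", {
  ep <- noise_epochs(n_trials = 5, n_ch = 2, n_t = 3, k = 2, seed = 15)
  d <- build_design(ep$categories, zscore_covariates(ep$covariates))
  expect_error(fit_glm(ep, d), "parameters",
               class = "erpsep_validation_error")
  ep2 <- noise_epochs(n_trials = 10, n_ch = 2, n_t = 3, k = 0, seed = 15)
  d2 <- sim_design(ep2, NULL)
  expect_error_class(fit_glm(noise_epochs(12), d2),
                     "erpsep_consistency_error")
})

test_that("contrast is antisymmetric in the category columns", {
  ep <- noise_epochs(n_trials = 30, n_ch = 3, n_t = 8, k = 0, seed = 16)
  fit_ab <- fit_glm(ep, build_design(ep$categories, levels = c("A", "B")))
  fit_ba <- fit_glm(ep, build_design(ep$categories, levels = c("B", "A")))
  ca <- compute_contrast(fit_ab)
  cb <- compute_contrast(fit_ba)
  expect_equal(ca$values, -cb$values, tolerance = 1e-10)
})

test_that("contrast ignores a constant shift of all trials", {
  ep <- noise_epochs(n_trials = 30, n_ch = 2, n_t = 6, k = 0, seed = 17)
  shifted <- ep
  shifted$data <- ep$data + 7.5
  d <- sim_design(ep, NULL)
  c1 <- compute_contrast(fit_glm(ep, d))
  c2 <- compute_contrast(fit_glm(shifted, d))
  expect_equal(c1$values, c2$values, tolerance = 1e-10)
})

test_that("adding columns never decreases R2 (nested monotonicity)", {
  ep <- noise_epochs(n_trials = 60, n_ch = 4, n_t = 12, k = 3, seed = 18)
  z <- zscore_covariates(ep$covariates)
  r2_cat <- fit_glm(ep, build_design(ep$categories))$r2
  r2_one <- fit_glm(ep, build_design(ep$categories, z[, 1, drop = FALSE]))$r2
  r2_all <- fit_glm(ep, build_design(ep$categories, z))$r2
  expect_true(all(r2_one - r2_cat >= -1e-12))
  expect_true(all(r2_all - r2_one >= -1e-12))
})

test_that("covariate column permutation permutes betas, preserves R2", {
  ep <- noise_epochs(n_trials = 50, n_ch = 2, n_t = 6, k = 3, seed = 19)
  z <- zscore_covariates(ep$covariates)
  f1 <- fit_glm(ep, build_design(ep$categories, z))
  f2 <- fit_glm(ep, build_design(ep$categories, z[, c(3, 1, 2)]))
  expect_equal(f1$r2, f2$r2, tolerance = 1e-10)
  expect_equal(f1$betas[, , "c2"], f2$betas[, , "c2"], tolerance = 1e-10)
})

test_that("naive baseline averages repetitions and is order-invariant", {
  ep <- noise_epochs(n_trials = 60, n_ch = 2, n_t = 8, k = 4, seed = 20)
  d <- build_design(ep$categories, zscore_covariates(ep$covariates))

  one <- naive_baseline(ep, d, n_reps = 1, seed = 7)
  single <- fit_glm(ep, make_naive_design(d, one$seeds[1]))
  expect_equal(one$mean_r2, single$r2, tolerance = 1e-12)

  nb <- naive_baseline(ep, d, n_reps = 5, seed = 7)
  manual <- Reduce(`+`, lapply(nb$seeds[c(4, 2, 5, 1, 3)], function(s) {
    fit_glm(ep, make_naive_design(d, s))$r2
  })) / 5
  expect_equal(nb$mean_r2, manual, tolerance = 1e-12)

  cat_only <- build_design(ep$categories)
  expect_error_class(naive_baseline(ep, cat_only, 2, 1),
                     "erpsep_validation_error")
})

test_that("naive mean R2 matches the (k+1)/(n-1) dimensionality expectation", {
  n <- 100
  k <- 8
  ep <- noise_epochs(n_trials = n, n_ch = 3, n_t = 20, k = k, seed = 21)
  d <- build_design(ep$categories, zscore_covariates(ep$covariates))
  nb <- naive_baseline(ep, d, n_reps = 30, seed = 5)
  p <- k + 1  # k covariates + one effective category dimension
  expected <- p / (n - 1)
  # the category contribution is common to all repetitions (same data,
  # same category column), so it only averages over the 60 grid points;
  # the covariate contribution averages over points x repetitions
  beta_var <- function(q) {
    (q / 2) * ((n - 1 - q) / 2) / (((n - 1) / 2)^2 * ((n - 1) / 2 + 1))
  }
  se <- sqrt(beta_var(1) / 60 + beta_var(k) / (30 * 60))
  expect_lt(abs(mean(nb$mean_r2) - expected), 3 * se)
})
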