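test_that("identical config and seed give bit-identical datasets", {
  cfg <- sim_config(n_subjects = 3, n_trials = 20, seed = 11)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$epochs, b$epochs)
  expect_identical(a$truth$covariates, b$truth$covariates)
  c <- simulate_dataset(sim_config(n_subjects = 3, n_trials = 20, seed = 12))
  expect_false(identical(a$epochs[[1]]$data, c$epochs[[1]]$data))
})

test_that("noiseless covariate effect reproduces amplitude x z-value exactly", {
  cfg <- sim_config(
    n_subjects = 1, n_trials = 10, channel_layout = c(2, 2),
    srate = 128, time_window = c(0, 200),
    categorical_effect = list(amplitude = 0, channels = "E01",
                              window = c(150, 200)),
    covariate_specs = list(list(name = "v", amplitude = 2,
                                channels = c("E01", "E02"),
                                window = c(50, 100))),
    noise_sd = 0, subject_sd = 0, seed = 4
  )
  sim <- simulate_dataset(cfg)
  ep <- sim$epochs[[1]]
  z <- sim$truth$covariates[[1]]$v
  mask <- sim$truth$masks$v
  for (tr in c(1, 5, 10)) {
    slice <- ep$data[tr, , ]
    expect_equal(slice[mask], rep(2 * z[tr], sum(mask)), tolerance = 1e-12)
    expect_true(all(slice[!mask] == 0))
  }
})

test_that("null categorical effect leaves the mean contrast near zero", {
  cfg <- sim_config(
    n_subjects = 1, n_trials = 100,
    categorical_effect = list(amplitude = 0, channels = "E01",
                              window = c(300, 380)),
    covariate_specs = list(), noise_sd = 1, seed = 21
  )
  ep <- simulate_dataset(cfg)$epochs[[1]]
  a <- ep$categories == "A"
  # per-point category mean difference, averaged over the grid
  diff <- apply(ep$data[a, , , drop = FALSE], c(2, 3), mean) -
    apply(ep$data[!a, , , drop = FALSE], c(2, 3), mean)
  sem <- sqrt(1 / sum(a) + 1 / sum(!a)) / sqrt(length(diff))
  expect_lt(abs(mean(diff)), 3 * sem)
})

test_that("requested covariate correlation is realized at large n", {
  R <- matrix(c(1, 0.8, 0.8, 1), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  cfg <- sim_config(
    n_subjects = 1, n_trials = 10000, channel_layout = c(1, 2),
    covariate_specs = list(
      list(name = "a", amplitude = 0, channels = "E01", window = c(50, 100)),
      list(name = "b", amplitude = 0, channels = "E02", window = c(50, 100))
    ),
    categorical_effect = list(amplitude = 0, channels = "E01",
                              window = c(300, 380)),
    covariate_correlation = R, noise_sd = 0, seed = 31
  )
  covs <- simulate_dataset(cfg)$truth$covariates[[1]]
  expect_lt(abs(cor(covs$a, covs$b) - 0.8), 0.02)
})

test_that("category-code correlation induces the requested confound", {
  R <- matrix(c(1, 0.6, 0.6, 1), 2, 2,
              dimnames = list(c("v", "category"), c("v", "category")))
  cfg <- sim_config(
    n_subjects = 1, n_trials = 10000,
    covariate_specs = list(list(name = "v", amplitude = 1,
                                channels = "E11", window = c(50, 100))),
    covariate_correlation = R, seed = 32
  )
  sim <- simulate_dataset(cfg)
  r <- cor(sim$truth$covariates[[1]]$v, sim$truth$codes[[1]])
  expect_lt(abs(r - 0.6), 0.03)
})

test_that("joint noiseless simulation is the sum of single-effect runs", {
  base <- function(cat_amp, cov_amp) {
    sim_config(
      n_subjects = 2, n_trials = 20, noise_sd = 0, subject_sd = 0,
      categorical_effect = list(amplitude = cat_amp,
                                channels = c("E01", "E02"),
                                window = c(300, 380)),
      covariate_specs = list(list(name = "v", amplitude = cov_amp,
                                  channels = "E11", window = c(50, 100))),
      seed = 5
    )
  }
  joint <- simulate_dataset(base(1.5, 2))
  cat_only <- simulate_dataset(base(1.5, 0))
  cov_only <- simulate_dataset(base(0, 2))
  for (s in 1:2) {
    expect_equal(joint$epochs[[s]]$data,
                 cat_only$epochs[[s]]$data + cov_only$epochs[[s]]$data,
                 tolerance = 1e-12)
  }
})

test_that("per-subject covariates are z-scored (mean 0, population SD 1)", {
  sim <- simulate_dataset(sim_config(n_subjects = 4, n_trials = 60, seed = 6))
  for (tab in sim$truth$covariates) {
    for (v in tab) {
      expect_lt(abs(mean(v)), 1e-12)
      expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-12)
    }
  }
})

test_that("invalid configurations are rejected", {
  expect_error_class(sim_config(n_trials = 99), "erpsep_config_error")
  bad <- matrix(c(1, 0.9, 0.9, 1), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  bad[1, 2] <- 2  # breaks both symmetry bound and PSD
  bad[2, 1] <- 2
  expect_error_class(
    sim_config(covariate_specs = list(
      list(name = "a", amplitude = 0, channels = "E01", window = c(0, 50)),
      list(name = "b", amplitude = 0, channels = "E01", window = c(0, 50))
    ), covariate_correlation = bad),
    "erpsep_config_error"
  )
  expect_error_class(
    sim_config(time_window = c(500, -200)), "erpsep_config_error"
  )
})

test_that("grid adjacency matches hand enumeration", {
  expect_identical(unname(lengths(grid_neighbours(c(1, 1)))), 0L)

  nb22 <- grid_neighbours(c(2, 2))
  expect_true(all(lengths(nb22) == 3))  # every pair adjacent: 6 pairs
  expect_equal(sum(lengths(nb22)) / 2, 6)  # unique adjacent pairs

  nb33 <- grid_neighbours(c(3, 3))
  expect_identical(length(nb33$E05), 8L)          # centre channel
  expect_identical(sort(nb33$E01), c("E02", "E04", "E05"))  # corner
  # symmetry and irreflexivity
  for (lab in names(nb33)) {
    expect_false(lab %in% nb33[[lab]])
    for (other in nb33[[lab]]) expect_true(lab %in% nb33[[other]])
  }
})
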