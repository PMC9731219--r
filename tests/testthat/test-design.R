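test_that("z-scoring uses the population-SD convention and is idempotent", {
  tab <- data.frame(x = c(1, 2, 3))
  z <- zscore_covariates(tab)
  expect_equal(z$x, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)

  z2 <- zscore_covariates(z)
  expect_equal(z2$x, z$x, tolerance = 1e-12)

  expect_error(zscore_covariates(data.frame(ok = 1:3, flat = c(5, 5, 5))),
               "flat", class = "erpsep_validation_error")
})

test_that("design matrices have the documented layout under both codings", {
  cats <- c("M", "N", "M", "N")
  d <- build_design(cats, NULL, coding = "dummy", levels = c("M", "N"))
  expect_equal(unname(d$matrix[, 1:2]),
               rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1)))
  expect_equal(unname(d$matrix[, 3]), rep(1, 4))
  expect_identical(ncol(d$matrix), 3L)
  expect_identical(d$column_roles, c("category", "category", "constant"))

  s <- build_design(cats, NULL, coding = "signed", levels = c("M", "N"))
  expect_equal(unname(s$matrix[, 1:2]),
               rbind(c(1, -1), c(-1, 1), c(1, -1), c(-1, 1)))

  covs <- zscore_covariates(data.frame(u = rnorm(4), v = rnorm(4)))
  full <- build_design(cats, covs, levels = c("M", "N"))
  expect_identical(full$column_roles,
                   c("category", "category", "covariate", "covariate",
                     "constant"))
  expect_identical(ncol(full$matrix), 5L)

  expect_error_class(build_design(c("A", "A", "A", "A")),
                     "erpsep_validation_error")
  expect_error_class(build_design(c("A", "B", "C", "A")),
                     "erpsep_validation_error")
})

test_that("category-block ranks expose the solver's pseudo-inverse path", {
  cats <- rep(c("M", "N"), 10)
  s <- build_design(cats, NULL, coding = "signed", levels = c("M", "N"))
  d <- build_design(cats, NULL, coding = "dummy", levels = c("M", "N"))
  expect_identical(qr(s$matrix[, 1:2])$rank, 1L)
  expect_identical(qr(d$matrix[, 1:2])$rank, 2L)
  # dummy block + constant is singular: rank 2, not 3
  expect_identical(qr(d$matrix)$rank, 2L)
})

test_that("build_design is invariant under trial permutation round trips", {
  set.seed(8)
  cats <- sample(rep(c("M", "N"), 10))
  covs <- zscore_covariates(data.frame(u = rnorm(20)))
  d <- build_design(cats, covs, levels = c("M", "N"))
  perm <- sample(20)
  dp <- build_design(cats[perm], covs[perm, , drop = FALSE],
                     levels = c("M", "N"))
  expect_equal(unname(dp$matrix[order(perm), ]), unname(d$matrix),
               tolerance = 1e-12)
})

test_that("unscaled covariates are refused", {
  cats <- rep(c("M", "N"), 5)
  expect_error(build_design(cats, data.frame(u = 1:10)), "z-scored",
               class = "erpsep_validation_error")
})

test_that("naive designs keep the category block and randomize covariates", {
  set.seed(3)
  cats <- sample(rep(c("M", "N"), 50))
  covs <- zscore_covariates(as.data.frame(matrix(rnorm(1000), 100, 10)))
  d <- build_design(cats, covs, levels = c("M", "N"))
  nv <- make_naive_design(d, seed = 42)

  is_cat <- d$column_roles %in% c("category", "constant")
  expect_identical(nv$matrix[, is_cat], d$matrix[, is_cat])
  expect_false(any(nv$matrix[, !is_cat] == d$matrix[, !is_cat]))

  # covariate block of a random design has full column rank
  expect_identical(qr(nv$matrix[, nv$column_roles == "covariate"])$rank, 10L)
  # naive covariates are z-scored like real ones
  blk <- nv$matrix[, nv$column_roles == "covariate"]
  expect_lt(max(abs(colMeans(blk))), 1e-12)

  expect_identical(make_naive_design(d, seed = 42)$matrix, nv$matrix)
  expect_false(identical(make_naive_design(d, seed = 43)$matrix, nv$matrix))

  cat_only <- build_design(cats, NULL, levels = c("M", "N"))
  expect_error_class(make_naive_design(cat_only, 1),
                     "erpsep_validation_error")
})

test_that("covariate reduction handles perfect, anti- and zero correlation", {
  set.seed(9)
  x <- rnorm(2000)
  y <- rnorm(2000)

  dup <- reduce_covariates(data.frame(a = x, b = 2 * x + 5),
                           groups = list(g = c("a", "b")))
  expect_equal(unname(dup$explained_variance["g"]), 1.0, tolerance = 1e-12)

  anti <- reduce_covariates(data.frame(a = x, b = -x),
                            groups = list(g = c("a", "b")))
  expect_equal(unname(anti$explained_variance["g"]), 1.0, tolerance = 1e-12)

  indep <- reduce_covariates(data.frame(a = x, b = y),
                             groups = list(g = c("a", "b")))
  expect_lt(abs(indep$explained_variance["g"] - 0.5), 0.05)

  # explained variance never below 1/group_size
  three <- reduce_covariates(data.frame(a = x, b = y, c = rnorm(2000)),
                             groups = list(g = c("a", "b", "c")))
  expect_gte(unname(three$explained_variance["g"]), 1 / 3)

  expect_error_class(
    reduce_covariates(data.frame(a = x, b = y), groups = list(g = "a")),
    "erpsep_validation_error"
  )
  expect_error_class(
    reduce_covariates(data.frame(a = x, b = y), threshold = 1.2),
    "erpsep_validation_error"
  )
})

test_that("threshold grouping is single linkage on the |r| graph", {
  set.seed(10)
  n <- 5000
  a <- rnorm(n)
  b <- 0.65 * a + sqrt(1 - 0.65^2) * rnorm(n)   # |r| ~ 0.65 with a
  c <- -0.65 * b + sqrt(1 - 0.65^2) * rnorm(n)  # links to b only
  d <- rnorm(n)                                 # independent
  expect_lt(abs(cor(a, c)), 0.55)  # chain, not a clique
  red <- reduce_covariates(data.frame(a = a, b = b, c = c, d = d),
                           threshold = 0.55)
  expect_identical(length(red$grouping), 1L)
  expect_setequal(red$grouping[[1]], c("a", "b", "c"))
  expect_true("d" %in% names(red$table))
  # one component column + the pass-through column
  expect_identical(ncol(red$table), 2L)
})
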