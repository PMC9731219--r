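# Shared fixtures and independent oracles for the test suite.

# Small pure-noise subject with k covariates attached.
noise_epochs <- function(n_trials = 100, n_ch = 4, n_t = 30, k = 2,
                         srate = 128, seed = 1) {
  set.seed(seed)
  covs <- NULL
  if (k > 0) {
    covs <- as.data.frame(matrix(rnorm(n_trials * k), n_trials, k))
    names(covs) <- paste0("c", seq_len(k))
  }
  epoched_eeg(
    data = array(rnorm(n_trials * n_ch * n_t), c(n_trials, n_ch, n_t)),
    channel_labels = sprintf("E%02d", seq_len(n_ch)),
    times = seq(0, by = 1000 / srate, length.out = n_t),
    srate = srate,
    categories = rep(c("A", "B"), length.out = n_trials),
    subject_id = "noise", covariates = covs
  )
}

# Design for one subject of a simulated dataset, selecting covariate
# columns by name (NULL = categorical model).
sim_design <- function(epochs, cols = NULL, levels = c("A", "B")) {
  if (is.null(cols)) {
    build_design(epochs$categories, NULL, levels = levels)
  } else {
    z <- zscore_covariates(epochs$covariates)
    build_design(epochs$categories, z[, cols, drop = FALSE], levels = levels)
  }
}

# Independent connected-components oracle: builds the explicit edge
# list of the spatio-temporal graph over masked points and lets igraph
# partition it.
flood_fill_oracle <- function(mask, adj) {
  pts <- which(mask)
  if (length(pts) == 0) return(list())
  n_ch <- nrow(mask)
  coords <- cbind(ch = (pts - 1) %% n_ch + 1, t = (pts - 1) %/% n_ch + 1)
  edges <- NULL
  for (a in seq_along(pts)) {
    for (b in seq_along(pts)) {
      if (a >= b) next
      same_ch <- coords[a, "ch"] == coords[b, "ch"] &&
        abs(coords[a, "t"] - coords[b, "t"]) == 1
      same_t <- coords[a, "t"] == coords[b, "t"] &&
        adj[coords[a, "ch"], coords[b, "ch"]]
      if (same_ch || same_t) edges <- rbind(edges, c(a, b))
    }
  }
  g <- igraph::make_empty_graph(n = length(pts), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  unname(lapply(split(seq_along(pts), comp), function(ix) sort(pts[ix])))
}

# Canonical form of a partition (list of index vectors) for comparison.
canonical_partition <- function(parts) {
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, min, numeric(1)))]
}

expect_error_class <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}

# Four-model pipeline (categorical / psycho / image / psycho-image plus
# naive baselines) on a simulated dataset; reused by the acceptance suite.
fit_four_models <- function(sim, psycho = "p1", image = "i1", n_reps = 8,
                            seed = 50) {
  lv <- sim$truth$config$category_labels
  models <- list(categorical = NULL, psycho = psycho, image = image,
                 psycho_image = c(psycho, image))
  fits <- lapply(names(models), function(nm) {
    lapply(sim$epochs, function(e) {
      fit_glm(e, sim_design(e, models[[nm]], levels = lv), nm)
    })
  })
  names(fits) <- names(models)
  naives <- lapply(c("psycho", "image", "psycho_image"), function(nm) {
    lapply(seq_along(sim$epochs), function(s) {
      naive_baseline(sim$epochs[[s]], fits[[nm]][[s]]$design,
                     n_reps = n_reps, seed = seed + s)
    })
  })
  computed_effects(fits$categorical, fits$psycho, fits$image,
                   fits$psycho_image, naives[[1]], naives[[2]], naives[[3]])
}

two_family_config <- function(correlation = NULL, n_subjects = 6,
                              n_trials = 150, seed = 51) {
  sim_config(
    n_subjects = n_subjects, n_trials = n_trials,
    covariate_specs = list(
      list(name = "p1", amplitude = 1, channels = c("E11", "E12"),
           window = c(50, 100)),
      list(name = "i1", amplitude = 1, channels = c("E15", "E16"),
           window = c(120, 170))
    ),
    covariate_correlation = correlation, seed = seed
  )
}
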