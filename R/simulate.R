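#' Configuration for the synthetic ERP generator
#'
#' Builds and validates the parameter set consumed by
#' [simulate_dataset()].  The defaults describe a desk-scale study: 15
#' subjects, a 4 x 4 synthetic electrode grid (16 channels), 100 trials
#' split evenly between two stimulus categories, epochs from -200 to
#' 500 ms sampled at 128 Hz, one additive categorical effect in a late
#' frontal window and one covariate-driven effect in an early posterior
#' window, with unit-SD Gaussian trial noise.
#'
#' Covariates are drawn from a multivariate normal with the requested
#' correlation structure and then z-scored per subject (population-SD
#' convention), so each covariate enters the signal in units of
#' microvolts per SD.  A row/column of `covariate_correlation` named
#' `"category"` induces a correlation between a covariate and the
#' -1/+1 category code, i.e. a built-in confound.
#'
#' @param n_subjects number of simulated subjects.
#' @param n_trials trials per subject; must be even so the two
#'   categories balance exactly.
#' @param channel_layout integer vector `c(rows, cols)` of the synthetic
#'   electrode grid.  Channels are labelled `E01`, `E02`, ... row-major.
#' @param time_window `c(start_ms, end_ms)` of the epoch.
#' @param srate sampling rate in Hz.
#' @param categorical_effect list with `amplitude` (microvolts, the
#'   voltage added for the +1 category and subtracted for the -1
#'   category), `channels` (labels) and `window` (ms).  Use amplitude 0
#'   for a null categorical effect.
#' @param covariate_specs list of lists, each with `name`, `amplitude`
#'   (microvolts per SD of the covariate), `channels` and `window`.
#' @param covariate_correlation symmetric positive-semidefinite
#'   correlation matrix over the covariate names, optionally including a
#'   `"category"` row/column.
#' @param noise_sd trial-level Gaussian noise SD in microvolts.
#' @param noise_ma width (in samples) of an optional moving-average
#'   kernel applied to the noise along time to mimic ERP
#'   autocorrelation; 1 means white noise.  The smoothed noise is
#'   rescaled so its marginal SD stays `noise_sd`.
#' @param subject_sd SD of the per-subject constant voltage offset.
#' @param effect_shape `"boxcar"` (default) or `"hann"` temporal profile
#'   of the injected effects inside their windows.
#' @param category_labels the two category names; the first label maps
#'   to code +1 and to the first design-matrix column downstream.
#' @param seed integer seed; identical configurations with identical
#'   seeds produce bit-identical datasets.
#'
#' @return an object of class `sim_config`.
#' @seealso [simulate_dataset()], [grid_neighbours()]
#' @export
sim_config <- function(n_subjects = 15,
                       n_trials = 100,
                       channel_layout = c(4, 4),
                       time_window = c(-200, 500),
                       srate = 128,
                       categorical_effect = list(
                         amplitude = 1,
                         channels = c("E01", "E02", "E05", "E06"),
                         window = c(300, 380)
                       ),
                       covariate_specs = list(
                         list(
                           name = "cov1",
                           amplitude = 1,
                           channels = c("E11", "E12", "E15", "E16"),
                           window = c(50, 100)
                         )
                       ),
                       covariate_correlation = NULL,
                       noise_sd = 1,
                       noise_ma = 1,
                       subject_sd = 0.5,
                       effect_shape = c("boxcar", "hann"),
                       category_labels = c("A", "B"),
                       seed = 1) {
  effect_shape <- match.arg(effect_shape)
  stopifnot(
    n_subjects >= 1, n_trials >= 2,
    length(channel_layout) == 2, all(channel_layout >= 1),
    length(time_window) == 2, srate > 0,
    noise_sd >= 0, subject_sd >= 0, noise_ma >= 1,
    length(category_labels) == 2
  )
  if (n_trials %% 2 != 0) {
    stop_typed(
      "n_trials must be even: the two categories must balance exactly",
      "erpsep_config_error"
    )
  }
  if (time_window[1] >= time_window[2]) {
    stop_typed("time_window start must be before end", "erpsep_config_error")
  }

  cov_names <- vapply(covariate_specs, function(s) s$name, character(1))
  if (anyDuplicated(cov_names)) {
    stop_typed("covariate names must be unique", "erpsep_config_error")
  }

  k <- length(cov_names)
  if (is.null(covariate_correlation)) {
    covariate_correlation <- diag(k)
    dimnames(covariate_correlation) <- list(cov_names, cov_names)
  }
  if (k > 0) validate_correlation(covariate_correlation, cov_names)

  n_ch <- prod(channel_layout)
  labels <- sprintf("E%02d", seq_len(n_ch))
  times <- seq(time_window[1], time_window[2], by = 1000 / srate)

  check_spec <- function(spec, what) {
    if (!all(spec$channels %in% labels)) {
      stop_typed(
        sprintf(
          "%s names channels outside the %dx%d layout: %s", what,
          channel_layout[1], channel_layout[2],
          paste(setdiff(spec$channels, labels), collapse = ", ")
        ),
        "erpsep_config_error"
      )
    }
    if (spec$window[1] >= spec$window[2]) {
      stop_typed(paste(what, "window start must be before end"),
                 "erpsep_config_error")
    }
  }
  check_spec(categorical_effect, "categorical_effect")
  for (s in covariate_specs) check_spec(s, paste0("covariate '", s$name, "'"))

  structure(
    list(
      n_subjects = n_subjects, n_trials = n_trials,
      channel_layout = as.integer(channel_layout),
      channel_labels = labels, times = times, srate = srate,
      categorical_effect = categorical_effect,
      covariate_specs = covariate_specs,
      covariate_correlation = covariate_correlation,
      noise_sd = noise_sd, noise_ma = noise_ma, subject_sd = subject_sd,
      effect_shape = effect_shape,
      category_labels = category_labels, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Correlation matrix must be symmetric, unit-diagonal and PSD; its names
# must cover the covariates (plus optionally "category").
validate_correlation <- function(R, cov_names) {
  if (!is.matrix(R) || nrow(R) != ncol(R)) {
    stop_typed("covariate_correlation must be a square matrix",
               "erpsep_config_error")
  }
  nm <- rownames(R)
  if (is.null(nm) || !identical(nm, colnames(R))) {
    stop_typed("covariate_correlation must carry matching row/col names",
               "erpsep_config_error")
  }
  allowed <- c(cov_names, "category")
  if (!all(nm %in% allowed) || !all(cov_names %in% nm)) {
    stop_typed(
      "covariate_correlation names must be the covariate names (plus optionally 'category')",
      "erpsep_config_error"
    )
  }
  if (max(abs(R - t(R))) > 1e-10) {
    stop_typed("covariate_correlation must be symmetric",
               "erpsep_config_error")
  }
  if (max(abs(diag(R) - 1)) > 1e-10) {
    stop_typed("covariate_correlation must have unit diagonal",
               "erpsep_config_error")
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop_typed(
      sprintf("covariate_correlation is not positive semidefinite (min eigenvalue %.3g)",
              min(ev)),
      "erpsep_config_error"
    )
  }
  invisible(R)
}

#' Simulate a multi-subject single-trial ERP dataset with ground truth
#'
#' Each trial's voltage is built additively: a per-subject constant
#' offset, the categorical effect times the trial's -1/+1 category code,
#' each covariate effect times the trial's z-scored covariate value
#' (all confined to their channel subsets and time windows), plus
#' Gaussian noise.  Covariates are drawn jointly from the configured
#' correlation structure -- conditionally on the category code when the
#' correlation matrix includes a `"category"` entry -- and then z-scored
#' within subject.
#'
#' @param config a [sim_config()] object.
#' @return a list with components
#'   \describe{
#'     \item{epochs}{list of [epoched_eeg()] objects, one per subject,
#'       each carrying its covariate table;}
#'     \item{truth}{a `ground_truth` list: `masks` (named channels x
#'       timepoints logical matrices, one per effect), `covariates`
#'       (per-subject z-scored tables), `codes` (per-subject -1/+1
#'       vectors) and the `config`.}
#'   }
#' @examples
#' sim <- simulate_dataset(sim_config(n_subjects = 2, n_trials = 20))
#' dim(sim$epochs[[1]]$data)   # trials x channels x timepoints
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  n_ch <- length(config$channel_labels)
  n_t <- length(config$times)
  n <- config$n_trials
  cov_names <- vapply(config$covariate_specs, function(s) s$name, character(1))
  k <- length(cov_names)

  shapes <- effect_shapes(config)

  half <- n / 2L
  epochs <- vector("list", config$n_subjects)
  truth_cov <- vector("list", config$n_subjects)
  truth_code <- vector("list", config$n_subjects)

  for (s in seq_len(config$n_subjects)) {
    code <- sample(rep(c(1, -1), c(half, half)))
    covs <- draw_covariates(config, code, cov_names)

    signal <- array(0, dim = c(n, n_ch, n_t))
    offset <- stats::rnorm(1, 0, config$subject_sd)
    signal <- signal + offset

    amp <- config$categorical_effect$amplitude
    if (amp != 0) {
      signal <- signal + outer(code * amp, shapes$categorical)
    }
    for (j in seq_along(config$covariate_specs)) {
      a <- config$covariate_specs[[j]]$amplitude
      if (a != 0) {
        signal <- signal + outer(covs[, j] * a, shapes$covariate[[j]])
      }
    }
    if (config$noise_sd > 0) {
      signal <- signal + draw_noise(config, n, n_ch, n_t)
    }

    cov_tab <- as.data.frame(covs)
    names(cov_tab) <- cov_names
    labels <- ifelse(code > 0, config$category_labels[1],
                     config$category_labels[2])
    epochs[[s]] <- epoched_eeg(
      data = signal,
      channel_labels = config$channel_labels,
      times = config$times,
      srate = config$srate,
      categories = labels,
      subject_id = sprintf("sub%02d", s),
      covariates = if (k > 0) cov_tab else NULL
    )
    truth_cov[[s]] <- cov_tab
    truth_code[[s]] <- code
  }

  masks <- c(
    list(categorical = shapes$categorical > 0),
    stats::setNames(lapply(shapes$covariate, function(m) m > 0), cov_names)
  )
  list(
    epochs = epochs,
    truth = structure(
      list(masks = masks, covariates = truth_cov, codes = truth_code,
           config = config),
      class = "ground_truth"
    )
  )
}

# Per-effect channels x timepoints amplitude profile (0 outside the
# window; boxcar or Hann taper inside).
effect_shapes <- function(config) {
  one <- function(spec) {
    m <- matrix(0, length(config$channel_labels), length(config$times),
                dimnames = list(config$channel_labels, NULL))
    tsel <- which(config$times >= spec$window[1] &
                    config$times <= spec$window[2])
    prof <- if (config$effect_shape == "hann" && length(tsel) > 1) {
      0.5 * (1 - cos(2 * pi * (seq_along(tsel) - 1) / (length(tsel) - 1)))
    } else {
      rep(1, length(tsel))
    }
    m[spec$channels, tsel] <- rep(prof, each = length(spec$channels))
    m
  }
  list(
    categorical = one(config$categorical_effect),
    covariate = lapply(config$covariate_specs, one)
  )
}

# Draw the covariate block for one subject.  When the correlation matrix
# has a "category" entry the covariates are drawn conditionally on the
# (fixed, balanced) -1/+1 code so their correlation with the code matches
# the requested value.  Columns are z-scored afterwards.
draw_covariates <- function(config, code, cov_names) {
  k <- length(cov_names)
  if (k == 0) {
    return(matrix(numeric(0), length(code), 0))
  }
  R <- config$covariate_correlation
  n <- length(code)
  if ("category" %in% rownames(R)) {
    r <- R[cov_names, "category"]
    S <- R[cov_names, cov_names, drop = FALSE] - tcrossprod(r)
    mu <- outer(code, r)
  } else {
    S <- R[cov_names, cov_names, drop = FALSE]
    mu <- matrix(0, n, k)
  }
  eps <- MASS::mvrnorm(n, mu = rep(0, k), Sigma = S, tol = 1e-6)
  covs <- mu + matrix(eps, n, k)
  apply(covs, 2, zscore_vec)
}

# Trial noise: iid Gaussian, optionally smoothed along time with a
# moving-average kernel and rescaled to keep the marginal SD.
draw_noise <- function(config, n, n_ch, n_t) {
  eps <- array(stats::rnorm(n * n_ch * n_t, 0, config$noise_sd),
               dim = c(n, n_ch, n_t))
  w <- round(config$noise_ma)
  if (w > 1) {
    kern <- rep(1 / w, w)
    flat <- matrix(aperm(eps, c(3, 1, 2)), n_t, n * n_ch)
    sm <- apply(flat, 2, function(x) {
      y <- stats::filter(x, kern, sides = 2)
      y[is.na(y)] <- x[is.na(y)]
      y
    })
    eps <- aperm(array(sm * sqrt(w), dim = c(n_t, n, n_ch)), c(2, 3, 1))
  }
  eps
}

#' Channel adjacency for a rectangular electrode grid
#'
#' Two channels are neighbours iff their grid positions differ by at
#' most 1 in each coordinate (8-connectivity).  The adjacency is
#' symmetric and irreflexive.
#'
#' @param channel_layout integer vector `c(rows, cols)`.
#' @return a `channel_neighbours` object: a named list mapping each
#'   channel label to the character vector of its neighbours.
#' @examples
#' nb <- grid_neighbours(c(3, 3))
#' length(nb$E05)  # centre channel of a 3x3 grid has 8 neighbours
#' @export
grid_neighbours <- function(channel_layout) {
  stopifnot(length(channel_layout) == 2, all(channel_layout >= 1))
  nr <- channel_layout[1]
  nc <- channel_layout[2]
  n <- nr * nc
  labels <- sprintf("E%02d", seq_len(n))
  row <- (seq_len(n) - 1) %/% nc + 1
  col <- (seq_len(n) - 1) %% nc + 1
  adj <- lapply(seq_len(n), function(i) {
    near <- abs(row - row[i]) <= 1 & abs(col - col[i]) <= 1
    near[i] <- FALSE
    labels[near]
  })
  names(adj) <- labels
  structure(adj, class = "channel_neighbours")
}

# Dense logical adjacency matrix in the order of `labels`; channels the
# neighbour structure does not mention have no spatial neighbours.
neighbours_matrix <- function(neighbours, labels) {
  n <- length(labels)
  A <- matrix(FALSE, n, n, dimnames = list(labels, labels))
  if (is.null(neighbours)) {
    return(A)
  }
  unknown <- setdiff(names(neighbours), labels)
  if (length(unknown) > 0) {
    stop_typed(
      sprintf("adjacency names channels absent from the data: %s",
              paste(unknown, collapse = ", ")),
      "erpsep_validation_error"
    )
  }
  for (lab in names(neighbours)) {
    nb <- intersect(neighbours[[lab]], labels)
    A[lab, nb] <- TRUE
    A[nb, lab] <- TRUE
  }
  diag(A) <- FALSE
  A
}
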