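#' Per-subject mass-univariate OLS over channels x timepoints
#'
#' Fits the linear model `ERP = X beta + eps` independently at every
#' channel/timepoint, with all trials entering one least-squares solve
#' per point.  Implemented as a single minimum-norm pseudo-inverse of
#' the design applied to all channel x time responses at once, which is
#' mathematically identical to the per-point solves but far cheaper.
#' Rank-deficient designs (e.g. dummy coding plus constant) yield the
#' minimum-norm solution; fitted values and R-squared are unaffected by
#' the choice of generalized inverse.
#'
#' R-squared is `1 - SS_res / SS_tot` with `SS_tot` taken about the
#' across-trial mean, so the constant column itself contributes 0.
#' Points whose voltage is identical on every trial (SS_tot = 0, only
#' possible in noiseless synthetic data) get R-squared 0.
#'
#' @param epochs an [epoched_eeg()] object.
#' @param design a [build_design()] result with rows matching the
#'   trials.  At least `ncol + 1` trials are required: with as many
#'   parameters as observations the fit interpolates noise.
#' @param model_name label stored with the fit (e.g. `"categorical"`,
#'   `"psycho"`).
#' @return a `first_level_fit`: list with `betas` (channels x
#'   timepoints x columns), `r2` (channels x timepoints), `model_name`,
#'   `design`, `channel_labels`, `times`, `subject_id`.
#' @export
fit_glm <- function(epochs, design, model_name = "model") {
  stopifnot(inherits(epochs, "epoched_eeg"), inherits(design, "design_matrix"))
  X <- design$matrix
  d <- dim(epochs$data)
  if (nrow(X) != d[1]) {
    stop_typed("design rows do not match the epoch trial count",
               "erpsep_consistency_error")
  }
  if (d[1] <= ncol(X)) {
    stop_typed(
      sprintf(
        "refusing to fit: %d trials for %d design columns; more parameters than observations overfits (need >= %d trials)",
        d[1], ncol(X), ncol(X) + 1
      ),
      "erpsep_validation_error"
    )
  }
  if (any(!is.finite(epochs$data))) {
    stop_typed("epochs contain non-finite voltages", "erpsep_validation_error")
  }

  n_pts <- d[2] * d[3]
  Y <- matrix(epochs$data, d[1], n_pts)   # trials x (channel-major points)
  P <- pseudo_inverse(X)
  B <- P %*% Y                            # columns x points
  fitted <- X %*% B
  res <- Y - fitted
  mu <- colMeans(Y)
  ss_tot <- colSums(Y^2) - d[1] * mu^2
  ss_res <- colSums(res^2)
  r2 <- ifelse(ss_tot > 0, pmax(0, 1 - ss_res / ss_tot), 0)

  betas <- aperm(array(t(B), dim = c(d[2], d[3], ncol(X))), c(1, 2, 3))
  dimnames(betas) <- list(epochs$channel_labels, NULL, design$column_names)
  r2 <- matrix(r2, d[2], d[3], dimnames = list(epochs$channel_labels, NULL))

  structure(
    list(betas = betas, r2 = r2, model_name = model_name, design = design,
         channel_labels = epochs$channel_labels, times = epochs$times,
         subject_id = epochs$subject_id),
    class = "first_level_fit"
  )
}

#' @export
print.first_level_fit <- function(x, ...) {
  cat(sprintf(
    "first_level_fit '%s' (%s): %d channels x %d timepoints, %d predictors, max R2 = %.3f\n",
    x$model_name, x$subject_id, nrow(x$r2), ncol(x$r2),
    dim(x$betas)[3], max(x$r2)
  ))
  invisible(x)
}

#' Categorical contrast map from a first-level fit
#'
#' The contrast is the elementwise difference between the two category
#' beta maps, first column minus second (e.g. manufactured minus
#' natural), per channel and timepoint.
#'
#' @param fit a `first_level_fit` whose design has two category columns.
#' @return a `contrast_map`: list with `values` (channels x timepoints),
#'   `channel_labels`, `times`, `subject_id`.
#' @export
compute_contrast <- function(fit) {
  stopifnot(inherits(fit, "first_level_fit"))
  idx <- which(fit$design$column_roles == "category")
  if (length(idx) != 2) {
    stop_typed("fit's design does not carry two category columns",
               "erpsep_validation_error")
  }
  structure(
    list(values = fit$betas[, , idx[1]] - fit$betas[, , idx[2]],
         channel_labels = fit$channel_labels, times = fit$times,
         subject_id = fit$subject_id),
    class = "contrast_map"
  )
}

#' Naive-model baseline: repetition-averaged fits with random covariates
#'
#' Repeatedly replaces the design's covariate columns with random
#' standard-normal vectors ([make_naive_design()]), refits, and averages
#' the R-squared maps and the category betas over repetitions.  The
#' averaged R-squared estimates how much explained variance the model
#' gains from its dimensionality alone, and is subtracted from the real
#' model's R-squared before any covariate-effect inference.
#'
#' @param epochs an `epoched_eeg`.
#' @param design a design with >= 1 covariate column.
#' @param n_reps number of naive repetitions (default 30).
#' @param seed integer seed; repetition seeds are derived
#'   deterministically from it.
#' @return a `naive_baseline`: list with `mean_r2` (channels x
#'   timepoints), `mean_category_betas` (channels x timepoints x 2),
#'   `n_reps`, `seeds`, `model_name`.
#' @export
naive_baseline <- function(epochs, design, n_reps = 30, seed = 1) {
  stopifnot(n_reps >= 1)
  if (n_covariates(design) == 0) {
    stop_typed("design has no covariates: nothing to replace in a naive model",
               "erpsep_validation_error")
  }
  seeds <- derive_seeds(seed, n_reps)
  cat_idx <- which(design$column_roles == "category")
  sum_r2 <- 0
  sum_betas <- 0
  for (r in seq_len(n_reps)) {
    fit <- fit_glm(epochs, make_naive_design(design, seeds[r]),
                   model_name = "naive")
    sum_r2 <- sum_r2 + fit$r2
    sum_betas <- sum_betas + fit$betas[, , cat_idx, drop = FALSE]
  }
  structure(
    list(mean_r2 = sum_r2 / n_reps,
         mean_category_betas = sum_betas / n_reps,
         n_reps = n_reps, seeds = seeds,
         model_name = paste0("naive_", design$coding),
         channel_labels = epochs$channel_labels, times = epochs$times,
         subject_id = epochs$subject_id),
    class = "naive_baseline"
  )
}
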