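#' R-squared excess of a model over its naive baseline
#'
#' Elementwise difference between a first-level fit's R-squared map and
#' the repetition-averaged R-squared of the matching naive model.  The
#' excess isolates the explained variance attributable to the real
#' covariate values (dimensionality cancels, because the naive model
#' has the same rank); stacks of these maps feed
#' [bootstrap_cluster_test()] to localize covariate influence.
#'
#' @param fit a `first_level_fit` whose design carries >= 1 covariate
#'   column, or a plain channels x timepoints R-squared matrix.
#' @param naive the matching [naive_baseline()], or a plain matrix.
#' @return channels x timepoints matrix of differences (may be
#'   negative).
#' @export
r2_excess <- function(fit, naive) {
  r2 <- if (inherits(fit, "first_level_fit")) {
    if (n_covariates(fit$design) == 0) {
      stop_typed(
        "the categorical model has no covariates; its naive excess is undefined",
        "erpsep_validation_error"
      )
    }
    fit$r2
  } else {
    as.matrix(fit)
  }
  base <- if (inherits(naive, "naive_baseline")) naive$mean_r2 else
    as.matrix(naive)
  if (!identical(dim(r2), dim(base))) {
    stop_typed("model and naive R-squared maps differ in shape",
               "erpsep_consistency_error")
  }
  r2 - base
}

#' Explained-variance decomposition across the four models
#'
#' Given per-subject R-squared maps for the categorical, psycho, image
#' and psycho-image models plus the naive baselines of the three
#' covariate models, computes, per subject and channel/timepoint, the
#' decomposition of explained variance into categorical and covariate
#' contributions.
#'
#' Each covariate model's R-squared is first corrected for
#' dimensionality: its naive mean is subtracted and the categorical
#' model's R-squared added back (the naive model carries the same
#' category columns, so the naive mean equals the categorical
#' R-squared plus the pure dimensionality inflation).  On the
#' corrected maps `model_*` the decomposition reads:
#'
#' * `computed_psycho = model_psycho_image - model_image`: the part of
#'   the psycho-covariate effect orthogonal to the categories;
#' * `computed_categorical_psycho = model_psycho - computed_psycho`:
#'   the categorical effect reconstructed through the psycho family;
#' * `r2_loss_psycho = e_categorical - computed_categorical_psycho`:
#'   explained variance lost in the reconstruction -- zero when the
#'   three effects are mutually orthogonal, negative when the two
#'   covariate families share variance;
#'
#' plus the mirrored image-family version (psycho and image swapped).
#' Negative values are legitimate and preserved.
#'
#' @param r2_categorical list of per-subject channels x timepoints
#'   R-squared maps of the categorical (covariate-free) model.
#' @param r2_psycho,r2_image,r2_psycho_image per-subject maps of the
#'   covariate models.
#' @param naive_psycho,naive_image,naive_psycho_image per-subject
#'   [naive_baseline()] objects (or mean-R-squared matrices) matching
#'   each covariate model.
#' @return an `r2_decomposition`: list of subjects x channels x
#'   timepoints arrays -- raw `e_categorical`; covariate-only excesses
#'   `excess_psycho`, `excess_image`, `excess_psycho_image` (model
#'   minus naive, the maps fed to the covariate-influence cluster
#'   test); dimensionality-corrected `model_psycho`, `model_image`,
#'   `model_psycho_image`; and the derived `computed_psycho`,
#'   `computed_image`, `computed_categorical_psycho`,
#'   `computed_categorical_image`, `r2_loss_psycho`, `r2_loss_image`.
#' @export
computed_effects <- function(r2_categorical, r2_psycho, r2_image,
                             r2_psycho_image,
                             naive_psycho, naive_image, naive_psycho_image) {
  inputs <- list(
    r2_categorical = r2_categorical, r2_psycho = r2_psycho,
    r2_image = r2_image, r2_psycho_image = r2_psycho_image
  )
  missing <- names(inputs)[vapply(inputs, is.null, logical(1))]
  if (length(missing) > 0) {
    stop_typed(sprintf("missing model fits: %s",
                       paste(missing, collapse = ", ")),
               "erpsep_validation_error")
  }
  n_subj <- length(r2_categorical)
  if (!all(lengths(inputs) == n_subj)) {
    stop_typed("all four models must cover the same subjects",
               "erpsep_consistency_error")
  }
  as_map <- function(x) {
    if (inherits(x, "first_level_fit")) x$r2
    else if (inherits(x, "naive_baseline")) x$mean_r2
    else as.matrix(x)
  }
  to_stack <- function(maps) stack_maps(lapply(maps, as_map))

  e_cat <- to_stack(r2_categorical)
  excess_psy <- to_stack(r2_psycho) - to_stack(naive_psycho)
  excess_img <- to_stack(r2_image) - to_stack(naive_image)
  excess_pi <- to_stack(r2_psycho_image) - to_stack(naive_psycho_image)

  # dimensionality-corrected model R2: naive mean = categorical R2 +
  # pure dimensionality inflation, so model - naive + categorical
  # removes the inflation while keeping the categorical contribution
  model_psy <- excess_psy + e_cat
  model_img <- excess_img + e_cat
  model_pi <- excess_pi + e_cat

  computed_psycho <- model_pi - model_img
  computed_image <- model_pi - model_psy
  computed_cat_psy <- model_psy - computed_psycho
  computed_cat_img <- model_img - computed_image

  structure(
    list(
      e_categorical = e_cat,
      excess_psycho = excess_psy, excess_image = excess_img,
      excess_psycho_image = excess_pi,
      model_psycho = model_psy, model_image = model_img,
      model_psycho_image = model_pi,
      computed_psycho = computed_psycho,
      computed_image = computed_image,
      computed_categorical_psycho = computed_cat_psy,
      computed_categorical_image = computed_cat_img,
      r2_loss_psycho = e_cat - computed_cat_psy,
      r2_loss_image = e_cat - computed_cat_img,
      channel_labels = attr(e_cat, "channel_labels"),
      times = attr(e_cat, "times")
    ),
    class = "r2_decomposition"
  )
}

#' Summarize a per-subject map over a region of interest
#'
#' Averages each subject's map over the ROI members, then reports the
#' across-subject 20%-trimmed mean with a percentile-bootstrap 95%
#' confidence interval (resampling subjects) and the interquartile
#' range of the per-subject values.
#'
#' @param stack subjects x channels x timepoints array (or list of
#'   matrices, see [stack_maps()]).
#' @param roi logical channels x timepoints mask, or integer grid
#'   indices (column-major, channel fastest), or a cluster record from
#'   [form_clusters()].
#' @param trim trimming fraction of the across-subject mean.
#' @param n_ci_boot bootstrap resamples for the CI (default 1000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return a `roi_summary`: list with `per_subject`, `estimate`
#'   (trimmed mean), `ci` (length 2), `iqr` (length 2), `n_points`.
#' @export
roi_summary <- function(stack, roi, trim = 0.2, n_ci_boot = 1000, seed = 1,
                        conf = 0.95) {
  if (is.list(stack) && !is.array(stack)) stack <- stack_maps(stack)
  d <- dim(stack)
  if (d[1] < 3) {
    stop_typed("need at least 3 subjects for a ROI summary",
               "erpsep_validation_error")
  }
  idx <- roi_indices(roi, d[2], d[3])
  if (length(idx) == 0) {
    stop_typed("ROI is empty", "erpsep_validation_error")
  }
  Xm <- matrix(stack, d[1], d[2] * d[3])
  per_subject <- rowMeans(Xm[, idx, drop = FALSE])
  est <- trimmed_mean(per_subject, trim)
  set.seed(as.integer(seed))
  boot <- vapply(seq_len(n_ci_boot), function(b) {
    trimmed_mean(sample(per_subject, replace = TRUE), trim)
  }, numeric(1))
  a <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(a, 1 - a), type = 6))
  structure(
    list(per_subject = per_subject, estimate = est, ci = ci,
         iqr = unname(stats::quantile(per_subject, c(0.25, 0.75))),
         n_points = length(idx), trim = trim, n_ci_boot = n_ci_boot,
         conf = conf),
    class = "roi_summary"
  )
}

roi_indices <- function(roi, n_ch, n_t) {
  if (is.list(roi) && !is.null(roi$member_idx)) {
    return(roi$member_idx)
  }
  if (is.logical(roi)) {
    if (!identical(dim(roi), c(n_ch, n_t))) {
      stop_typed("ROI mask shape does not match the maps",
                 "erpsep_consistency_error")
    }
    return(which(roi))
  }
  idx <- as.integer(roi)
  if (any(idx < 1 | idx > n_ch * n_t)) {
    stop_typed("ROI indices outside the channel x time grid",
               "erpsep_validation_error")
  }
  idx
}

#' Separability verdict from two confidence intervals
#'
#' The categorical and covariate effects are declared `"separable"`
#' when the R-squared-loss CI lies entirely below the categorical-model
#' CI (loss upper bound < categorical lower bound): the loss is then
#' significantly lower than the categorical explained variance.  The
#' verdict is `"not separable"` when the loss CI reaches at least as
#' high as the categorical CI (its lower bound at or above the
#' categorical lower bound, or its upper bound at or above the
#' categorical upper bound).  Anything in between -- a loss CI that
#' merely grazes the categorical CI from below -- is `"inconclusive"`.
#'
#' @param categorical_ci length-2 numeric, CI of the categorical-model
#'   R-squared on the ROI.
#' @param loss_ci length-2 numeric, CI of the R-squared loss on the
#'   same ROI.
#' @return `"separable"`, `"not separable"` or `"inconclusive"`.
#' @export
separability_verdict <- function(categorical_ci, loss_ci) {
  stopifnot(length(categorical_ci) == 2, length(loss_ci) == 2,
            categorical_ci[1] <= categorical_ci[2],
            loss_ci[1] <= loss_ci[2])
  if (loss_ci[2] < categorical_ci[1]) {
    "separable"
  } else if (loss_ci[1] >= categorical_ci[1] ||
             loss_ci[2] >= categorical_ci[2]) {
    "not separable"
  } else {
    "inconclusive"
  }
}

#' Overlap between categorical and covariate clusters; unbiased ROI
#'
#' For every categorical-contrast cluster, reports the fraction of its
#' members lying inside any covariate-influence cluster, and derives
#' the "unbiased ROI": the categorical members minus all covariate
#' members -- the region a classifier may use without exploiting
#' covariate information.  An empty unbiased ROI is flagged with a
#' warning.
#'
#' @param categorical_clusters,covariate_clusters cluster-record lists
#'   from [form_clusters()] / [bootstrap_cluster_test()], over one
#'   channels x timepoints grid.
#' @param n_ch,n_t grid dimensions (only needed for the index
#'   bookkeeping when clusters carry no `member_idx`).
#' @return list with `overlap` (data.frame: cluster id, n_members,
#'   n_overlapping, fraction) and `unbiased_roi` (sorted grid indices).
#' @export
overlap_report <- function(categorical_clusters, covariate_clusters,
                           n_ch = NULL, n_t = NULL) {
  cov_members <- sort(unique(unlist(
    lapply(covariate_clusters, function(cl) cl$member_idx)
  )))
  rows <- lapply(seq_along(categorical_clusters), function(i) {
    m <- categorical_clusters[[i]]$member_idx
    ov <- sum(m %in% cov_members)
    data.frame(cluster = i, n_members = length(m), n_overlapping = ov,
               fraction = if (length(m) > 0) ov / length(m) else 0)
  })
  cat_members <- sort(unique(unlist(
    lapply(categorical_clusters, function(cl) cl$member_idx)
  )))
  unbiased <- setdiff(cat_members, cov_members)
  if (length(cat_members) > 0 && length(unbiased) == 0) {
    warn_typed(
      "every categorical-cluster point overlaps a covariate cluster: the unbiased ROI is empty",
      "erpsep_empty_roi"
    )
  }
  list(
    overlap = if (length(rows) > 0) do.call(rbind, rows) else
      data.frame(cluster = integer(0), n_members = integer(0),
                 n_overlapping = integer(0), fraction = numeric(0)),
    unbiased_roi = unbiased
  )
}

#' Full separability report on one region of interest
#'
#' Convenience wrapper: summarizes the categorical-model explained
#' variance and each family's R-squared loss over a ROI
#' ([roi_summary()]), renders the verdict ([separability_verdict()]),
#' and attaches a secondary robust check -- a Yuen paired-difference
#' test of (categorical - loss) across subjects.
#'
#' @param decomp an [computed_effects()] result.
#' @param roi ROI specification (see [roi_summary()]).
#' @param families which loss families to report, subset of
#'   `c("psycho", "image")`.
#' @param trim,n_ci_boot,seed passed to [roi_summary()].
#' @return a `separability_report`: per family, the categorical CI,
#'   loss CI, verdict, and the Yuen test of the paired difference.
#' @export
separability_report <- function(decomp, roi,
                                families = c("psycho", "image"),
                                trim = 0.2, n_ci_boot = 1000, seed = 1) {
  stopifnot(inherits(decomp, "r2_decomposition"))
  families <- match.arg(families, several.ok = TRUE)
  cat_sum <- roi_summary(decomp$e_categorical, roi, trim = trim,
                         n_ci_boot = n_ci_boot, seed = seed)
  out <- list()
  for (fam in families) {
    loss_stack <- decomp[[paste0("r2_loss_", fam)]]
    loss_sum <- roi_summary(loss_stack, roi, trim = trim,
                            n_ci_boot = n_ci_boot, seed = seed + 1)
    diff <- cat_sum$per_subject - loss_sum$per_subject
    yuen <- tryCatch(yuen_t_one_sample(diff, trim = trim),
                     error = function(e) NULL)
    out[[fam]] <- list(
      categorical = cat_sum, loss = loss_sum,
      verdict = separability_verdict(cat_sum$ci, loss_sum$ci),
      paired_yuen = yuen
    )
  }
  structure(out, class = "separability_report")
}

#' @export
print.separability_report <- function(x, ...) {
  for (fam in names(x)) {
    r <- x[[fam]]
    cat(sprintf(
      "%s family: categorical R2 CI [%.4f, %.4f], loss CI [%.4f, %.4f] -> %s\n",
      fam, r$categorical$ci[1], r$categorical$ci[2],
      r$loss$ci[1], r$loss$ci[2], r$verdict
    ))
  }
  invisible(x)
}
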