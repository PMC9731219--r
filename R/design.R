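#' Z-score covariate columns (population-SD convention)
#'
#' Each column is centred and scaled to unit SD over the subject's
#' trials, using the population SD (divisor n).  Covariates enter the
#' design matrix in these units so betas read as microvolts per SD.
#'
#' @param table data.frame of numeric covariate columns.
#' @return data.frame of the same shape with every column mean 0, SD 1.
#' @export
zscore_covariates <- function(table) {
  table <- as.data.frame(table)
  for (j in seq_along(table)) {
    if (!is.numeric(table[[j]])) {
      stop_typed(sprintf("column '%s' is not numeric", names(table)[j]),
                 "erpsep_validation_error")
    }
    s <- stats::sd(table[[j]]) * sqrt((nrow(table) - 1) / nrow(table))
    if (is.na(s) || s == 0) {
      stop_typed(
        sprintf("column '%s' is constant and cannot be z-scored",
                names(table)[j]),
        "erpsep_validation_error"
      )
    }
    table[[j]] <- (table[[j]] - mean(table[[j]])) / s
  }
  table
}

#' Reduce correlated covariates to principal-component summaries
#'
#' Groups of strongly correlated covariates are replaced by the first
#' principal component of their z-scored values, mirroring the common
#' practice of collapsing near-duplicate stimulus descriptors (e.g. two
#' word-frequency norms) into one dimension before regression.  Within
#' each group, members anti-correlated with the first member are sign
#' flipped before the PCA so the component has a consistent
#' orientation.  Ungrouped covariates pass through unchanged.
#'
#' Groups are given explicitly, or discovered from a correlation
#' threshold: the groups are then the connected components (single
#' linkage) of the graph joining covariate pairs with `|r| >=
#' threshold`; components of size 1 pass through.
#'
#' @param table data.frame of numeric covariates.
#' @param groups named list of character vectors (group name ->
#'   member column names); groups must be disjoint and have >= 2
#'   members.
#' @param threshold alternative to `groups`: absolute-correlation
#'   threshold in (0, 1).  Default 0.55.
#' @return a `reduced_covariates` object: list with `table` (reduced
#'   data.frame), `grouping` (group -> members), `explained_variance`
#'   (per group, fraction in (0, 1]) and `loadings` (per group).
#' @export
reduce_covariates <- function(table, groups = NULL, threshold = 0.55) {
  table <- as.data.frame(table)
  nm <- names(table)
  if (is.null(groups)) {
    if (threshold <= 0 || threshold >= 1) {
      stop_typed("threshold must lie strictly between 0 and 1",
                 "erpsep_validation_error")
    }
    groups <- threshold_groups(table, threshold)
  } else {
    members <- unlist(groups, use.names = FALSE)
    if (anyDuplicated(members)) {
      stop_typed("groups must be disjoint", "erpsep_validation_error")
    }
    if (!all(members %in% nm)) {
      stop_typed(
        sprintf("unknown covariates in groups: %s",
                paste(setdiff(members, nm), collapse = ", ")),
        "erpsep_validation_error"
      )
    }
    if (any(lengths(groups) < 2)) {
      stop_typed("singleton groups cannot be reduced", "erpsep_validation_error")
    }
    if (is.null(names(groups)) || any(names(groups) == "")) {
      names(groups) <- vapply(groups, function(g) paste(g, collapse = "+"),
                              character(1))
    }
  }

  grouped <- unlist(groups, use.names = FALSE)
  keep <- setdiff(nm, grouped)
  out <- table[, keep, drop = FALSE]
  ev <- numeric(0)
  loadings <- list()
  for (g in names(groups)) {
    z <- as.matrix(zscore_covariates(table[, groups[[g]], drop = FALSE]))
    # align signs to the first member so anti-correlated descriptors
    # point the same way before extracting the component
    flip <- sign(stats::cor(z)[1, ])
    flip[flip == 0] <- 1
    z <- sweep(z, 2, flip, `*`)
    pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
    ev[g] <- pc$sdev[1]^2 / sum(pc$sdev^2)
    ld <- pc$rotation[, 1] * flip
    names(ld) <- groups[[g]]
    loadings[[g]] <- ld
    out[[g]] <- pc$x[, 1]
  }
  structure(
    list(table = out, grouping = groups, explained_variance = ev,
         loadings = loadings),
    class = "reduced_covariates"
  )
}

# Maximal groups where every member has |r| >= threshold with at least
# one other member: connected components of the thresholded |r| graph.
threshold_groups <- function(table, threshold) {
  nm <- names(table)
  p <- length(nm)
  if (p < 2) {
    return(stats::setNames(list(), character(0)))
  }
  A <- abs(stats::cor(as.matrix(table))) >= threshold
  diag(A) <- FALSE
  comp <- rep(NA_integer_, p)
  cid <- 0L
  for (i in seq_len(p)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    comp[i] <- cid
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(A[v, ] & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  groups <- split(nm, comp)
  groups <- groups[lengths(groups) >= 2]
  stats::setNames(groups,
                  vapply(groups, function(g) paste(g, collapse = "+"),
                         character(1)))
}

#' Build a trials x predictors design matrix
#'
#' Columns are ordered `[category1, category2, covariates..., constant]`.
#' Under `"signed"` coding a trial carries +1 in its own category column
#' and -1 in the other; under `"dummy"` coding 1 and 0.  The first
#' category level (of `levels`, or alphabetical) maps to the first
#' column.  Covariates must already be z-scored (see
#' [zscore_covariates()]); the constant column of ones absorbs the
#' subject's mean response.
#'
#' Note the dummy-coded category block plus the constant is rank
#' deficient by construction; the first-level solver handles this with
#' a minimum-norm pseudo-inverse.
#'
#' @param categories per-trial category labels with exactly two levels.
#' @param covariates optional data.frame of z-scored covariates.
#' @param coding `"signed"` (-1/+1, default) or `"dummy"` (0/1).
#' @param levels optional length-2 character vector fixing which
#'   category maps to the first column.
#' @return a `design_matrix` object: list with `matrix`, `column_names`,
#'   `column_roles` (`"category"`, `"covariate"`, `"constant"`),
#'   `coding` and `category_levels`.
#' @export
build_design <- function(categories, covariates = NULL,
                         coding = c("signed", "dummy"), levels = NULL) {
  coding <- match.arg(coding)
  categories <- as.character(categories)
  lev <- levels %||% sort(unique(categories))
  if (length(unique(categories)) != 2 || length(lev) != 2 ||
      !all(categories %in% lev)) {
    stop_typed("categories must take exactly two levels",
               "erpsep_validation_error")
  }
  n <- length(categories)
  own <- categories == lev[1]
  if (coding == "signed") {
    cat_block <- cbind(ifelse(own, 1, -1), ifelse(own, -1, 1))
  } else {
    cat_block <- cbind(as.numeric(own), as.numeric(!own))
  }
  colnames(cat_block) <- paste0("cat_", lev)

  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) {
      stop_typed("covariate rows do not match the trial count",
                 "erpsep_consistency_error")
    }
    cm <- as.matrix(covariates)
    if (ncol(cm) > 0) {
      mu <- colMeans(cm)
      sdev <- sqrt(colMeans(sweep(cm, 2, mu)^2))
      if (any(abs(mu) > 1e-6) || any(abs(sdev - 1) > 1e-6)) {
        stop_typed(
          "covariates must be z-scored (mean 0, SD 1) before entering the design; call zscore_covariates()",
          "erpsep_validation_error"
        )
      }
    }
  } else {
    cm <- matrix(numeric(0), n, 0)
  }

  X <- cbind(cat_block, cm, constant = 1)
  roles <- c("category", "category",
             rep("covariate", ncol(cm)), "constant")
  structure(
    list(matrix = X, column_names = colnames(X), column_roles = roles,
         coding = coding, category_levels = lev),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix: %d trials x %d columns (%s coding)\n",
              nrow(x$matrix), ncol(x$matrix), x$coding))
  cat(sprintf("roles: %s\n", paste(x$column_roles, collapse = ", ")))
  invisible(x)
}

n_covariates <- function(design) sum(design$column_roles == "covariate")

#' Replace a design's covariates by random vectors ("naive" design)
#'
#' The category and constant columns are copied verbatim -- the naive
#' model keeps the same category for each trial -- while every covariate
#' column is replaced by an independent standard-normal draw of matched
#' rank (identity covariance), then z-scored like a real covariate.
#' Fitting naive designs quantifies how much R-squared a model gains
#' purely from its dimensionality.
#'
#' @param design a [build_design()] result with >= 1 covariate column.
#' @param seed integer seed; identical seeds give identical draws.
#' @return a `design_matrix` with the same shape, names and roles.
#' @export
make_naive_design <- function(design, seed) {
  stopifnot(inherits(design, "design_matrix"))
  k <- n_covariates(design)
  if (k == 0) {
    stop_typed(
      "design has no covariate columns: the naive model is undefined for the categorical model",
      "erpsep_validation_error"
    )
  }
  n <- nrow(design$matrix)
  set.seed(as.integer(seed))
  draws <- matrix(stats::rnorm(n * k), n, k)
  draws <- apply(draws, 2, zscore_vec)
  out <- design
  out$matrix[, design$column_roles == "covariate"] <- draws
  out
}

#' Export a design matrix as delimited text for audit
#'
#' Writes the matrix with a first header row of column names and a
#' second header row of column roles.
#'
#' @param design a `design_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_design <- function(design, path) {
  stopifnot(inherits(design, "design_matrix"))
  lines <- c(
    paste(design$column_names, collapse = "\t"),
    paste(design$column_roles, collapse = "\t"),
    apply(design$matrix, 1, function(r) {
      paste(sprintf("%.17g", r), collapse = "\t")
    })
  )
  writeLines(lines, path)
  invisible(path)
}
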