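#' Trimmed mean
#'
#' Mean after removing the `floor(trim * n)` smallest and largest
#' values (stable sort, so ties are kept in input order).  The default
#' 20% trim is the robust-location convention used throughout the
#' second-level inference.
#'
#' @param values numeric vector.
#' @param trim trimming fraction per tail, in `[0, 0.5)`.
#' @return the trimmed mean (scalar).
#' @examples
#' trimmed_mean(1:10, 0.2)  # drops {1,2,9,10} -> 5.5
#' @export
trimmed_mean <- function(values, trim = 0.2) {
  stopifnot(is.numeric(values), length(values) >= 1)
  if (trim < 0 || trim >= 0.5) {
    stop_typed("trim must lie in [0, 0.5)", "erpsep_validation_error")
  }
  n <- length(values)
  g <- floor(trim * n)
  if (n - 2 * g < 1) {
    stop_typed("trimming removes every value", "erpsep_validation_error")
  }
  s <- sort(values, method = "radix")
  mean(s[(g + 1):(n - g)])
}

#' One-sample Yuen t-test on the trimmed mean
#'
#' Robust one-sample location test: the statistic is the trimmed mean
#' minus `mu0`, over the standard error
#' `sqrt(s2_w * (n - 1) / (h * (h - 1)))` built from the winsorized
#' sample variance `s2_w`, with effective degrees of freedom `h - 1`
#' where `h = n - 2 * floor(trim * n)`.  At `trim = 0` this is exactly
#' the Student one-sample t-test.
#'
#' @param values numeric vector (n >= 4 with the default trim).
#' @param trim trimming fraction per tail, default 0.2.
#' @param mu0 null location, default 0.
#' @return list with `statistic`, `df`, `p_value` (two-sided),
#'   `trimmed_mean`, `se`.
#' @export
yuen_t_one_sample <- function(values, trim = 0.2, mu0 = 0) {
  stopifnot(is.numeric(values))
  n <- length(values)
  g <- floor(trim * n)
  h <- n - 2 * g
  if (h < 2) {
    stop_typed("too few values after trimming (need h >= 2)",
               "erpsep_validation_error")
  }
  res <- yuen_t_map(matrix(values, n, 1), trim = trim, mu0 = mu0)
  if (res$degenerate[1]) {
    stop_typed("winsorized variance is zero: the test is degenerate",
               "erpsep_validation_error")
  }
  list(statistic = res$t[1], df = res$df, p_value = res$p_two[1],
       trimmed_mean = res$tm[1], se = res$se[1])
}

# Vectorized Yuen statistics over the columns of a subjects x points
# matrix.  One radix sort labels-by-(column, value) replaces per-column
# sorting, which keeps the bootstrap loop cheap.
yuen_t_map <- function(X, trim = 0.2, mu0 = 0) {
  n <- nrow(X)
  m <- ncol(X)
  g <- floor(trim * n)
  h <- n - 2 * g
  Xs <- matrix(X[order(col(X), X, method = "radix")], n, m)
  tm <- colMeans(Xs[(g + 1):(n - g), , drop = FALSE])
  Xw <- Xs
  if (g > 0) {
    Xw[seq_len(g), ] <- rep(Xs[g + 1, ], each = g)
    Xw[(n - g + 1):n, ] <- rep(Xs[n - g, ], each = g)
  }
  winvar <- (colSums(Xw^2) - n * colMeans(Xw)^2) / (n - 1)
  winvar[winvar < 0] <- 0
  degenerate <- winvar <= 0
  # SE of the trimmed mean from the winsorized variance, with the h
  # that also sets the df; reduces to sd/sqrt(n) at trim = 0
  se <- sqrt(winvar * (n - 1) / (h * (h - 1)))
  tval <- ifelse(degenerate, 0, (tm - mu0) / ifelse(degenerate, 1, se))
  df <- h - 1
  p_two <- ifelse(degenerate, 1, 2 * stats::pt(-abs(tval), df))
  p_greater <- ifelse(degenerate, 1, stats::pt(tval, df, lower.tail = FALSE))
  list(t = tval, p_two = p_two, p_greater = p_greater, tm = tm, se = se,
       df = df, degenerate = degenerate)
}

# Connected components of the suprathreshold mask under spatio-temporal
# connectivity: (ch, t) ~ (ch, t +/- 1) and (ch, t) ~ (ch', t) for
# spatially adjacent channels.  Returns a list of sorted grid indices
# (column-major, channel fastest).
label_components <- function(mask, A) {
  pts <- which(mask)
  if (length(pts) == 0) {
    return(list())
  }
  n_ch <- nrow(mask)
  n_t <- ncol(mask)
  lookup <- matrix(0L, n_ch, n_t)
  lookup[pts] <- seq_along(pts)
  nbrs <- lapply(seq_len(n_ch), function(ch) which(A[ch, ]))
  seen <- logical(length(pts))
  comps <- list()
  for (p in seq_along(pts)) {
    if (seen[p]) next
    stack <- p
    seen[p] <- TRUE
    members <- integer(0)
    while (length(stack) > 0) {
      q <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, q)
      gidx <- pts[q]
      ch <- (gidx - 1L) %% n_ch + 1L
      tt <- (gidx - 1L) %/% n_ch + 1L
      cand <- integer(0)
      if (tt > 1L && mask[ch, tt - 1L]) cand <- c(cand, lookup[ch, tt - 1L])
      if (tt < n_t && mask[ch, tt + 1L]) cand <- c(cand, lookup[ch, tt + 1L])
      nb <- nbrs[[ch]]
      if (length(nb) > 0) {
        sel <- nb[mask[nb, tt]]
        if (length(sel) > 0) cand <- c(cand, lookup[sel, tt])
      }
      fresh <- cand[!seen[cand]]
      if (length(fresh) > 0) {
        seen[fresh] <- TRUE
        stack <- c(stack, fresh)
      }
    }
    comps[[length(comps) + 1L]] <- sort(pts[members])
  }
  comps
}

#' Form spatio-temporal clusters from a suprathreshold mask
#'
#' Connected components over the channels x timepoints grid, where
#' points are connected to their temporal neighbours on the same
#' channel and to spatially adjacent channels at the same timepoint.
#' Cluster mass is the sum of `|statistic|` over members.  Clusters are
#' returned ordered by start time, ties broken by descending peak
#' statistic.
#'
#' @param mask logical channels x timepoints matrix.
#' @param stat_map numeric matrix of the same shape (e.g. Yuen T).
#' @param neighbours a `channel_neighbours` object (or `NULL` for no
#'   spatial adjacency, i.e. per-channel temporal clustering).
#' @param channel_labels,times grid annotation; default from the mask's
#'   rownames and time indices.
#' @return list of cluster records: each has `members` (data.frame
#'   `channel`, `time_idx`, `time_ms`), `mass`, `peak_value`,
#'   `peak_channel`, `peak_ms`.
#' @export
form_clusters <- function(mask, stat_map, neighbours = NULL,
                          channel_labels = NULL, times = NULL) {
  stopifnot(is.logical(mask), identical(dim(mask), dim(stat_map)))
  channel_labels <- channel_labels %||% rownames(mask) %||%
    sprintf("E%02d", seq_len(nrow(mask)))
  times <- times %||% seq_len(ncol(mask))
  A <- if (is.matrix(neighbours) && is.logical(neighbours)) {
    neighbours
  } else {
    neighbours_matrix(neighbours, channel_labels)
  }
  comps <- label_components(mask, A)
  records <- lapply(comps, function(members) {
    vals <- stat_map[members]
    ch <- (members - 1L) %% nrow(mask) + 1L
    tt <- (members - 1L) %/% nrow(mask) + 1L
    pk <- which.max(abs(vals))
    list(
      members = data.frame(
        channel = channel_labels[ch],
        time_idx = tt,
        time_ms = times[tt]
      ),
      member_idx = members,
      mass = sum(abs(vals)),
      peak_value = vals[pk],
      peak_channel = channel_labels[ch[pk]],
      peak_ms = times[tt[pk]]
    )
  })
  start <- vapply(records, function(r) min(r$members$time_ms), numeric(1))
  peak <- vapply(records, function(r) abs(r$peak_value), numeric(1))
  records[order(start, -peak)]
}

#' Stack per-subject maps into a subjects x channels x timepoints array
#'
#' @param maps list of `contrast_map` objects or plain channels x
#'   timepoints matrices, one per subject, all of one shape.
#' @return numeric array with `channel_labels` and `times` attributes.
#' @export
stack_maps <- function(maps) {
  mats <- lapply(maps, function(m) {
    if (inherits(m, "contrast_map")) m$values else as.matrix(m)
  })
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1)))) {
    stop_typed("all subject maps must share one shape",
               "erpsep_consistency_error")
  }
  out <- array(unlist(mats), dim = c(d[1], d[2], length(mats)))
  out <- aperm(out, c(3, 1, 2))
  first <- maps[[1]]
  attr(out, "channel_labels") <- if (inherits(first, "contrast_map")) {
    first$channel_labels
  } else {
    rownames(mats[[1]])
  }
  attr(out, "times") <- if (inherits(first, "contrast_map")) first$times
  out
}

#' Bootstrap spatio-temporal cluster test on a stack of subject maps
#'
#' Second-level robust inference: a pointwise one-sample Yuen t-test
#' across subjects, cluster formation among points with uncorrected
#' p below `cluster_alpha`, and family-wise correction of each
#' cluster's mass (sum of `|T|`) against a bootstrap null.  The null
#' enforces H0 by subtracting the per-point trimmed mean from every
#' subject's map, then draws `n_boot` sign-flipped resamples (each
#' subject's whole centred map multiplied by a random -1/+1: a
#' Rademacher wild bootstrap), recording the maximal cluster mass of
#' each resample.
#' Corrected p-values are `(1 + #(null >= mass)) / (1 + n_boot)`, so
#' they can never drop below `1 / (n_boot + 1)`.
#'
#' @param stack subjects x channels x timepoints array (see
#'   [stack_maps()]); >= 2 subjects.
#' @param neighbours `channel_neighbours` (or `NULL`).
#' @param trim Yuen trimming fraction, default 0.2.
#' @param cluster_alpha pointwise cluster-forming alpha, default 0.05.
#' @param n_boot bootstrap resamples, default 1000.
#' @param seed integer seed for the resampling.
#' @param tail `"two"` (contrasts) or `"greater"` (signed quantities
#'   such as R-squared excess, where only positive deviations are
#'   meaningful).
#' @param channel_labels,times grid annotation; defaults from the
#'   stack's attributes.
#' @return a `cluster_test_result`: list with `t_map`, `p_map`
#'   (uncorrected), `clusters` (each with `p_corrected`),
#'   `null_distribution`, and the settings used.
#' @export
bootstrap_cluster_test <- function(stack, neighbours = NULL, trim = 0.2,
                                   cluster_alpha = 0.05, n_boot = 1000,
                                   seed = 1, tail = c("two", "greater"),
                                   channel_labels = NULL, times = NULL) {
  tail <- match.arg(tail)
  stopifnot(is.array(stack), length(dim(stack)) == 3, n_boot >= 1,
            cluster_alpha > 0, cluster_alpha < 1)
  d <- dim(stack)
  if (d[1] < 2) {
    stop_typed("need at least 2 subjects", "erpsep_validation_error")
  }
  if (any(!is.finite(stack))) {
    stop_typed("stack contains non-finite values", "erpsep_validation_error")
  }
  channel_labels <- channel_labels %||% attr(stack, "channel_labels") %||%
    sprintf("E%02d", seq_len(d[2]))
  times <- times %||% attr(stack, "times") %||% seq_len(d[3])
  A <- neighbours_matrix(neighbours, channel_labels)

  Xm <- matrix(stack, d[1], d[2] * d[3])
  obs <- yuen_t_map(Xm, trim = trim)
  mask_of <- function(res) {
    if (tail == "two") {
      res$p_two < cluster_alpha
    } else {
      res$t > 0 & res$p_greater < cluster_alpha
    }
  }
  t_map <- matrix(obs$t, d[2], d[3], dimnames = list(channel_labels, NULL))
  p_map <- matrix(if (tail == "two") obs$p_two else obs$p_greater,
                  d[2], d[3], dimnames = list(channel_labels, NULL))
  mask <- matrix(mask_of(obs), d[2], d[3])
  clusters <- form_clusters(mask, t_map, neighbours = A,
                            channel_labels = channel_labels, times = times)

  # H0 enforcement: recentre each point at its trimmed mean, then draw
  # sign-flipped (Rademacher wild bootstrap) resamples.  Flipping whole
  # subjects preserves each map's spatio-temporal structure and, unlike
  # resampling with replacement, cannot collapse the winsorized
  # variance through duplicated subjects.
  Xc <- Xm - rep(obs$tm, each = d[1])
  set.seed(as.integer(seed))
  null <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    signs <- sample(c(-1, 1), d[1], replace = TRUE)
    res <- yuen_t_map(signs * Xc, trim = trim)
    bm <- matrix(mask_of(res), d[2], d[3])
    if (!any(bm)) next
    comps <- label_components(bm, A)
    null[b] <- max(vapply(comps, function(m) sum(abs(res$t[m])), numeric(1)))
  }
  for (i in seq_along(clusters)) {
    clusters[[i]]$p_corrected <-
      (1 + sum(null >= clusters[[i]]$mass)) / (1 + n_boot)
  }
  structure(
    list(t_map = t_map, p_map = p_map, cluster_alpha = cluster_alpha,
         tail = tail, trim = trim, clusters = clusters,
         null_distribution = null, n_boot = n_boot, seed = seed,
         mass_statistic = "sum_abs_t",
         channel_labels = channel_labels, times = times),
    class = "cluster_test_result"
  )
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat(sprintf(
    "cluster_test_result: %d cluster(s), tail=%s, trim=%.2f, alpha=%.3g, n_boot=%d\n",
    length(x$clusters), x$tail, x$trim, x$cluster_alpha, x$n_boot
  ))
  if (length(x$clusters) > 0) {
    print(cluster_table(x$clusters))
  }
  invisible(x)
}

#' Threshold-free cluster enhancement of a statistic map
#'
#' Replaces each point's statistic by the integral over thresholds h of
#' `extent(h)^E * h^H * dh`, where `extent(h)` is the size of the
#' spatio-temporal cluster containing the point at threshold h.
#' Positive and negative parts are enhanced separately and recombined
#' with their signs.  Defaults E = 0.5, H = 2 are the field-standard
#' choice.
#'
#' @param t_map channels x timepoints statistic matrix.
#' @param neighbours `channel_neighbours` (or `NULL`).
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param dh integration step (default 0.1).
#' @param channel_labels channel labels; default from rownames.
#' @return enhanced matrix of the same shape.
#' @export
tfce_transform <- function(t_map, neighbours = NULL, E = 0.5, H = 2,
                           dh = 0.1, channel_labels = NULL) {
  stopifnot(is.matrix(t_map), dh > 0)
  channel_labels <- channel_labels %||% rownames(t_map) %||%
    sprintf("E%02d", seq_len(nrow(t_map)))
  A <- if (is.matrix(neighbours) && is.logical(neighbours)) {
    neighbours
  } else {
    neighbours_matrix(neighbours, channel_labels)
  }
  out <- matrix(0, nrow(t_map), ncol(t_map),
                dimnames = dimnames(t_map))
  for (sgn in c(1, -1)) {
    M <- pmax(sgn * t_map, 0)
    top <- max(M)
    if (top < dh) next
    for (h in seq(dh, top, by = dh)) {
      comps <- label_components(M >= h, A)
      for (members in comps) {
        out[members] <- out[members] + sgn * length(members)^E * h^H * dh
      }
    }
  }
  out
}
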