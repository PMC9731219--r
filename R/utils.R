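# Internal helpers shared across modules.

# Minimum-norm pseudo-inverse via SVD with a relative singular-value cutoff
# (machine eps times the larger matrix dimension).  Needed because the
# dummy-coded category block plus the constant column is rank deficient.
pseudo_inverse <- function(X) {
  s <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * max(s$d, 0)
  keep <- s$d > tol
  if (!any(keep)) {
    return(matrix(0, ncol(X), nrow(X)))
  }
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# Population-SD z-score (divisor n, not n - 1).
zscore_vec <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) {
    stop("cannot z-score a constant vector", call. = FALSE)
  }
  (x - mean(x)) / s
}

# Deterministic child-seed stream: n seeds drawn under `seed`, each usable
# as its own set.seed() argument.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1L)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_typed <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "erpsep_error")))
}

warn_typed <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "erpsep_warning")))
}
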