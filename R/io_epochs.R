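#' Construct a validated single-subject epoched EEG container
#'
#' The container holds one subject's single-trial voltages as a
#' trials x channels x timepoints array in microvolts, together with
#' channel labels, the time vector in ms (stimulus onset at 0 ms), the
#' sampling rate, per-trial category labels and an optional per-trial
#' covariate table.
#'
#' @param data numeric array, trials x channels x timepoints.
#' @param channel_labels character vector, one label per channel.
#' @param times numeric vector in ms; must be strictly increasing with a
#'   uniform step of `1000 / srate`.
#' @param srate sampling rate in Hz.
#' @param categories per-trial category labels (character or factor).
#' @param subject_id subject identifier string.
#' @param covariates optional data.frame with one row per trial.
#' @return an object of class `epoched_eeg`.
#' @export
epoched_eeg <- function(data, channel_labels, times, srate, categories,
                        subject_id, covariates = NULL) {
  if (!is.array(data) || length(dim(data)) != 3) {
    stop_typed("data must be a trials x channels x timepoints array",
               "erpsep_schema_error")
  }
  if (anyNA(data) || any(!is.finite(data))) {
    stop_typed("data contains missing or non-finite voltages",
               "erpsep_schema_error")
  }
  d <- dim(data)
  if (length(channel_labels) != d[2]) {
    stop_typed("channel_labels length does not match the channel dimension",
               "erpsep_schema_error")
  }
  if (length(times) != d[3]) {
    stop_typed("times length does not match the timepoint dimension",
               "erpsep_schema_error")
  }
  step <- diff(times)
  if (length(times) > 1 &&
      (any(step <= 0) || max(abs(step - 1000 / srate)) > 1e-6)) {
    stop_typed("times must increase uniformly with step 1000/srate ms",
               "erpsep_schema_error")
  }
  if (length(categories) != d[1]) {
    stop_typed("categories length does not match the trial count",
               "erpsep_consistency_error")
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != d[1]) {
      stop_typed("covariate table row count does not match the trial count",
                 "erpsep_consistency_error")
    }
  }
  dimnames(data) <- list(NULL, channel_labels, NULL)
  structure(
    list(data = data, channel_labels = as.character(channel_labels),
         times = as.numeric(times), srate = srate,
         categories = as.character(categories),
         subject_id = as.character(subject_id), covariates = covariates),
    class = "epoched_eeg"
  )
}

#' @export
print.epoched_eeg <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "epoched_eeg '%s': %d trials x %d channels x %d timepoints (%g Hz, %g..%g ms)\n",
    x$subject_id, d[1], d[2], d[3], x$srate, min(x$times), max(x$times)
  ))
  cat(sprintf("categories: %s\n",
              paste(names(table(x$categories)), table(x$categories),
                    sep = "=", collapse = ", ")))
  if (!is.null(x$covariates)) {
    cat(sprintf("covariates: %s\n", paste(names(x$covariates), collapse = ", ")))
  }
  invisible(x)
}

#' Write / read one subject's epochs as a portable text container
#'
#' `write_epochs()` stores a subject under `path/`: `data.tsv` holds the
#' voltages (one row per trial x channel, one column per timepoint,
#' full `%.17g` precision so the round trip is exact) and `meta.json`
#' holds labels, times, sampling rate, categories and the covariate
#' table.  `read_epochs()` validates the container and reconstructs the
#' [epoched_eeg()] object exactly.
#'
#' @param epochs an `epoched_eeg` object.
#' @param path directory to create (write) or read.
#' @return `write_epochs()` returns `path` invisibly; `read_epochs()`
#'   returns an `epoched_eeg`.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoched_eeg"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(epochs$data)
  # rows ordered trial-major: (trial 1, ch 1..C), (trial 2, ch 1..C), ...
  flat <- matrix(aperm(epochs$data, c(2, 1, 3)), d[1] * d[2], d[3])
  header <- paste(c("trial", "channel",
                    sprintf("t%d", seq_len(d[3]))), collapse = "\t")
  rows <- sprintf(
    "%d\t%s\t%s",
    rep(seq_len(d[1]), each = d[2]),
    rep(epochs$channel_labels, d[1]),
    apply(flat, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  )
  writeLines(c(header, rows), file.path(path, "data.tsv"))

  meta <- list(
    subject_id = epochs$subject_id,
    srate = epochs$srate,
    times = epochs$times,
    channel_labels = epochs$channel_labels,
    categories = epochs$categories,
    n_trials = d[1]
  )
  if (!is.null(epochs$covariates)) meta$covariates <- epochs$covariates
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  meta_file <- file.path(path, "meta.json")
  data_file <- file.path(path, "data.tsv")
  if (!file.exists(meta_file) || !file.exists(data_file)) {
    stop_typed(sprintf("'%s' is not an epochs container (need meta.json and data.tsv)",
                       path),
               "erpsep_schema_error")
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  for (field in c("subject_id", "srate", "times", "channel_labels",
                  "categories", "n_trials")) {
    if (is.null(meta[[field]])) {
      stop_typed(sprintf("epochs container missing field '%s'", field),
                 "erpsep_schema_error")
    }
  }
  tab <- utils::read.delim(data_file, check.names = FALSE,
                           colClasses = c("integer", "character",
                                          rep("numeric", length(meta$times))))
  n_ch <- length(meta$channel_labels)
  n_trials <- meta$n_trials
  if (nrow(tab) != n_trials * n_ch) {
    stop_typed(
      sprintf("data.tsv has %d rows, expected %d (%d trials x %d channels)",
              nrow(tab), n_trials * n_ch, n_trials, n_ch),
      "erpsep_consistency_error"
    )
  }
  if (length(meta$categories) != n_trials) {
    stop_typed("category labels do not match the stored trial count",
               "erpsep_consistency_error")
  }
  flat <- as.matrix(tab[, -(1:2), drop = FALSE])
  data <- aperm(array(flat, dim = c(n_ch, n_trials, length(meta$times))),
                c(2, 1, 3))
  covs <- if (!is.null(meta$covariates)) as.data.frame(meta$covariates)
  epoched_eeg(
    data = data, channel_labels = meta$channel_labels, times = meta$times,
    srate = meta$srate, categories = meta$categories,
    subject_id = meta$subject_id, covariates = covs
  )
}
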