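#' Read a per-trial covariate table from delimited text
#'
#' Parses a header-carrying delimited file of real-valued covariate
#' columns and checks it against the expected trial count.  Parsing is
#' strict: any non-numeric or missing cell is an error naming the
#' offending row and column -- covariates with missing values must be
#' resolved upstream, not silently dropped.
#'
#' @param path file path of the delimited text (tab, comma or semicolon
#'   separated; autodetected from the header line).
#' @param n_trials expected number of rows.
#' @return a data.frame of numeric covariate columns.
#' @export
read_covariates <- function(path, n_trials) {
  if (!file.exists(path)) {
    stop_typed(sprintf("covariate file '%s' does not exist", path),
               "erpsep_schema_error")
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(";", first)) ";" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE)
  if (nrow(tab) != n_trials) {
    stop_typed(
      sprintf("covariate table has %d rows but %d trials were expected",
              nrow(tab), n_trials),
      "erpsep_consistency_error"
    )
  }
  out <- tab
  for (j in seq_along(tab)) {
    v <- suppressWarnings(as.numeric(tab[[j]]))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      stop_typed(
        sprintf("non-numeric value '%s' at row %d, column '%s'",
                tab[[j]][bad[1]], bad[1], names(tab)[j]),
        "erpsep_parse_error"
      )
    }
    out[[j]] <- v
  }
  out
}

#' Read a channel adjacency definition
#'
#' The file is a JSON object mapping each channel label to the list of
#' its neighbours.  The adjacency is symmetrized (if A lists B, B gains
#' A) and self-links are dropped with a warning.  An empty object is
#' valid: clustering then degenerates to per-channel temporal
#' clustering.
#'
#' @param path JSON file path.
#' @return a `channel_neighbours` object (named list label -> labels).
#' @export
read_neighbours <- function(path) {
  if (!file.exists(path)) {
    stop_typed(sprintf("adjacency file '%s' does not exist", path),
               "erpsep_schema_error")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(raw) == 0) {
    return(structure(stats::setNames(list(), character(0)),
                     class = "channel_neighbours"))
  }
  adj <- lapply(raw, as.character)
  labels <- union(names(adj), unlist(adj, use.names = FALSE))
  full <- stats::setNames(vector("list", length(labels)), labels)
  for (lab in labels) full[[lab]] <- character(0)
  for (lab in names(adj)) {
    for (nb in adj[[lab]]) {
      if (nb == lab) {
        warn_typed(sprintf("dropping self-adjacency of channel '%s'", lab),
                   "erpsep_self_link")
        next
      }
      full[[lab]] <- union(full[[lab]], nb)
      full[[nb]] <- union(full[[nb]], lab)
    }
  }
  structure(full, class = "channel_neighbours")
}

#' Write / read a spatio-temporal cluster report
#'
#' `write_cluster_report()` emits two files: `<path>.tsv`, one row per
#' cluster with columns `cluster_id`, `start_ms`, `end_ms`,
#' `peak_channel`, `peak_ms`, `peak_T`, `p_corrected`, `n_points`; and
#' `<path>.json` additionally carrying every cluster's full member list
#' (channel label / time ms pairs).  Clusters are ordered by start time,
#' ties broken by descending peak statistic.
#'
#' @param clusters a list of cluster records as produced by
#'   [bootstrap_cluster_test()] (element `clusters`).
#' @param path output path prefix (without extension).
#' @return invisibly, the data.frame written to the `.tsv`.
#' @export
write_cluster_report <- function(clusters, path) {
  tab <- cluster_table(clusters)
  utils::write.table(tab, paste0(path, ".tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  ord <- attr(tab, "order")
  members <- lapply(clusters[ord], function(cl) {
    list(channel = cl$members$channel, time_ms = cl$members$time_ms)
  })
  jsonlite::write_json(
    list(clusters = tab, members = members),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(tab)
}

cluster_table <- function(clusters) {
  if (length(clusters) == 0) {
    tab <- data.frame(
      cluster_id = integer(0), start_ms = numeric(0), end_ms = numeric(0),
      peak_channel = character(0), peak_ms = numeric(0), peak_T = numeric(0),
      p_corrected = numeric(0), n_points = integer(0)
    )
    attr(tab, "order") <- integer(0)
    return(tab)
  }
  start <- vapply(clusters, function(cl) min(cl$members$time_ms), numeric(1))
  peak <- vapply(clusters, function(cl) cl$peak_value, numeric(1))
  ord <- order(start, -abs(peak))
  tab <- data.frame(
    cluster_id = seq_along(ord),
    start_ms = start[ord],
    end_ms = vapply(clusters[ord], function(cl) max(cl$members$time_ms),
                    numeric(1)),
    peak_channel = vapply(clusters[ord], function(cl) cl$peak_channel,
                          character(1)),
    peak_ms = vapply(clusters[ord], function(cl) cl$peak_ms, numeric(1)),
    peak_T = peak[ord],
    p_corrected = vapply(clusters[ord],
                         function(cl) cl$p_corrected %||% NA_real_,
                         numeric(1)),
    n_points = vapply(clusters[ord], function(cl) nrow(cl$members),
                      integer(1))
  )
  attr(tab, "order") <- ord
  tab
}

#' @rdname write_cluster_report
#' @export
read_cluster_report <- function(path) {
  json_file <- paste0(path, ".json")
  if (!file.exists(json_file)) {
    stop_typed(sprintf("cluster report '%s' does not exist", json_file),
               "erpsep_schema_error")
  }
  raw <- jsonlite::read_json(json_file)
  lapply(seq_along(raw$clusters), function(i) {
    row <- raw$clusters[[i]]
    mem <- raw$members[[i]]
    list(
      members = data.frame(
        channel = unlist(mem$channel, use.names = FALSE),
        time_ms = as.numeric(unlist(mem$time_ms, use.names = FALSE))
      ),
      peak_channel = row$peak_channel,
      peak_ms = row$peak_ms,
      peak_value = row$peak_T,
      p_corrected = row$p_corrected
    )
  })
}
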