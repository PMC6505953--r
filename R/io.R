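#' Read and write epoched power as portable plain-text containers
#'
#' Stores a trials x electrodes x time power array as a long-format CSV
#' (`trial`, `electrode`, `time`, `power`) with a JSON sidecar recording
#' the dimensions, time axis, band, and edge-sample flag. The same layout
#' accepts externally recorded data: any table with those four columns can
#' be ingested with `read_epoched_power()`.
#'
#' @param ep An [epoched_power()].
#' @param prefix Path prefix; writes `<prefix>.csv` and `<prefix>.json`.
#' @return `write_epoched_power()` returns `prefix` invisibly;
#'   `read_epoched_power()` returns an [epoched_power()].
#' @export
write_epoched_power <- function(ep, prefix) {
  stopifnot(inherits(ep, "epoched_power"))
  d <- dim(ep)
  times <- attr(ep, "times")
  long <- tibble(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    electrode = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    time = rep(times, each = d[1] * d[2]),
    power = as.vector(unclass(ep))
  )
  readr::write_csv(long, paste0(prefix, ".csv"))
  jsonlite::write_json(
    list(n_trials = d[1], n_electrodes = d[2], n_samples = d[3],
         times = times, band = attr(ep, "band"),
         edge_samples = attr(ep, "edge_samples")),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(prefix)
}

#' @rdname write_epoched_power
#' @export
read_epoched_power <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  long <- readr::read_csv(paste0(prefix, ".csv"), show_col_types = FALSE)
  times <- meta$times
  arr <- array(NA_real_, c(meta$n_trials, meta$n_electrodes, meta$n_samples))
  arr[cbind(long$trial, long$electrode, match(long$time, times))] <- long$power
  epoched_power(arr, times = times, band = meta$band,
                edge_samples = meta$edge_samples %||% 0L)
}

#' Read and write trial tables as CSV
#'
#' @param trials A trial tibble (see [sample_trial_positions()]).
#' @param path File path.
#' @return `read_trial_table()` returns a tibble with integer bin columns.
#' @export
write_trial_table <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  for (col in intersect(c("trial", "bin_probed", "bin_unprobed", "set"), names(out))) {
    out[[col]] <- as.integer(out[[col]])
  }
  out
}
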