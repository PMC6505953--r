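#' Generate one synthetic subject's electrode data
#'
#' Simulates a subject under the linear encoding model. A subject owns one
#' weight matrix `W` (`n_electrodes` x `n_channels`, entries drawn uniformly
#' from `[0, 1]`) that is shared across conditions (a subject has one head).
#' For each trial the channel responses are evaluated at the exact stimulus
#' position(s) with the half-sinusoid basis; on two-item trials the two
#' items' channel-response vectors are summed (representations are assumed
#' additive) and optionally scaled by `amplitude_scale_two_item`. Electrode
#' data are `W %*% C` plus i.i.d. Gaussian noise with the condition's SD.
#'
#' @param config A [sim_config()].
#' @param condition `"both"` (default), `"one_item"`, or `"two_item"`.
#' @param seed Optional RNG seed (falls back to `config$seed`).
#' @return A `sim_subject`: a list with `electrode_data` (trials x
#'   electrodes), `true_weights` (electrodes x channels), `trials` (the
#'   trial tibble, rows aligned with `electrode_data`), and `basis`.
#' @examples
#' subj <- generate_subject(sim_config(), seed = 1)
#' dim(subj$electrode_data)
#' @export
generate_subject <- function(config, condition = c("both", "one_item", "two_item"),
                             seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  condition <- match.arg(condition)
  local_seed(seed %||% config$seed)
  basis <- make_basis(config$n_channels, config$basis_exponent)
  W <- matrix(runif(config$n_electrodes * config$n_channels), config$n_electrodes)

  conds <- if (condition == "both") c("one_item", "two_item") else condition
  parts <- lapply(conds, function(cond) {
    trials <- sample_trial_positions(config, cond)
    C <- channel_responses(basis, trials, config$amplitude_scale_two_item)
    sdn <- if (cond == "one_item") config$noise_sd_one_item else config$noise_sd_two_item
    E <- W %*% C
    if (sdn > 0) E <- E + matrix(rnorm(length(E), 0, sdn), nrow(E))
    list(trials = trials, E = t(E))
  })
  trials <- dplyr::bind_rows(lapply(parts, `[[`, "trials"))
  trials$trial <- seq_len(nrow(trials))
  structure(
    list(
      electrode_data = do.call(rbind, lapply(parts, `[[`, "E")),
      true_weights = W,
      trials = trials,
      basis = basis
    ),
    class = "sim_subject"
  )
}

# Channel responses (channels x trials) at the exact per-trial positions;
# two-item responses are additive and then amplitude-scaled.
channel_responses <- function(basis, trials, amplitude_scale_two_item = 1) {
  C <- basis_response(basis, trials$angle_probed)
  two <- !is.na(trials$bin_unprobed)
  if (any(two)) {
    C[, two] <- C[, two] + basis_response(basis, trials$angle_unprobed[two])
    C[, two] <- C[, two] * amplitude_scale_two_item
  }
  C
}

#' @export
print.sim_subject <- function(x, ...) {
  cat(sprintf("<sim_subject> %d trials x %d electrodes (%s)\n",
              nrow(x$electrode_data), ncol(x$electrode_data),
              paste(unique(x$trials$condition), collapse = " + ")))
  invisible(x)
}

#' Generate a time-resolved synthetic dataset with a known tuning window
#'
#' Builds an epoched power array (trials x electrodes x time) in which
#' spatially tuned signal is present only inside `[tuning_onset,
#' tuning_offset]` ms; outside the window the data are pure Gaussian noise.
#' This gives the time-resolved pipeline (and the cluster-based permutation
#' test) exact ground truth about when location information exists.
#'
#' @param config A [sim_config()].
#' @param tuning_onset,tuning_offset Tuning window in ms (onset < offset).
#' @param times Sample times in ms.
#' @param condition Condition to simulate (`"one_item"` or `"two_item"`).
#' @param seed Optional RNG seed.
#' @return A list with `power` (an [epoched_power()] array), `trials`,
#'   `true_weights`, and the tuning window.
#' @export
generate_timecourse_dataset <- function(config, tuning_onset, tuning_offset,
                                        times = seq(-500, 1480, by = 20),
                                        condition = "one_item", seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!tuning_onset < tuning_offset) {
    abort("`tuning_onset` must be earlier than `tuning_offset`.")
  }
  local_seed(seed %||% config$seed)
  basis <- make_basis(config$n_channels, config$basis_exponent)
  W <- matrix(runif(config$n_electrodes * config$n_channels), config$n_electrodes)
  trials <- sample_trial_positions(config, condition)
  C <- channel_responses(basis, trials, config$amplitude_scale_two_item)
  signal <- t(W %*% C)                       # trials x electrodes
  sdn <- if (condition == "one_item") config$noise_sd_one_item else config$noise_sd_two_item
  n <- nrow(trials); m <- config$n_electrodes
  tuned <- times >= tuning_onset & times <= tuning_offset
  pow <- array(rnorm(n * m * length(times), 0, sdn), dim = c(n, m, length(times)))
  pow[, , tuned] <- pow[, , tuned] + rep(signal, sum(tuned))
  list(
    power = epoched_power(pow, times = times),
    trials = trials,
    true_weights = W,
    tuning_window = c(tuning_onset, tuning_offset)
  )
}
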