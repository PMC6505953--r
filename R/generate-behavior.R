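#' Generate continuous-report response errors from a mixture model
#'
#' Generative twin of the mixture models fitted by [fit_mixture2()] and
#' [fit_mixture3()]. Each trial's signed response error (degrees, relative
#' to the probed item) is drawn from a three-component mixture: with
#' probability `p_guess` a uniform guess on `(-180, 180]`; with probability
#' `p_swap` a von Mises report centred on the unprobed item's offset from
#' the probed item; otherwise a von Mises centred on 0 with circular s.d.
#' `sd_target`. The true generating component of every trial is recorded so
#' parameter-recovery tests have ground truth.
#'
#' When swaps are generated and `nontarget_offsets` is not supplied, the
#' unprobed item's offset is taken from a counterbalanced two-item trial
#' table when `n_trials` permits exact counterbalancing (divisible by 64
#' under the default 8-bin design), and from uniformly sampled jittered bins
#' otherwise.
#'
#' @param sd_target Circular s.d. (degrees) of the target von Mises.
#' @param p_guess,p_swap Mixture weights; `p_guess + p_swap` must be <= 1.
#' @param n_trials Number of trials.
#' @param nontarget_offsets Optional per-trial signed offsets (degrees) of
#'   the unprobed item relative to the probed item.
#' @param config A [sim_config()] used to build the trial table when
#'   offsets must be generated.
#' @param seed Optional RNG seed.
#' @return A tibble with `trial`, `error` (signed degrees in
#'   `(-180, 180]`), `component` (`"target"`, `"guess"`, or `"swap"`), and
#'   `nontarget_offset`.
#' @examples
#' err <- generate_behavioral_errors(6, p_guess = 0.1, p_swap = 0.2,
#'                                   n_trials = 576, seed = 1)
#' table(err$component)
#' @export
generate_behavioral_errors <- function(sd_target, p_guess = 0, p_swap = 0,
                                       n_trials, nontarget_offsets = NULL,
                                       config = sim_config(), seed = NULL) {
  if (p_guess < 0 || p_swap < 0 || p_guess + p_swap > 1) {
    abort("`p_guess` and `p_swap` must be >= 0 with `p_guess + p_swap` <= 1.")
  }
  if (sd_target <= 0) abort("`sd_target` must be > 0.")
  n_trials <- assert_count(n_trials, "n_trials")
  local_seed(seed)
  kappa <- vm_kappa_from_sd(sd_target)

  if (is.null(nontarget_offsets)) {
    k2 <- config$n_channels^2
    if (p_swap > 0 && n_trials %% k2 == 0) {
      tt <- sample_trial_positions(config, "two_item", n_trials = n_trials)
      nontarget_offsets <- circ_diff(tt$angle_unprobed, tt$angle_probed)
    } else {
      bins <- sample(0:(config$n_channels - 1L), n_trials, replace = TRUE)
      nontarget_offsets <- circ_diff(
        jitter_in_bin(bins, 360 / config$n_channels) +
          runif(n_trials, 0, 360), runif(n_trials, 0, 360)
      )
      # independent uniform reference: offsets are wedge-jittered bins
      # relative to a uniformly random probed position
    }
  } else if (length(nontarget_offsets) != n_trials) {
    abort("`nontarget_offsets` must have length `n_trials`.")
  }

  u <- runif(n_trials)
  component <- ifelse(u < p_guess, "guess",
                      ifelse(u < p_guess + p_swap, "swap", "target"))
  error <- numeric(n_trials)
  is_g <- component == "guess"
  is_s <- component == "swap"
  is_t <- component == "target"
  if (any(is_g)) error[is_g] <- circ_diff(runif(sum(is_g), 0, 360), 0)
  if (any(is_t)) error[is_t] <- rvonmises(sum(is_t), 0, kappa)
  if (any(is_s)) {
    error[is_s] <- circ_diff(
      rvonmises(sum(is_s), 0, kappa) + nontarget_offsets[is_s], 0
    )
  }
  tibble(
    trial = seq_len(n_trials),
    error = error,
    component = component,
    nontarget_offset = nontarget_offsets
  )
}
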