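#' Configuration for the synthetic-subject generator
#'
#' Bundles every parameter of the synthetic data generator: the number of
#' simulated subjects and trials, the electrode montage size, the channel
#' basis, and the condition-specific noise and amplitude settings. The
#' defaults reproduce the canonical study conditions: 28 subjects, 576
#' trials per condition, 30 electrodes, 8 channels with an exponent-25
#' half-sinusoid basis, unit Gaussian electrode noise in both conditions,
#' and equal channel-response amplitude across conditions.
#'
#' Two knobs distinguish the standard simulation variants:
#' `noise_sd_two_item = 2` adds extra noise to the two-item condition only,
#' and `amplitude_scale_two_item = 0.9` scales the underlying two-item
#' channel responses down by 10%.
#'
#' @param n_subjects Number of synthetic subjects per sample.
#' @param n_trials_per_condition Trials per condition per subject. Must be
#'   divisible by `n_channels^2` so the two-item bin pairs counterbalance
#'   exactly (and hence by `n_channels` for the one-item condition).
#' @param n_electrodes Number of electrodes (must be >= `n_channels` so the
#'   encoding model is invertible).
#' @param n_channels Number of spatial channels / position bins.
#' @param basis_exponent Half-sinusoid exponent of the channel basis.
#' @param noise_sd_one_item,noise_sd_two_item SD of the i.i.d. Gaussian
#'   noise added to each electrode's response, per condition.
#' @param amplitude_scale_two_item Multiplicative scaling of the two-item
#'   channel responses, in `[0, 1]`.
#' @param min_item_separation Minimum angular separation (degrees) between
#'   the two items' exact positions on two-item trials.
#' @param seed Optional RNG seed stored with the config and used by
#'   generator functions when they are not given their own seed.
#' @return A `sim_config` object (a validated list).
#' @examples
#' cfg <- sim_config()                              # equal-noise settings
#' cfg_noise <- sim_config(noise_sd_two_item = 2)   # extra two-item noise
#' cfg_amp <- sim_config(amplitude_scale_two_item = 0.9)
#' @export
sim_config <- function(n_subjects = 28,
                       n_trials_per_condition = 576,
                       n_electrodes = 30,
                       n_channels = 8,
                       basis_exponent = 25,
                       noise_sd_one_item = 1,
                       noise_sd_two_item = 1,
                       amplitude_scale_two_item = 1,
                       min_item_separation = 4.6,
                       seed = NULL) {
  cfg <- list(
    n_subjects = assert_count(n_subjects, "n_subjects"),
    n_trials_per_condition = assert_count(n_trials_per_condition,
                                          "n_trials_per_condition"),
    n_electrodes = assert_count(n_electrodes, "n_electrodes"),
    n_channels = assert_count(n_channels, "n_channels", min = 2L),
    basis_exponent = basis_exponent,
    noise_sd_one_item = noise_sd_one_item,
    noise_sd_two_item = noise_sd_two_item,
    amplitude_scale_two_item = amplitude_scale_two_item,
    min_item_separation = min_item_separation,
    seed = if (!is.null(seed)) as.integer(seed)
  )
  if (cfg$n_trials_per_condition %% cfg$n_channels^2 != 0) {
    abort(sprintf(
      "`n_trials_per_condition` (%d) must be divisible by n_channels^2 (%d) for exact two-item counterbalancing.",
      cfg$n_trials_per_condition, cfg$n_channels^2
    ))
  }
  if (cfg$n_electrodes < cfg$n_channels) {
    abort("`n_electrodes` must be >= `n_channels` (the model is otherwise not invertible).")
  }
  if (noise_sd_one_item < 0 || noise_sd_two_item < 0) {
    abort("Noise SDs must be >= 0.")
  }
  if (amplitude_scale_two_item < 0 || amplitude_scale_two_item > 1) {
    abort("`amplitude_scale_two_item` must lie in [0, 1].")
  }
  if (min_item_separation < 0 || min_item_separation >= 360 / cfg$n_channels) {
    abort("`min_item_separation` must lie in [0, bin width).")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d subjects x %d trials/condition, %d electrodes, %d channels (exponent %g)\n",
              x$n_subjects, x$n_trials_per_condition, x$n_electrodes,
              x$n_channels, x$basis_exponent))
  cat(sprintf("  noise SD: one-item %g, two-item %g; two-item amplitude scale %g\n",
              x$noise_sd_one_item, x$noise_sd_two_item,
              x$amplitude_scale_two_item))
  cat(sprintf("  min item separation %g deg%s\n", x$min_item_separation,
              if (is.null(x$seed)) "" else sprintf("; seed %d", x$seed)))
  invisible(x)
}

#' Read or write a simulation config as JSON
#'
#' @param config A `sim_config`.
#' @param path File path.
#' @return `read_sim_config()` returns a `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(sim_config, x)
}
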