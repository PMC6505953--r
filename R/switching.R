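#' Simulated-switching null reconstruction
#'
#' Builds the CTF expected under a switching account — only one of several
#' items is actively represented at any moment — from one-item data alone.
#' On each IEM iteration a fresh random `fraction` of the one-item trials
#' has its position labels randomized (by default, permuted among the
#' scrambled trials within each partition set, which keeps every set's
#' per-bin trial counts exactly balanced; uniform redrawing over the bins
#' is available via `redraw`); the remaining trials keep their true
#' labels. The encoding model itself is trained on veridically labelled
#' data (the switching account leaves the encoding intact and varies only
#' which item is active), and the scrambled labels enter at the
#' reconstruction stage, when the held-out set is bin-averaged and
#' aligned.
#'
#' Because reconstruction is linear in the test data, the expected
#' switching CTF is exactly `fraction * flat + (1 - fraction) * CTF`, where
#' `CTF` is the ordinary one-item reconstruction; its slope is therefore
#' `(1 - fraction)` times the one-item slope.
#'
#' @param power One-item power input, as for [run_iem()].
#' @param trials One-item trial tibble.
#' @param fraction Fraction of trials whose labels are redrawn, in `[0, 1]`.
#' @param n_iterations,seed,basis,n_sets As in [run_iem()].
#' @param redraw `"permute_within_set"` (default), `"all_bins"`, or `"other_bins"` (exclude the
#'   true bin when redrawing).
#' @param partitions Optional explicit partitions, as in [run_iem()].
#' @return A `ctf_reconstruction` whose condition is `"switching"`.
#' @export
simulate_switching <- function(power, trials, fraction = 0.5,
                               n_iterations = 10, seed = NULL, basis = NULL,
                               n_sets = 3, redraw = "permute_within_set",
                               partitions = NULL) {
  if (fraction < 0 || fraction > 1) abort("`fraction` must lie in [0, 1].")
  scramble <- if (fraction > 0) list(fraction = fraction, redraw = redraw)
  rec <- run_iem(power, trials, regime = "within_condition",
                 n_iterations = n_iterations, seed = seed, basis = basis,
                 n_sets = n_sets, partitions = partitions,
                 .test_scramble = scramble)
  rec$conditions <- rep("switching", length(rec$conditions))
  dimnames(rec$profiles)[[1]] <- rec$conditions
  rec$fraction <- fraction
  rec
}

#' Compare two-item and simulated-switching selectivity
#'
#' Paired comparisons of per-subject CTF slopes between the two-item
#' condition and the simulated-switching null, over planned delay-period
#' windows. If observed two-item selectivity reliably exceeds the
#' switching null, the data are inconsistent with a strict one-item-at-a-
#' time account.
#'
#' @param two_item_slopes,switching_slopes Matched per-subject slope
#'   vectors, or subjects x time matrices.
#' @param times Time axis (ms) when matrices are supplied.
#' @param windows Named list of `c(from, to)` windows in ms; defaults to
#'   the delay period (250-1250 ms) and a late window (800-1250 ms). When
#'   slope vectors are supplied a single unnamed comparison is returned.
#' @return A tibble with one row per window: see [window_compare()].
#' @export
compare_switching <- function(two_item_slopes, switching_slopes, times = NULL,
                              windows = list(delay = c(250, 1250),
                                             late = c(800, 1250))) {
  if (is.null(dim(two_item_slopes))) {
    out <- window_compare(two_item_slopes, switching_slopes)
    out$window <- "all"
    return(out)
  }
  rows <- lapply(names(windows), function(w) {
    out <- window_compare(two_item_slopes, switching_slopes,
                          times = times, window = windows[[w]])
    out$window <- w
    out
  })
  dplyr::bind_rows(rows)
}

#' Monte Carlo comparison of concurrent-storage and switching accounts
#'
#' Simulation harness for validating the switching analysis against known
#' ground truth. Each sample simulates `config$n_subjects` subjects; per
#' subject, one-item data are generated as usual and a two-item "truth"
#' dataset is generated under either account:
#' * `"concurrent"` — both items are represented on every trial, each at
#'   `amplitude_per_item` times the one-item amplitude;
#' * `"alternation"` — exactly one item (probed or unprobed, equal odds)
#'   is represented per trial, at full amplitude.
#'
#' A common encoding model is trained per subject on the veridical
#' one-item data; the two-item data and the switching null (one-item data
#' with `fraction` of labels redrawn) enter only as test sets, so the two
#' reconstructions differ only in their test data. A paired t test on the
#' per-subject slopes is computed per sample.
#'
#' @param config A [sim_config()].
#' @param truth `"concurrent"` or `"alternation"`.
#' @param amplitude_per_item Per-item amplitude under the concurrent truth.
#' @param fraction Label-scrambling fraction of the switching null.
#' @param n_samples Number of simulated samples.
#' @param n_iterations IEM iterations per reconstruction.
#' @param seed Optional RNG seed.
#' @return A `switching_study` object: tibble `samples` (per-sample mean
#'   slopes, paired t and p) plus settings.
#' @export
switching_study <- function(config = sim_config(),
                            truth = c("concurrent", "alternation"),
                            amplitude_per_item = 0.75, fraction = 0.5,
                            n_samples = 100, n_iterations = 10, seed = NULL) {
  truth <- match.arg(truth)
  local_seed(seed)
  basis <- make_basis(config$n_channels, config$basis_exponent)
  samples <- purrr::map_dfr(seq_len(n_samples), function(i) {
    slopes <- vapply(seq_len(config$n_subjects), function(s) {
      subject_switching_slopes(config, basis, truth, amplitude_per_item,
                               fraction, n_iterations)
    }, numeric(2))
    d <- slopes[1, ] - slopes[2, ]
    tstat <- if (sd(d) == 0) 0 else mean(d) / (sd(d) / sqrt(length(d)))
    tibble(
      sample = i,
      mean_slope_two_item = mean(slopes[1, ]),
      mean_slope_switching = mean(slopes[2, ]),
      statistic = tstat,
      p_value = 2 * pt(-abs(tstat), df = length(d) - 1)
    )
  })
  structure(
    list(samples = samples, truth = truth,
         amplitude_per_item = amplitude_per_item, fraction = fraction,
         config = config, n_iterations = n_iterations, seed = seed),
    class = "switching_study"
  )
}

# Per-subject (two_item, switching) slope pair under a shared one-item-
# trained encoding model.
subject_switching_slopes <- function(config, basis, truth, amplitude_per_item,
                                     fraction, n_iterations) {
  W <- matrix(runif(config$n_electrodes * config$n_channels),
              config$n_electrodes)
  tr1 <- sample_trial_positions(config, "one_item")
  E1 <- t(W %*% basis_response(basis, tr1$angle_probed))
  if (config$noise_sd_one_item > 0) {
    E1 <- E1 + matrix(rnorm(length(E1), 0, config$noise_sd_one_item), nrow(E1))
  }
  tr2 <- sample_trial_positions(config, "two_item")
  C2 <- if (truth == "concurrent") {
    amplitude_per_item * (basis_response(basis, tr2$angle_probed) +
                            basis_response(basis, tr2$angle_unprobed))
  } else {
    use_probed <- runif(nrow(tr2)) < 0.5
    ang <- ifelse(use_probed, tr2$angle_probed, tr2$angle_unprobed)
    basis_response(basis, ang)
  }
  E2 <- t(W %*% C2)
  if (config$noise_sd_two_item > 0) {
    E2 <- E2 + matrix(rnorm(length(E2), 0, config$noise_sd_two_item), nrow(E2))
  }
  trials <- dplyr::bind_rows(tr1, tr2)
  trials$trial <- seq_len(nrow(trials))
  power <- rbind(E1, E2)

  # shared partitions: the cross-trained two-item reconstruction and the
  # switching null then use byte-identical training matrices per fold
  partitions <- lapply(seq_len(n_iterations), function(i) {
    partition_trials(trials, regime = "within_condition")$set
  })
  one <- trials$condition == "one_item"
  rec2 <- run_iem(power, trials, regime = "cross_training",
                  n_iterations = n_iterations, basis = basis,
                  partitions = partitions)
  rec_sw <- simulate_switching(E1, tr1, fraction = fraction,
                               n_iterations = n_iterations, basis = basis,
                               partitions = lapply(partitions, `[`, one))
  c(ctf_slope(rec2$profiles[1, , 1]), ctf_slope(rec_sw$profiles[1, , 1]))
}

#' @export
print.switching_study <- function(x, ...) {
  cat(sprintf(
    "<switching_study> truth = %s, %d samples; two-item > switching in %.1f%% (p < 0.05 in %.1f%%)\n",
    x$truth, nrow(x$samples),
    100 * mean(x$samples$statistic > 0),
    100 * mean(x$samples$p_value < 0.05)
  ))
  invisible(x)
}
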