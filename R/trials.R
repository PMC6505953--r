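#' Sample a counterbalanced trial table
#'
#' Draws the per-trial stimulus positions for one subject under the task's
#' position design: positions fall in `n_channels` bins, each spanning a
#' `360/n_channels`-degree wedge centred on the bin centre, with uniform
#' jitter inside the wedge so all 360deg of positions occur. One-item trials
#' sample each bin equally often. Two-item trials counterbalance the ordered
#' (probed, unprobed) bin pair exactly — every pair occurs
#' `n_trials / n_channels^2` times — and the two items' exact positions are
#' re-jittered until they are at least `min_item_separation` degrees apart.
#'
#' Counterbalancing is exact, not merely in expectation, which is what lets
#' the probed item's representation be isolated by averaging: across trials
#' of any probed bin, the unprobed item visits every bin equally often.
#'
#' @param config A [sim_config()].
#' @param condition `"one_item"` or `"two_item"`.
#' @param n_trials Number of trials; defaults to
#'   `config$n_trials_per_condition`. Must be divisible by `n_channels`
#'   (one-item) or `n_channels^2` (two-item).
#' @param seed Optional RNG seed.
#' @return A tibble with one row per trial: `trial`, `condition`,
#'   `bin_probed`, `angle_probed`, and (two-item only non-`NA`)
#'   `bin_unprobed`, `angle_unprobed`. Bins are integers in
#'   `0:(n_channels-1)`; angles are continuous degrees in `[0, 360)`.
#' @examples
#' tr <- sample_trial_positions(sim_config(), "two_item", seed = 1)
#' table(tr$bin_probed, tr$bin_unprobed)  # exactly uniform
#' @export
sample_trial_positions <- function(config, condition = c("one_item", "two_item"),
                                   n_trials = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  condition <- match.arg(condition)
  local_seed(seed)
  k <- config$n_channels
  n <- n_trials %||% config$n_trials_per_condition
  bin_width <- 360 / k

  if (condition == "one_item") {
    if (n %% k != 0) {
      abort(sprintf("one-item `n_trials` (%d) must be divisible by %d bins.", n, k))
    }
    bins <- sample(rep.int(0:(k - 1L), n %/% k))
    tibble(
      trial = seq_len(n),
      condition = "one_item",
      bin_probed = bins,
      angle_probed = jitter_in_bin(bins, bin_width),
      bin_unprobed = NA_integer_,
      angle_unprobed = NA_real_
    )
  } else {
    if (n %% (k * k) != 0) {
      abort(sprintf("two-item `n_trials` (%d) must be divisible by %d bin pairs.", n, k * k))
    }
    pairs <- expand.grid(bin_probed = 0:(k - 1L), bin_unprobed = 0:(k - 1L))
    idx <- sample(rep.int(seq_len(k * k), n %/% (k * k)))
    bp <- pairs$bin_probed[idx]
    bu <- pairs$bin_unprobed[idx]
    ap <- jitter_in_bin(bp, bin_width)
    au <- jitter_in_bin(bu, bin_width)
    # joint rejection: re-jitter both items of any trial closer than the
    # minimum separation; preserves wedge-uniform marginals conditional on
    # the separation constraint
    repeat {
      bad <- which(circ_dist(ap, au) < config$min_item_separation)
      if (!length(bad)) break
      ap[bad] <- jitter_in_bin(bp[bad], bin_width)
      au[bad] <- jitter_in_bin(bu[bad], bin_width)
    }
    tibble(
      trial = seq_len(n),
      condition = "two_item",
      bin_probed = bp,
      angle_probed = ap,
      bin_unprobed = bu,
      angle_unprobed = au
    )
  }
}

jitter_in_bin <- function(bins, bin_width) {
  (bins * bin_width + runif(length(bins), -bin_width / 2, bin_width / 2)) %% 360
}
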