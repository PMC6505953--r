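#' Bin-averaged electrode matrix
#'
#' Averages the electrode data of one set's trials within each position
#' bin, producing the electrodes x bins measurement matrix the encoding
#' model is trained and tested on.
#'
#' @param power Trials x electrodes matrix of power at one time point.
#' @param trials Trial tibble containing `bin_probed` and (from
#'   [partition_trials()]) a `set` column.
#' @param set_id Which set to average (an integer, or a vector of set ids
#'   whose trials are pooled — used for combined training sets).
#' @param n_bins Number of position bins (default: `max(bin) + 1`).
#' @return An electrodes x `n_bins` matrix; column `b + 1` is the mean over
#'   the set's bin-`b` trials.
#' @export
average_by_bin <- function(power, trials, set_id, n_bins = NULL) {
  if (!"set" %in% names(trials)) {
    abort("`trials` must carry a `set` column (see `partition_trials()`).")
  }
  n_bins <- n_bins %||% (max(trials$bin_probed) + 1L)
  idx <- which(trials$set %in% set_id)
  out <- bin_avg(power, trials$bin_probed, idx, n_bins)
  if (anyNA(out[1, ])) {
    abort(sprintf("Empty position bin(s) %s in set %s.",
                  paste(which(is.na(out[1, ])) - 1L, collapse = ", "),
                  paste(set_id, collapse = "+")))
  }
  out
}

# Fast path: electrodes x k matrix of per-bin means over `idx`; empty bins
# yield NA columns (callers decide whether that is an error).
bin_avg <- function(power, labels, idx, k) {
  sums <- rowsum(power[idx, , drop = FALSE], labels[idx])
  counts <- tabulate(labels[idx] + 1L, nbins = k)
  out <- matrix(NA_real_, ncol(power), k)
  present <- as.integer(rownames(sums)) + 1L
  out[, present] <- t(sums / counts[present])
  out
}

#' Estimate channel weights by least squares
#'
#' Training stage of the inverted encoding model. Given training
#' measurements `B1` (electrodes x n1) and the basis-predicted channel
#' responses `C1` (channels x n1) for those measurements, estimates the
#' weight matrix `W` (electrodes x channels) of the linear forward model
#' `B1 = W C1` by ordinary least squares, row-wise per electrode. The value
#' equals `B1 C1' (C1 C1')^-1`; the computation uses a QR factorization.
#'
#' @param B1 Electrodes x measurements training data.
#' @param C1 Channels x measurements predicted channel responses.
#' @return A `channel_weights` matrix (electrodes x channels).
#' @export
train_weights <- function(B1, C1) {
  if (ncol(B1) != ncol(C1)) {
    abort("`B1` and `C1` must have the same number of measurements.")
  }
  qrc <- qr(t(C1))
  if (qrc$rank < nrow(C1)) {
    abort(sprintf(
      "Predicted channel responses are rank deficient (rank %d < %d channels): the training measurements do not span all channels.",
      qrc$rank, nrow(C1)
    ))
  }
  W <- t(qr.coef(qrc, t(B1)))
  dimnames(W) <- list(rownames(B1), rownames(C1))
  class(W) <- c("channel_weights", class(W))
  W
}

#' Invert the encoding model on test data
#'
#' Test stage of the inverted encoding model: transforms observed test
#' measurements `B2` (electrodes x n2) into estimated channel responses
#' using the trained weights. The value equals `(W'W)^-1 W' B2`; the
#' computation uses a QR factorization of `W`.
#'
#' @param w Trained weights (electrodes x channels), see [train_weights()].
#' @param B2 Electrodes x measurements test data.
#' @return Channels x measurements matrix of estimated channel responses.
#' @export
invert_model <- function(w, B2) {
  w <- unclass(w)
  if (nrow(w) != nrow(B2)) {
    abort("`w` and `B2` must agree on the number of electrodes.")
  }
  qrw <- qr(w)
  if (qrw$rank < ncol(w)) {
    abort(sprintf(
      "Estimated weights are rank deficient (rank %d < %d channels); the model cannot be inverted.",
      qrw$rank, ncol(w)
    ))
  }
  ok <- !is.na(B2[1, ])
  out <- matrix(NA_real_, ncol(w), ncol(B2))
  out[, ok] <- qr.coef(qrw, B2[, ok, drop = FALSE])
  out
}

# Offsets (degrees) on the (-180, 180] grid, in ascending order, and the
# permutation mapping raw offset index 0..k-1 (channel - bin) onto it.
offset_grid <- function(k) {
  step <- 360 / k
  raw <- (seq_len(k) - 1L) * step
  deg <- ifelse(raw > 180, raw - 360, raw)
  list(sorted = sort(deg), order = order(deg), step = step)
}

# Align each test bin's estimated channel responses to a common centre
# (offset 0 = channel tuned to the probed bin) and accumulate. Returns
# per-raw-offset sums and profile counts.
align_accumulate <- function(C2, k) {
  s <- numeric(k); n <- 0
  for (b in which(!is.na(C2[1, ])) - 1L) {
    s <- s + C2[((seq_len(k) - 1L + b) %% k) + 1L, b + 1L]
    n <- n + 1
  }
  list(sum = s, n = n)
}

#' Run the inverted encoding model with cross-validation
#'
#' The full IEM routine, applied at each time point: partition trials into
#' `n_sets` balanced sets, bin-average each set, train the encoding model
#' on `n_sets - 1` sets and invert it on the held-out set (leave-one-out
#' over all folds), circularly shift each test bin's estimated
#' channel-response profile so the channel tuned to the probed location
#' sits at offset 0, and average over bins, folds, and `n_iterations`
#' random re-partitions (re-randomized each iteration so different excess
#' trials are left out).
#'
#' Three training regimes are supported:
#' * `"condition_neutral"` — a single encoding model per fold is trained on
#'   data combined across conditions before averaging (with per-bin trial
#'   counts equated across conditions), and the held-out set of each
#'   condition is reconstructed separately. Differences between conditions
#'   are then attributable to the test data alone.
#' * `"within_condition"` — the model is trained and tested within each
#'   condition separately.
#' * `"cross_training"` — the model is trained on one-item sets and tested
#'   on the held-out two-item set.
#'
#' @param power A trials x electrodes matrix (single time point) or an
#'   [epoched_power()] / 3-D array (trials x electrodes x time).
#' @param trials Trial tibble aligned with the rows of `power`.
#' @param regime Training regime, see above.
#' @param n_iterations Number of random re-partitions to average over
#'   (50 is conventional for a single-band analysis, 10 for frequency
#'   sweeps and simulations).
#' @param seed Optional RNG seed.
#' @param basis A [make_basis()] basis set; default 8 channels, exponent 25.
#' @param n_sets Number of partition sets (default 3).
#' @param shuffle_labels If `TRUE`, position labels are randomly permuted
#'   within every training and test set (fresh per iteration) — the
#'   label-randomization null used by the cluster-based permutation test.
#' @param partitions Optional list (length `n_iterations`) of explicit
#'   per-trial set assignments (integer vectors, 0 = unassigned),
#'   bypassing the internal randomization; intended for exact
#'   reproducibility checks.
#' @param .test_scramble Internal: `list(fraction =, redraw =)` applied to
#'   test-stage labels only (see [simulate_switching()]).
#' @return A `ctf_reconstruction`: profiles array (condition x channel
#'   offset x time) plus metadata. Use [tidy()] for a long tibble and
#'   [ctf_slopes()] for the selectivity time course.
#' @examples
#' cfg <- sim_config(n_trials_per_condition = 192)
#' subj <- generate_subject(cfg, seed = 1)
#' rec <- run_iem(subj$electrode_data, subj$trials, n_iterations = 2, seed = 2)
#' ctf_slopes(rec)
#' @export
run_iem <- function(power, trials,
                    regime = c("condition_neutral", "within_condition", "cross_training"),
                    n_iterations = 10, seed = NULL, basis = NULL, n_sets = 3,
                    shuffle_labels = FALSE, partitions = NULL,
                    .test_scramble = NULL) {
  regime <- match.arg(regime)
  basis <- basis %||% make_basis()
  k <- length(basis$centers)
  local_seed(seed)
  n_iterations <- assert_count(n_iterations, "n_iterations")

  pw <- as_power_array(power)
  n_time <- dim(pw)[3]
  times <- attr(power, "times") %||% seq_len(n_time)
  if (nrow(trials) != dim(pw)[1]) {
    abort("`trials` must have one row per row of `power`.")
  }
  if (!is.null(partitions) && length(partitions) < n_iterations) {
    abort("`partitions` must supply one assignment per iteration.")
  }

  out_conds <- present_conditions(trials, regime)
  C_centers <- basis_response(basis, basis$centers)
  n_cond <- length(out_conds)
  cond_rows <- lapply(out_conds, function(cond) trials$condition == cond)
  train_rows <- switch(regime,
    cross_training = trials$condition == "one_item",
    rep(TRUE, nrow(trials))
  )

  prof_sum <- array(0, dim = c(n_cond, k, n_time))
  prof_n <- array(0, dim = c(n_cond, k, n_time))
  part_regime <- if (regime == "within_condition") "within_condition" else "condition_neutral"

  for (it in seq_len(n_iterations)) {
    set <- if (is.null(partitions)) {
      partition_trials(trials, n_sets = n_sets, regime = part_regime)$set
    } else {
      partitions[[it]]
    }
    labels <- trials$bin_probed
    if (shuffle_labels) {
      for (cond in unique(trials$condition)) {
        for (s in seq_len(n_sets)) {
          idx <- which(trials$condition == cond & set == s)
          labels[idx] <- sample(labels[idx])
        }
      }
    }
    test_labels <- if (is.null(.test_scramble)) {
      labels
    } else {
      scramble_bins(labels, .test_scramble$fraction, k,
                    .test_scramble$redraw %||% "permute_within_set",
                    set = set)
    }

    for (t_i in seq_len(n_time)) {
      E <- pw[, , t_i]
      # per-set bin averages, computed once per iteration/time
      B_test <- lapply(seq_len(n_cond), function(ci) {
        lapply(seq_len(n_sets), function(s) {
          bin_avg(E, test_labels, which(cond_rows[[ci]] & set == s), k)
        })
      })
      A_train <- if (regime == "within_condition") {
        lapply(seq_len(n_cond), function(ci) {
          lapply(seq_len(n_sets), function(s) {
            bin_avg(E, labels, which(cond_rows[[ci]] & set == s), k)
          })
        })
      } else {
        one <- lapply(seq_len(n_sets), function(s) {
          bin_avg(E, labels, which(train_rows & set == s), k)
        })
        rep(list(one), n_cond)
      }
      for (f in seq_len(n_sets)) {
        train_sets <- setdiff(seq_len(n_sets), f)
        for (ci in seq_len(n_cond)) {
          B1 <- do.call(cbind, A_train[[ci]][train_sets])
          C1 <- do.call(cbind, rep(list(C_centers), length(train_sets)))
          W <- train_weights(B1, C1)
          C2 <- invert_model(W, B_test[[ci]][[f]])
          acc <- align_accumulate(C2, k)
          prof_sum[ci, , t_i] <- prof_sum[ci, , t_i] + acc$sum
          prof_n[ci, , t_i] <- prof_n[ci, , t_i] + acc$n
        }
      }
    }
  }

  og <- offset_grid(k)
  profiles <- (prof_sum / prof_n)[, og$order, , drop = FALSE]
  dimnames(profiles) <- list(out_conds, og$sorted, NULL)
  structure(
    list(
      profiles = profiles, offsets = og$sorted, conditions = out_conds,
      times = times, regime = regime, n_iterations = n_iterations,
      n_sets = n_sets, basis = basis, seed = seed,
      shuffle_labels = shuffle_labels
    ),
    class = "ctf_reconstruction"
  )
}

as_power_array <- function(power) {
  if (is.matrix(power)) {
    array(power, dim = c(dim(power), 1L))
  } else if (is.array(power) && length(dim(power)) == 3) {
    unclass(power)
  } else {
    abort("`power` must be a trials x electrodes matrix or a trials x electrodes x time array.")
  }
}

present_conditions <- function(trials, regime) {
  conds <- unique(trials$condition)
  if (regime == "cross_training") {
    if (!all(c("one_item", "two_item") %in% conds)) {
      abort("`cross_training` needs both one-item and two-item trials.")
    }
    "two_item"
  } else {
    conds
  }
}

# Randomize the labels of a random `fraction` of trials.
# "permute_within_set" randomly permutes the scrambled trials' labels among
# themselves within each partition set, preserving every set's label
# histogram exactly (so bin-averaged test matrices keep balanced counts);
# "all_bins" redraws uniformly over all k bins (may coincide with the
# truth); "other_bins" excludes the true bin.
scramble_bins <- function(labels, fraction, k,
                          redraw = c("permute_within_set", "all_bins", "other_bins"),
                          set = NULL) {
  redraw <- match.arg(redraw)
  if (fraction < 0 || fraction > 1) abort("`fraction` must lie in [0, 1].")
  n <- length(labels)
  pick <- sample.int(n, round(fraction * n))
  if (redraw == "permute_within_set") {
    if (is.null(set)) set <- rep(1L, n)
    for (s in unique(set[pick])) {
      idx <- pick[set[pick] == s]
      labels[idx] <- labels[idx][sample.int(length(idx))]
    }
  } else if (redraw == "all_bins") {
    labels[pick] <- sample.int(k, length(pick), replace = TRUE) - 1L
  } else {
    shift <- sample.int(k - 1L, length(pick), replace = TRUE)
    labels[pick] <- (labels[pick] + shift) %% k
  }
  labels
}

#' @export
print.ctf_reconstruction <- function(x, ...) {
  cat(sprintf(
    "<ctf_reconstruction> %s regime, %d iteration(s), conditions: %s, %d time point(s)\n",
    x$regime, x$n_iterations, paste(x$conditions, collapse = ", "),
    dim(x$profiles)[3]
  ))
  invisible(x)
}
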