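#' Partition trials into balanced training/test sets
#'
#' Randomly assigns trials to `n_sets` independent sets while equating the
#' number of trials per position bin within every set. Under the
#' `condition_neutral` regime the per-bin count is additionally equated
#' across conditions, so that training sets built by combining conditions
#' contain equal numbers of trials from each. Trials in excess of the
#' balanced count are left unassigned (`set = 0`); re-running with a
#' different seed re-randomizes which trials are excess, which is what the
#' iterative assignment scheme averages over.
#'
#' @param trials A trial tibble (see [sample_trial_positions()]); bin labels
#'   are taken from `bin_probed` and conditions from `condition`.
#' @param n_sets Number of sets (default 3).
#' @param regime `"condition_neutral"` (equate bin counts across
#'   conditions) or `"within_condition"` (equate within each condition
#'   separately).
#' @param seed Optional RNG seed.
#' @return A copy of `trials` with a `set` column (integer `0:n_sets`,
#'   0 = unassigned) and attributes `per_set_bin` (named per-condition
#'   count of trials per bin in each set) and `n_sets`.
#' @export
partition_trials <- function(trials, n_sets = 3,
                             regime = c("condition_neutral", "within_condition"),
                             seed = NULL) {
  regime <- match.arg(regime)
  n_sets <- assert_count(n_sets, "n_sets", min = 2L)
  local_seed(seed)
  conds <- unique(trials$condition)
  counts <- table(trials$condition, trials$bin_probed)
  if (regime == "condition_neutral") {
    per_set <- rep(min(counts) %/% n_sets, length(conds))
  } else {
    per_set <- apply(counts, 1, min)[conds] %/% n_sets
  }
  names(per_set) <- conds
  if (any(per_set < 1)) {
    bad <- counts[counts < n_sets, drop = FALSE]
    abort(paste0(
      "Too few trials to give every bin at least one trial per set. ",
      "Minimum per-bin count is ", min(counts), " for ", n_sets, " sets."
    ))
  }
  set <- integer(nrow(trials))
  for (cond in conds) {
    for (b in unique(trials$bin_probed)) {
      idx <- which(trials$condition == cond & trials$bin_probed == b)
      idx <- sample(idx)
      n_use <- n_sets * per_set[[cond]]
      set[idx[seq_len(n_use)]] <- rep(seq_len(n_sets), each = per_set[[cond]])
    }
  }
  out <- trials
  out$set <- set
  attr(out, "per_set_bin") <- per_set
  attr(out, "n_sets") <- n_sets
  out
}
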