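#' Channel-response profiles by inter-item distance
#'
#' Cross-trained analysis of two-item trials grouped by the angular
#' distance between the two items' position bins. The encoding model is
#' trained on one-item sets only and inverted on the held-out two-item set
#' separately for each inter-item distance. Before averaging, trials are
#' aligned so the unprobed item always sits clockwise of the probed
#' (tested) position: profiles from counter-clockwise configurations are
#' mirrored. On noiseless additive data the profile at distance `d` equals
#' the sum of two basis rows offset by `d` — two clear peaks at offsets 0
#' and 180 deg when the items are opposite, and a single double-amplitude
#' peak when they share a bin.
#'
#' @inheritParams run_iem
#' @return A tibble with `distance` (0, 45, 90, 135, 180 deg), `offset`
#'   (channel offset, deg), `response`, and `n_profiles` (number of
#'   bin x fold x iteration profiles averaged). Distances with no test
#'   trials are omitted with a warning.
#' @export
distance_profile <- function(power, trials, n_iterations = 10, seed = NULL,
                             basis = NULL, n_sets = 3) {
  basis <- basis %||% make_basis()
  k <- length(basis$centers)
  local_seed(seed)
  pw <- as_power_array(power)
  if (dim(pw)[3] != 1) abort("`distance_profile()` expects a single time point.")
  E_all <- pw[, , 1]
  if (!all(c("one_item", "two_item") %in% trials$condition)) {
    abort("`distance_profile()` needs both one-item and two-item trials.")
  }
  C_centers <- basis_response(basis, basis$centers)
  d8 <- (trials$bin_unprobed - trials$bin_probed) %% k
  half <- k %/% 2
  n_dist <- half + 1L
  prof_sum <- matrix(0, n_dist, k)
  prof_n <- matrix(0, n_dist, k)

  for (it in seq_len(n_iterations)) {
    set <- partition_trials(trials, n_sets = n_sets,
                            regime = "within_condition")$set
    for (f in seq_len(n_sets)) {
      train_sets <- setdiff(seq_len(n_sets), f)
      one <- trials$condition == "one_item"
      B1 <- do.call(cbind, lapply(train_sets, function(s) {
        bin_avg(E_all, trials$bin_probed, which(one & set == s), k)
      }))
      C1 <- do.call(cbind, rep(list(C_centers), length(train_sets)))
      W <- train_weights(B1, C1)
      for (d in 0:(k - 1L)) {
        test_idx <- which(trials$condition == "two_item" & set == f & d8 == d)
        if (!length(test_idx)) next
        B2 <- bin_avg(E_all, trials$bin_probed, test_idx, k)
        C2 <- invert_model(W, B2)
        mirror <- d > half
        row <- (if (mirror) k - d else d) + 1L
        for (b in which(!is.na(C2[1, ])) - 1L) {
          o <- (seq_len(k) - 1L)
          shifted <- C2[((o + b) %% k) + 1L, b + 1L]
          if (mirror) shifted <- shifted[((k - o) %% k) + 1L]
          prof_sum[row, ] <- prof_sum[row, ] + shifted
          prof_n[row, ] <- prof_n[row, ] + 1
        }
      }
    }
  }

  step <- 360 / k
  missing <- which(prof_n[, 1] == 0)
  if (length(missing)) {
    warn(sprintf("No two-item test trials at distance(s) %s deg; omitted.",
                 paste((missing - 1L) * step, collapse = ", ")))
  }
  og <- offset_grid(k)
  keep <- which(prof_n[, 1] > 0)
  out <- lapply(keep, function(row) {
    tibble(
      distance = (row - 1L) * step,
      offset = og$sorted,
      response = (prof_sum[row, ] / prof_n[row, ])[og$order],
      n_profiles = prof_n[row, og$order]
    )
  })
  dplyr::bind_rows(out)
}
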