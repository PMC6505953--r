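# Shared fixtures. Everything is generated in code; nothing is read from
# disk except where the IO round trips are themselves under test.

# small, fast study conditions for unit tests (not the canonical ones)
small_config <- function(n_subjects = 4, n_trials_per_condition = 192, ...) {
  sim_config(n_subjects = n_subjects,
             n_trials_per_condition = n_trials_per_condition, ...)
}

# trials pinned to exact bin centres (no jitter), n per bin, for exactness
# checks against the closed-form basis
center_trials <- function(n_per_bin = 3, k = 8, condition = "one_item") {
  bins <- rep(0:(k - 1L), each = n_per_bin)
  tibble::tibble(
    trial = seq_along(bins),
    condition = condition,
    bin_probed = bins,
    angle_probed = bins * (360 / k),
    bin_unprobed = NA_integer_,
    angle_unprobed = NA_real_
  )
}

# noiseless electrode data for a trial table under known weights
noiseless_power <- function(trials, W, basis = make_basis()) {
  C <- basis_response(basis, trials$angle_probed)
  two <- !is.na(trials$bin_unprobed)
  if (any(two)) {
    C[, two] <- C[, two] + basis_response(basis, trials$angle_unprobed[two])
  }
  t(W %*% C)
}

# the perfect aligned CTF (offsets -135..180) for a basis
perfect_ctf <- function(basis = make_basis()) {
  v <- basis_response(basis, 0)[, 1]        # response of each channel to 0 deg
  unname(v[c(6, 7, 8, 1, 2, 3, 4, 5)])      # reorder to offsets -135..180
}

# memoised canonical simulation studies shared by the acceptance tests
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_study <- function(which, n_samples = 1000) {
  key <- paste0(which, "_", n_samples)
  if (is.null(.acceptance_cache[[key]])) {
    cfg <- switch(which,
      equal = sim_config(),
      noise = sim_config(noise_sd_two_item = 2),
      amplitude = sim_config(amplitude_scale_two_item = 0.9)
    )
    .acceptance_cache[[key]] <- run_simulation_study(
      cfg, n_samples = n_samples, seed = match(which, c("equal", "noise", "amplitude")) * 1000L
    )
  }
  .acceptance_cache[[key]]
}
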