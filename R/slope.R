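#' Fold a channel-tuning function across equidistant channels
#'
#' Collapses an aligned channel-response profile over channels equidistant
#' from the tuned channel (offset 0): for the standard 8-channel basis,
#' responses at +/-45, +/-90, and +/-135 deg are averaged, while 0 and
#' 180 deg have no partner. Any even number of channels is supported.
#'
#' @param profile Numeric aligned profile ordered by ascending channel
#'   offset (`-135, -90, ..., 135, 180` for 8 channels — the order
#'   produced by [run_iem()]), optionally named by offset.
#' @return Named vector of responses at distances `0, step, ..., 180`.
#' @export
fold_profile <- function(profile) {
  k <- length(profile)
  if (k < 4 || k %% 2 != 0) {
    abort("`profile` must have an even number (>= 4) of channel offsets.")
  }
  p <- reorder_profile(profile)
  offs <- as.numeric(names(p))
  step <- 360 / k
  dists <- seq(0, 180, by = step)
  out <- vapply(dists, function(d) {
    mean(p[abs(offs) == d])
  }, numeric(1))
  names(out) <- dists
  out
}

reorder_profile <- function(profile) {
  k <- length(profile)
  step <- 360 / k
  grid <- seq(-180 + step, 180, by = step)
  if (!is.null(names(profile))) {
    got <- as.numeric(names(profile))
    if (!isTRUE(all.equal(sort(got), grid))) {
      abort(sprintf("Profile names must be the offsets %s.",
                    paste(grid, collapse = ", ")))
    }
    profile <- profile[order(got)]
  }
  names(profile) <- grid
  profile
}

#' CTF slope: spatial selectivity of a channel-tuning function
#'
#' Quantifies spatial selectivity as the slope of channel response against
#' channel position after folding equidistant channels together
#' ([fold_profile()]). The folded values are ordered by decreasing
#' angular distance from the tuned channel (for 8 channels: 180, 135, 90,
#' 45, 0 deg) and regressed on the unit-spaced ranks by ordinary least
#' squares; the slope of that line is returned. Higher slope means a
#' steeper, more selective tuning profile; a flat profile has slope 0.
#'
#' Note the x-axis is the unit-spaced rank, not degrees, so slopes are
#' scale-dependent: a noiseless exponent-25 profile has slope ~0.214, and
#' realistic band-power CTFs are typically an order of magnitude lower.
#'
#' @param profile An aligned profile over an even number of channel
#'   offsets (see [fold_profile()]), or an already-folded profile of
#'   `k/2 + 1` values ordered by increasing distance `0, ..., 180`.
#' @return The slope (dimensionless).
#' @examples
#' b <- make_basis()
#' perfect <- basis_response(b, 0)[c(6:8, 1:5)]  # offsets -135..180
#' ctf_slope(unname(perfect))
#' @export
ctf_slope <- function(profile) {
  folded <- if (length(profile) %% 2 == 1) {
    profile
  } else {
    fold_profile(profile)
  }
  y <- rev(unname(folded))   # decreasing distance: 180, ..., 45, 0
  x <- seq_along(y)
  sum((x - mean(x)) * y) / sum((x - mean(x))^2)
}

#' CTF slope time courses from a reconstruction
#'
#' @param recon A `ctf_reconstruction` from [run_iem()].
#' @return A tibble with `condition`, `time`, `slope`.
#' @export
ctf_slopes <- function(recon) {
  stopifnot(inherits(recon, "ctf_reconstruction"))
  grid <- expand.grid(
    condition = recon$conditions, time = recon$times,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$slope <- as.vector(vapply(
    seq_along(recon$times),
    function(t_i) vapply(seq_along(recon$conditions),
                         function(ci) ctf_slope(recon$profiles[ci, , t_i]),
                         numeric(1)),
    numeric(length(recon$conditions))
  ))
  as_tibble(grid[order(grid$condition, grid$time), ])
}
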