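# Angular helpers. All angles in degrees unless noted.

#' Unsigned circular distance between angles, in degrees
#'
#' @param a,b Angles in degrees.
#' @return Distances in `[0, 180]`.
#' @keywords internal
circ_dist <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

#' Signed circular difference mapped to (-180, 180]
#'
#' @param a,b Angles in degrees; result is `a - b` on the circle.
#' @keywords internal
circ_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Set the RNG seed for the remainder of the calling function only.
local_seed <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) {
    withr::local_seed(seed, .local_envir = env)
  }
  invisible(seed)
}

# Independent sub-stream seeds, reproducibly derived from the current RNG
# state. Kept strictly below 2^31 so they survive as R integers.
split_seeds <- function(n) {
  sample.int(.Machine$integer.max - 1L, n)
}

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x < min || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}
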