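#' Construct the spatial channel basis set
#'
#' Builds the graded spatial filters ("channels") used by the inverted
#' encoding model. Each channel's predicted response across angular position
#' is a half sinusoid raised to a power, centred on that channel's preferred
#' location, so that a channel responds maximally (1) to stimuli at its
#' centre, falls off smoothly with angular distance, and is 0 at 180deg.
#' With `n_channels = 8` the centres sit at 0deg, 45deg, ..., 315deg,
#' matching an 8-bin position design.
#'
#' At angular distance `d` from a channel's centre the predicted response is
#' `cos(d / 2)^exponent` (the circularly shifted half sinusoid). The default
#' exponent of 25 gives a narrow tuning profile whose value one bin away
#' (45deg) is about 0.138.
#'
#' @param n_channels Number of spatial channels (>= 2).
#' @param exponent Power to which the half sinusoid is raised (> 0).
#' @return An object of class `basis_set`: a list with `responses`
#'   (`n_channels` x 360 matrix of predicted responses at integer angles
#'   0deg-359deg), `centers` (channel centre angles, degrees), and
#'   `exponent`.
#' @examples
#' b <- make_basis()
#' plot(0:359, b$responses[1, ], type = "l")
#' @export
make_basis <- function(n_channels = 8, exponent = 25) {
  n_channels <- assert_count(n_channels, "n_channels", min = 2L)
  if (length(exponent) != 1L || !is.finite(exponent) || exponent <= 0) {
    abort("`exponent` must be a single positive number.")
  }
  centers <- (seq_len(n_channels) - 1L) * (360 / n_channels)
  responses <- basis_response(
    structure(list(centers = centers, exponent = exponent),
              class = "basis_set"),
    0:359
  )
  structure(
    list(responses = responses, centers = centers, exponent = exponent),
    class = "basis_set"
  )
}

#' Evaluate channel responses at arbitrary angles
#'
#' Closed-form evaluation of the basis at continuous angular positions
#' (the stored `responses` matrix holds only integer angles).
#'
#' @param basis A `basis_set`.
#' @param angles Angular positions in degrees.
#' @return A `n_channels` x `length(angles)` matrix of predicted responses.
#' @export
basis_response <- function(basis, angles) {
  d <- outer(basis$centers, angles, circ_dist)
  r <- cos(deg2rad(d) / 2)^basis$exponent
  rownames(r) <- paste0("channel_", seq_along(basis$centers))
  r
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf(
    "<basis_set> %d spatial channels, half-sinusoid exponent %g\n",
    length(x$centers), x$exponent
  ))
  cat("centers (deg):", paste(x$centers, collapse = ", "), "\n")
  invisible(x)
}
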