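#' Average a slope time course over a time window
#'
#' @param slopes Subjects x time matrix, or a per-subject vector already
#'   averaged (returned unchanged).
#' @param times Time axis in ms (length `ncol(slopes)`).
#' @param window Length-2 `c(from, to)` in ms, inclusive.
#' @return One value per subject.
#' @export
window_average <- function(slopes, times = NULL, window = NULL) {
  if (is.null(dim(slopes))) return(slopes)
  slopes <- as.matrix(slopes)
  if (is.null(window)) return(rowMeans(slopes))
  if (is.null(times) || length(times) != ncol(slopes)) {
    abort("`times` must match the columns of `slopes`.")
  }
  keep <- times >= window[1] & times <= window[2]
  if (!any(keep)) abort("`window` contains no time points.")
  rowMeans(slopes[, keep, drop = FALSE])
}

#' Paired comparison of window-averaged CTF selectivity
#'
#' Two-sided paired t test on per-subject CTF slopes averaged over a time
#' window, the planned comparison used for condition differences (e.g.
#' one-item vs two-item load, or two-item vs simulated switching). No
#' multiple-testing correction is applied across planned windows; raw p
#' values are reported.
#'
#' @param slopes_a,slopes_b Matched per-subject slope vectors, or
#'   subjects x time matrices combined with `times` and `window`.
#' @param times,window Optional time axis and window (ms) when matrices
#'   are supplied; see [window_average()].
#' @return A one-row tibble: `estimate` (mean a - b), `statistic` (paired
#'   t), `df`, `p_value`, and the window bounds.
#' @export
window_compare <- function(slopes_a, slopes_b, times = NULL, window = NULL) {
  a <- window_average(slopes_a, times, window)
  b <- window_average(slopes_b, times, window)
  if (length(a) != length(b)) {
    abort("`slopes_a` and `slopes_b` must cover the same subjects.")
  }
  d <- a - b
  n <- length(d)
  m <- mean(d)
  s <- sd(d)
  if (s == 0 || s < 1e-12 * abs(m)) {
    # zero within-pair variance: t degenerates
    tstat <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    tstat <- m / (s / sqrt(n))
    p <- 2 * pt(-abs(tstat), df = n - 1)
  }
  tibble(
    estimate = m,
    statistic = tstat,
    df = n - 1,
    p_value = p,
    window_from = if (is.null(window)) NA_real_ else window[1],
    window_to = if (is.null(window)) NA_real_ else window[2]
  )
}
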