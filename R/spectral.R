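#' Epoched time-series and power containers
#'
#' Light containers for epoched electrophysiology. `epoched_timeseries()`
#' holds voltage-like data as a trials x electrodes x samples array with a
#' uniform sampling rate; `epoched_power()` holds instantaneous band power
#' on the same layout, together with the band edges.
#'
#' @param data A 3-D numeric array, trials x electrodes x samples.
#' @param sampling_rate Sampling rate in Hz.
#' @param times Sample times in ms relative to stimulus onset; length must
#'   equal `dim(data)[3]`.
#' @param band Numeric length-2 `(low, high)` band edges in Hz, or `NULL`
#'   for power-like data with no spectral provenance (e.g. synthetic data).
#' @param edge_samples Number of samples at each epoch edge flagged as
#'   unreliable (within one filter length of the boundary).
#' @return An `epoched_timeseries` / `epoched_power` object: the array with
#'   `times` (and for power, `band`, `edge_samples`) attached as attributes.
#' @export
epoched_timeseries <- function(data, sampling_rate, times = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (is.null(times)) {
    times <- (seq_len(dim(data)[3]) - 1L) * 1000 / sampling_rate
  }
  if (length(times) != dim(data)[3]) {
    abort("`times` must have one entry per sample.")
  }
  structure(data, times = times, sampling_rate = sampling_rate,
            class = "epoched_timeseries")
}

#' @rdname epoched_timeseries
#' @export
epoched_power <- function(data, times, band = NULL, edge_samples = 0L) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (length(times) != dim(data)[3]) {
    abort("`times` must have one entry per sample.")
  }
  structure(data, times = times, band = band,
            edge_samples = as.integer(edge_samples), class = "epoched_power")
}

#' @export
print.epoched_power <- function(x, ...) {
  d <- dim(x)
  band <- attr(x, "band")
  cat(sprintf("<epoched_power> %d trials x %d electrodes x %d samples%s\n",
              d[1], d[2], d[3],
              if (is.null(band)) "" else sprintf(", band %g-%g Hz", band[1], band[2])))
  invisible(x)
}

#' @export
print.epoched_timeseries <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<epoched_timeseries> %d trials x %d electrodes x %d samples @ %g Hz\n",
              d[1], d[2], d[3], attr(x, "sampling_rate")))
  invisible(x)
}

# Analytic signal of a real vector via the frequency-domain construction:
# double the positive frequencies, zero the negative ones. No installed R
# package exposes this primitive, so it is implemented here directly.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous band-limited power of epoched data
#'
#' Per trial and electrode: the data are band-pass filtered with a
#' zero-phase (forward-backward) Hamming-window FIR filter, the complex
#' analytic signal is obtained via the Hilbert transform, and instantaneous
#' power is the squared complex magnitude. The filter order is
#' `3 * floor(sampling_rate / low)`, the conventional heuristic for two-way
#' FIR filtering of EEG; samples within one filter length of the epoch
#' edges are flagged in the `edge_samples` attribute and should not be
#' interpreted.
#'
#' @param ts An [epoched_timeseries()].
#' @param low,high Band edges in Hz; `0 < low < high < ` Nyquist.
#' @return An [epoched_power()] at the full sampling rate.
#' @examples
#' x <- array(sin(2 * pi * 10 * seq(0, 2, by = 1 / 500)), c(1, 1, 1001))
#' ep <- band_power(epoched_timeseries(x, 500), 8, 12)
#' @export
band_power <- function(ts, low, high) {
  stopifnot(inherits(ts, "epoched_timeseries"))
  rate <- attr(ts, "sampling_rate")
  if (!(low > 0 && high > low && high < rate / 2)) {
    abort("Band edges must satisfy 0 < low < high < Nyquist.")
  }
  ord <- 3L * (rate %/% low)
  n_samp <- dim(ts)[3]
  if (n_samp <= 3L * ord) {
    abort(sprintf(
      "Epoch too short (%d samples) for a zero-phase FIR of order %d.",
      n_samp, ord
    ))
  }
  fir <- signal::fir1(ord, c(low, high) / (rate / 2), type = "pass")
  d <- dim(ts)
  out <- array(NA_real_, d)
  for (tr in seq_len(d[1])) {
    for (el in seq_len(d[2])) {
      filt <- signal::filtfilt(fir, ts[tr, el, ])
      out[tr, el, ] <- Mod(analytic_signal(filt))^2
    }
  }
  epoched_power(out, times = attr(ts, "times"), band = c(low, high),
                edge_samples = ord)
}

#' Decimate an instantaneous power array
#'
#' Keeps every k-th sample of the already-computed power series (pure
#' decimation, no re-averaging), so downsampling cannot alter the power
#' values that are retained.
#'
#' @param ep An [epoched_power()].
#' @param interval_ms Desired sampling interval in ms; must be an integer
#'   multiple of the native sample period.
#' @return An [epoched_power()] at the decimated rate.
#' @export
downsample_power <- function(ep, interval_ms) {
  stopifnot(inherits(ep, "epoched_power"))
  times <- attr(ep, "times")
  native <- unique(round(diff(times), 10))
  if (length(native) != 1) abort("`ep` must be uniformly sampled.")
  fac <- interval_ms / native
  if (abs(fac - round(fac)) > 1e-8 || fac < 1) {
    abort(sprintf("`interval_ms` (%g) must be an integer multiple of the native period (%g ms).",
                  interval_ms, native))
  }
  fac <- as.integer(round(fac))
  keep <- seq(1L, dim(ep)[3], by = fac)
  epoched_power(unclass(ep)[, , keep, drop = FALSE], times = times[keep],
                band = attr(ep, "band"),
                edge_samples = ceiling(attr(ep, "edge_samples") / fac))
}

#' Band-limited power in a sweep of narrow bands
#'
#' Applies [band_power()] in contiguous `width`-Hz bands from `low` to
#' `high` (defaults: 1-Hz bands 4-5, 5-6, ..., 49-50 Hz).
#'
#' @param ts An [epoched_timeseries()].
#' @param low,high Sweep limits in Hz.
#' @param width Band width in Hz.
#' @param interval_ms Optional decimation interval applied to every band.
#' @return A named list of [epoched_power()] objects, one per band.
#' @export
band_sweep <- function(ts, low = 4, high = 50, width = 1, interval_ms = NULL) {
  starts <- seq(low, high - width, by = width)
  out <- lapply(starts, function(l) {
    ep <- band_power(ts, l, l + width)
    if (!is.null(interval_ms)) ep <- downsample_power(ep, interval_ms)
    ep
  })
  names(out) <- sprintf("%g-%g Hz", starts, starts + width)
  out
}
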