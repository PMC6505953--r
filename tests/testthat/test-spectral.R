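sine_epoch <- function(freqs, amps, rate = 500, dur = 2.5) {
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  x <- rowSums(mapply(function(f, a) a * sin(2 * pi * f * t), freqs, amps))
  epoched_timeseries(array(x, c(1, 1, length(t))), sampling_rate = rate)
}

interior <- function(ep) {
  edge <- attr(ep, "edge_samples")
  as.vector(ep[1, 1, (edge + 1):(dim(ep)[3] - edge)])
}

test_that("in-band sinusoid power equals squared amplitude; out-of-band is rejected", {
  ep10 <- band_power(sine_epoch(10, 2), 8, 12)
  expect_true(all(abs(interior(ep10) - 4) / 4 < 0.01))
  ep20 <- band_power(sine_epoch(20, 2), 8, 12)
  expect_true(all(interior(ep20) < 0.01 * 4))
  expect_true(all(unclass(ep10) >= 0))
})

test_that("an out-of-band component does not disturb in-band power", {
  mix <- band_power(sine_epoch(c(10, 40), c(1.5, 3)), 8, 12)
  pure <- band_power(sine_epoch(10, 1.5), 8, 12)
  expect_true(all(abs(interior(mix) - interior(pure)) / interior(pure) < 0.02))
})

test_that("band-pass filtering is zero phase", {
  rate <- 500
  t <- seq(0, 2.5 - 1 / rate, by = 1 / rate)
  x <- sin(2 * pi * 10 * t)
  fir <- signal::fir1(3L * (rate %/% 8L), c(8, 12) / (rate / 2), type = "pass")
  filt <- signal::filtfilt(fir, x)
  keep <- 300:950
  cc <- stats::ccf(filt[keep], x[keep], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("downsampling decimates the already-computed power exactly", {
  ep <- band_power(sine_epoch(10, 1), 8, 12)
  ds <- downsample_power(ep, 20)
  expect_equal(diff(attr(ds, "times"))[1], 20)
  expect_equal(dim(ds)[3], ceiling(dim(ep)[3] / 10))
  # retained values are an exact subsequence
  expect_identical(as.vector(ds[1, 1, ]), as.vector(ep[1, 1, seq(1, dim(ep)[3], by = 10)]))
  # identity at the native period
  expect_identical(unclass(downsample_power(ep, 2)), unclass(ep))
  expect_error(downsample_power(ep, 5), "integer multiple")
})

test_that("band sweep covers 46 one-hertz bands with the stated edges", {
  ts <- sine_epoch(10, 1)
  sw <- band_sweep(ts)
  expect_length(sw, 46)
  expect_equal(attr(sw[[1]], "band"), c(4, 5))
  expect_equal(attr(sw[[46]], "band"), c(49, 50))
  one <- band_sweep(ts, low = 8, high = 12, width = 4)
  expect_equal(unclass(one[[1]]), unclass(band_power(ts, 8, 12)))
})

test_that("white-noise band power matches each filter's analytic prediction", {
  # for zero-mean white noise through a zero-phase filter with response
  # |H(f)|^2, the mean instantaneous analytic-signal power is
  # 2 * sigma^2 * mean_f |H(f)|^4; every band of the sweep should sit on
  # its own prediction (bands differ in effective bandwidth because the
  # filter order scales with 1 / low-cutoff)
  # (bands below ~8 Hz are excluded: on a 2.5-s epoch their filter length
  # leaves too little transient-free interior to estimate mean power)
  set.seed(4)
  rate <- 500; n <- 1250; n_tr <- 24
  x <- array(rnorm(n_tr * n), c(n_tr, 1, n))
  ts <- epoched_timeseries(x, rate)
  sw <- band_sweep(ts, low = 8, high = 50, width = 2)
  ratios <- vapply(seq_along(sw), function(i) {
    ep <- sw[[i]]
    band <- attr(ep, "band")
    ord <- 3L * (rate %/% band[1])
    h <- signal::fir1(ord, band / (rate / 2), type = "pass")
    H2 <- Mod(fft(c(h, rep(0, 8192 - length(h)))))^2   # filtfilt: |H|^2
    expected <- 2 * mean(H2^2)
    edge <- round(1.5 * attr(ep, "edge_samples"))
    mean(ep[, 1, (edge + 1):(dim(ep)[3] - edge)]) / expected
  }, numeric(1))
  expect_true(all(ratios > 0.85 & ratios < 1.15))
})

test_that("invalid bands and too-short epochs are rejected", {
  ts <- sine_epoch(10, 1)
  expect_error(band_power(ts, 12, 8), "Nyquist")
  expect_error(band_power(ts, 8, 300), "Nyquist")
  short <- epoched_timeseries(array(rnorm(100), c(1, 1, 100)), 500)
  expect_error(band_power(short, 8, 12), "short")
})
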