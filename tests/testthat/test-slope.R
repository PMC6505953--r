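test_that("slope of the perfect CTF matches an independent regression oracle", {
  prof <- perfect_ctf()
  folded <- fold_profile(prof)
  # independent oracle: lm on the folded values ordered by decreasing distance
  oracle <- unname(stats::coef(stats::lm(rev(folded) ~ seq_along(folded)))[2])
  expect_equal(ctf_slope(prof), oracle, tolerance = 1e-12)
  expect_equal(ctf_slope(prof), 0.213816, tolerance = 1e-6)
  expect_equal(ctf_slope(folded), ctf_slope(prof))
})

test_that("flat and negated profiles behave as expected", {
  expect_equal(ctf_slope(rep(3.7, 8)), 0)
  expect_equal(ctf_slope(-perfect_ctf()), -ctf_slope(perfect_ctf()))
})

test_that("the slope operator is linear in the profile", {
  set.seed(1)
  for (i in 1:10) {
    p <- rnorm(8); q <- rnorm(8); a <- rnorm(1); b <- rnorm(1)
    expect_equal(ctf_slope(a * p + b * q),
                 a * ctf_slope(p) + b * ctf_slope(q), tolerance = 1e-12)
  }
})

test_that("folding averages the symmetric offsets", {
  prof <- c(-135, -90, -45, 0, 45, 90, 135, 180)  # values = own offsets
  f <- fold_profile(prof)
  expect_equal(unname(f), c(0, 0, 0, 0, 180))
  named <- rev(prof)
  names(named) <- rev(c(-135, -90, -45, 0, 45, 90, 135, 180))
  expect_equal(fold_profile(named), f)   # name-aware reordering
  expect_error(ctf_slope(1:2), "even number")
})

test_that("ctf_slopes tidies a reconstruction into condition x time rows", {
  subj <- generate_subject(small_config(), seed = 2)
  rec <- run_iem(subj$electrode_data, subj$trials, n_iterations = 1, seed = 3)
  sl <- ctf_slopes(rec)
  expect_named(sl, c("condition", "time", "slope"))
  expect_equal(nrow(sl), 2)
  expect_equal(sl$slope[sl$condition == "one_item"],
               ctf_slope(rec$profiles["one_item", , 1]))
})
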