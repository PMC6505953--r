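test_that("noiseless one-item trials at channel centres reproduce weight columns", {
  cfg <- small_config(noise_sd_one_item = 0)
  subj <- generate_subject(cfg, condition = "one_item", seed = 1)
  # a trial at a channel centre drives only that channel (basis is a unit
  # vector there up to cross-channel leakage cos(22.5)^25 etc.)
  basis <- subj$basis
  i <- which.min(ctfiem:::circ_dist(subj$trials$angle_probed,
                                    subj$trials$bin_probed * 45))
  expected <- subj$true_weights %*% basis_response(basis, subj$trials$angle_probed[i])
  expect_equal(subj$electrode_data[i, ], expected[, 1], tolerance = 1e-12)
})

test_that("two-item responses are additive and amplitude scaling applies to them", {
  cfg1 <- small_config(noise_sd_one_item = 0, noise_sd_two_item = 0)
  cfg9 <- small_config(noise_sd_one_item = 0, noise_sd_two_item = 0,
                       amplitude_scale_two_item = 0.9)
  s1 <- generate_subject(cfg1, seed = 5)
  s9 <- generate_subject(cfg9, seed = 5)
  two <- s1$trials$condition == "two_item"
  # additivity: electrode row equals W (c(theta1) + c(theta2))
  basis <- s1$basis
  i <- which(two)[1]
  expected <- s1$true_weights %*%
    (basis_response(basis, s1$trials$angle_probed[i]) +
       basis_response(basis, s1$trials$angle_unprobed[i]))
  expect_equal(s1$electrode_data[i, ], expected[, 1], tolerance = 1e-12)
  # same seed, amplitude 0.9: two-item rows scale, one-item rows unchanged
  expect_equal(s9$electrode_data[two, ], 0.9 * s1$electrode_data[two, ],
               tolerance = 1e-12)
  expect_equal(s9$electrode_data[!two, ], s1$electrode_data[!two, ])
})

test_that("condition noise SDs act on the right condition", {
  cfg <- small_config(noise_sd_one_item = 0, noise_sd_two_item = 3)
  s <- generate_subject(cfg, seed = 7)
  noiseless <- noiseless_power(s$trials, s$true_weights, s$basis)
  resid <- s$electrode_data - noiseless
  one <- s$trials$condition == "one_item"
  expect_equal(max(abs(resid[one, ])), 0)
  expect_equal(sd(resid[!one, ]), 3, tolerance = 0.05)
})

test_that("weights lie in [0,1] and are shared across conditions", {
  s <- generate_subject(small_config(), seed = 3)
  expect_true(all(s$true_weights >= 0 & s$true_weights <= 1))
  expect_equal(dim(s$true_weights), c(30, 8))
  expect_equal(nrow(s$electrode_data), nrow(s$trials))
})

test_that("timecourse datasets carry tuning only inside the stated window", {
  cfg <- small_config(noise_sd_one_item = 0)
  ds <- generate_timecourse_dataset(cfg, 250, 750,
                                    times = seq(-100, 900, by = 100),
                                    seed = 11)
  times <- attr(ds$power, "times")
  inside <- times >= 250 & times <= 750
  # outside the window: pure noise, here exactly zero
  expect_true(all(ds$power[, , !inside] == 0))
  expect_true(all(apply(ds$power[, , inside, drop = FALSE], 3, sd) > 0))
  expect_error(generate_timecourse_dataset(cfg, 500, 500), "onset")
})
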