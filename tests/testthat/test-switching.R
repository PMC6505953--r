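test_that("fraction 0 reproduces the standard reconstruction exactly", {
  subj <- generate_subject(small_config(), condition = "one_item", seed = 1)
  parts <- lapply(1:2, function(i) {
    partition_trials(subj$trials, regime = "within_condition", seed = 10 + i)$set
  })
  base <- run_iem(subj$electrode_data, subj$trials, regime = "within_condition",
                  n_iterations = 2, partitions = parts)
  sw <- simulate_switching(subj$electrode_data, subj$trials, fraction = 0,
                           n_iterations = 2, partitions = parts)
  expect_equal(unname(sw$profiles), unname(base$profiles))
  expect_equal(sw$conditions, "switching")
  expect_error(simulate_switching(subj$electrode_data, subj$trials, fraction = 1.2),
               "fraction")
})

test_that("full scrambling abolishes selectivity on average", {
  subj <- generate_subject(small_config(noise_sd_one_item = 0.5),
                           condition = "one_item", seed = 2)
  slopes <- vapply(1:40, function(i) {
    sw <- simulate_switching(subj$electrode_data, subj$trials, fraction = 1,
                             n_iterations = 1, seed = 100 + i)
    ctf_slope(sw$profiles[1, , 1])
  }, numeric(1))
  expect_lt(abs(mean(slopes)), 2 * sd(slopes) / sqrt(length(slopes)))
})

test_that("switching slope scales with the unscrambled fraction on noiseless data", {
  cfg <- small_config(noise_sd_one_item = 0)
  ratios <- vapply(1:20, function(i) {
    subj <- generate_subject(cfg, condition = "one_item", seed = 200 + i)
    parts <- list(partition_trials(subj$trials, regime = "within_condition")$set)
    base <- run_iem(subj$electrode_data, subj$trials, regime = "within_condition",
                    n_iterations = 1, partitions = parts)
    sw <- simulate_switching(subj$electrode_data, subj$trials, fraction = 0.5,
                             n_iterations = 1, partitions = parts, seed = 300 + i)
    ctf_slope(sw$profiles[1, , 1]) / ctf_slope(base$profiles[1, , 1])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.5), 0.03)
})

test_that("compare_switching delegates to the paired window comparison", {
  a <- rnorm(12, 0.08, 0.01)
  res <- compare_switching(a, a)
  expect_equal(res$statistic, 0)
  m <- matrix(rnorm(12 * 20, 0.08, 0.01), 12)
  res2 <- compare_switching(m, m - 0.02, times = seq(0, 1900, by = 100))
  expect_equal(res2$window, c("delay", "late"))
  expect_true(all(res2$statistic > 0))
  expect_true(all(res2$p_value < 0.001))
})

test_that("switching study distinguishes concurrent truth at reduced per-item amplitude", {
  ss <- switching_study(sim_config(n_subjects = 8), truth = "concurrent",
                        amplitude_per_item = 0.75, n_samples = 4,
                        n_iterations = 2, seed = 3)
  expect_true(all(ss$samples$statistic > 0))
  expect_equal(nrow(ss$samples), 4)
})
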