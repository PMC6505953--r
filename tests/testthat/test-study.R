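test_that("the compiled condition-neutral core agrees exactly with the R path", {
  cfg <- small_config()
  subj <- generate_subject(cfg, seed = 11)
  trials <- subj$trials
  E <- subj$electrode_data
  parts <- lapply(1:3, function(i) {
    partition_trials(trials, regime = "condition_neutral", seed = 60 + i)$set
  })
  rec <- run_iem(E, trials, regime = "condition_neutral", n_iterations = 3,
                 partitions = parts)
  sl <- ctf_slopes(rec)
  one <- trials$condition == "one_item"
  res <- ctfiem:::cpp_iem_cn_slopes(
    E[one, ], E[!one, ], trials$bin_probed[one], trials$bin_probed[!one],
    sapply(parts, function(p) p[one]), sapply(parts, function(p) p[!one]),
    ctfiem:::neutral_projector(cfg)
  )
  expect_equal(res$slope_one, sl$slope[sl$condition == "one_item"],
               tolerance = 1e-12)
  expect_equal(res$slope_two, sl$slope[sl$condition == "two_item"],
               tolerance = 1e-12)
  # profiles agree too (compiled raw-offset order 0,45,...,315)
  raw_order <- match(c(0, 45, 90, 135, 180, -135, -90, -45), rec$offsets)
  expect_equal(as.vector(res$profile_one), rec$profiles["one_item", raw_order, 1],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("compiled and R study engines agree statistically", {
  cfg <- sim_config(n_subjects = 6, n_trials_per_condition = 192)
  st_cpp <- run_simulation_study(cfg, n_samples = 400, seed = 1, n_iterations = 2)
  st_r <- run_simulation_study(cfg, n_samples = 25, seed = 2, n_iterations = 2,
                               engine = "r")
  for (col in c("mean_slope_one_item", "mean_slope_two_item")) {
    se <- sd(st_r$samples[[col]]) / sqrt(nrow(st_r$samples))
    expect_lt(abs(mean(st_r$samples[[col]]) - mean(st_cpp$samples[[col]])), 4 * se)
  }
})

test_that("the compiled normal generator is sound", {
  z <- ctfiem:::cpp_ziggurat_normals(2e5, 123)
  expect_equal(mean(z), 0, tolerance = 0.01)
  expect_equal(sd(z), 1, tolerance = 0.01)
  expect_equal(mean(z^3), 0, tolerance = 0.03)
  expect_equal(mean(z^4), 3, tolerance = 0.1)
  expect_lt(abs(mean(abs(z) > 3) - 2 * pnorm(-3)), 4e-4)  # ~3 binomial SEs
  # chi-square goodness of fit on equiprobable normal bins
  breaks <- qnorm(seq(0, 1, length.out = 51))
  obs <- table(cut(z, breaks))
  chi <- sum((obs - length(z) / 50)^2 / (length(z) / 50))
  expect_lt(chi, qchisq(0.999, df = 49))
})

test_that("study results are reproducible and internally consistent", {
  cfg <- sim_config(n_subjects = 6, n_trials_per_condition = 192)
  a <- run_simulation_study(cfg, n_samples = 30, seed = 42, n_iterations = 2)
  b <- run_simulation_study(cfg, n_samples = 30, seed = 42, n_iterations = 2)
  expect_identical(a$samples, b$samples)
  s <- a$summary
  expect_equal(s$prop_one_gt_two + s$prop_two_gt_one, s$prop_significant)
  expect_true(all(s[, c("prop_significant", "prop_one_gt_two",
                        "prop_two_gt_one")] >= 0 &
                    s[, c("prop_significant", "prop_one_gt_two",
                          "prop_two_gt_one")] <= 1))
  # per-sample p values match the t statistics
  expect_equal(a$samples$p_value, 2 * pt(-abs(a$samples$statistic), df = 5))
})

test_that("non-default channel counts are routed to the R engine", {
  cfg <- sim_config(n_subjects = 3, n_trials_per_condition = 36, n_channels = 6)
  expect_error(run_simulation_study(cfg, n_samples = 2, seed = 1), "8-channel")
  st <- run_simulation_study(cfg, n_samples = 2, seed = 1, n_iterations = 1,
                             engine = "r")
  expect_equal(nrow(st$samples), 2)
  expect_true(all(is.finite(st$samples$statistic)))
})
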