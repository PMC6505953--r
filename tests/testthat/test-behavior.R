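test_that("response error wraps to (-180, 180] with the boundary at +180", {
  expect_equal(response_error(10, 350), 20)
  expect_equal(response_error(45, 45), 0)
  expect_equal(response_error(0, 180), 180)
  expect_equal(response_error(179, 0), 179)
  expect_equal(response_error(181, 0), -179)
  expect_equal(response_error(c(10, 0), c(350, 180)), c(20, 180))
})

test_that("kappa and circular s.d. conversions invert each other", {
  for (sd_deg in c(2, 6, 15, 40)) {
    expect_equal(vm_sd_from_kappa(vm_kappa_from_sd(sd_deg)), sd_deg,
                 tolerance = 1e-6)
  }
  set.seed(1)
  x <- rvonmises(20000, 0, vm_kappa_from_sd(10))
  r <- sqrt(mean(cos(x * pi / 180))^2 + mean(sin(x * pi / 180))^2)
  expect_equal(sqrt(-2 * log(r)) * 180 / pi, 10, tolerance = 0.3)
})

test_that("behavioral generator hits its degenerate limits", {
  # pure guessing: indistinguishable from uniform
  g <- generate_behavioral_errors(6, p_guess = 1, n_trials = 10000, seed = 2)
  expect_gt(suppressWarnings(
    stats::ks.test(g$error, "punif", -180, 180)$p.value), 0.01)
  expect_true(all(g$component == "guess"))
  # precise target responses only
  p <- generate_behavioral_errors(0.6, n_trials = 1000, seed = 3)
  expect_true(all(abs(p$error) < 5))
  expect_error(generate_behavioral_errors(6, p_guess = 0.7, p_swap = 0.5,
                                          n_trials = 100), "<= 1")
})

test_that("two-component fit recovers degenerate compositions", {
  set.seed(4)
  uniform <- runif(5000, -180, 180)
  fit_u <- fit_mixture2(uniform)
  expect_true(fit_u$p_guess >= 0.95)
  precise <- generate_behavioral_errors(3, n_trials = 2000, seed = 5)$error
  fit_p <- fit_mixture2(precise)
  expect_lt(fit_p$p_guess, 0.02)
  expect_equal(fit_p$sd, 3, tolerance = 0.3)
  expect_error(fit_mixture2(rnorm(10)), "20 observations")
})

test_that("three-component fit pins swaps at their true boundary values", {
  # all responses at the non-target location (offsets well away from 0)
  set.seed(10)
  off <- response_error(runif(2000, 90, 270), 0)
  errs <- response_error(off + rvonmises(2000, 0, vm_kappa_from_sd(4)), 0)
  fit <- fit_mixture3(errs, off)
  expect_gt(fit$p_swap, 0.9)
  # swap-free data: two- and three-component fits agree, p_swap ~ 0
  g <- generate_behavioral_errors(8, p_guess = 0.15, n_trials = 4000, seed = 6)
  f2 <- fit_mixture2(g$error)
  f3 <- fit_mixture3(g$error, g$nontarget_offset)
  expect_lt(f3$p_swap, 0.03)
  expect_equal(f3$sd, f2$sd, tolerance = 0.5)
  expect_equal(f3$p_guess, f2$p_guess, tolerance = 0.03)
})

test_that("fitted likelihood dominates the generating parameters", {
  g <- generate_behavioral_errors(6, p_guess = 0.1, p_swap = 0.2,
                                  n_trials = 2000, seed = 7)
  fit <- fit_mixture3(g$error, g$nontarget_offset)
  kappa_true <- vm_kappa_from_sd(6)
  ll_true <- -ctfiem:::mixture_nll(
    c(log(kappa_true), stats::qlogis(0.1), stats::qlogis(0.2 / 0.9)),
    g$error, g$nontarget_offset
  )
  expect_gte(fit$log_likelihood, ll_true - 1e-6)
  expect_true(fit$converged)
  # mixture weights stay in the simplex
  expect_lte(fit$p_guess + fit$p_swap, 1)
})

test_that("same-bin analysis computes errors against both items", {
  cfg <- sim_config(n_trials_per_condition = 320, min_item_separation = 0.5)
  tr <- sample_trial_positions(cfg, "two_item", seed = 8)
  # responses exactly at the probed item
  res <- same_bin_analysis(tr, tr$angle_probed)
  sb <- res$by_subject[res$by_subject$subset == "same_bin", ]
  expect_equal(sb$mean_abs_error_probed, 0)
  sep <- ctfiem:::circ_dist(tr$angle_probed, tr$angle_unprobed)
  same <- tr$bin_probed == tr$bin_unprobed
  expect_equal(sb$mean_abs_error_unprobed, mean(sep[same]))
  # responses at the midpoint of items d apart: both errors d/2
  mid <- (tr$angle_probed + response_error(tr$angle_unprobed, tr$angle_probed) / 2) %% 360
  res_mid <- same_bin_analysis(tr, mid)
  cl <- res_mid$by_subject[res_mid$by_subject$subset == "close", ]
  expect_equal(cl$mean_abs_error_probed, cl$mean_abs_error_unprobed, tolerance = 1e-10)
  expect_lt(cl$mean_abs_error_probed, 5)
})

test_that("a responder storing both items shows smaller error to the probed item", {
  set.seed(9)
  cfg <- sim_config(n_trials_per_condition = 192)
  by_subj <- purrr::map_dfr(1:12, function(s) {
    tr <- sample_trial_positions(cfg, "two_item")
    tr$subject_id <- s
    resp <- (tr$angle_probed + rvonmises(nrow(tr), 0, vm_kappa_from_sd(5))) %% 360
    same_bin_analysis(tr, resp)$by_subject
  })
  sb <- by_subj[by_subj$subset == "same_bin", ]
  tt <- t.test(sb$mean_abs_error_probed, sb$mean_abs_error_unprobed, paired = TRUE)
  expect_lt(tt$p.value, 0.001)
  expect_lt(mean(sb$mean_abs_error_probed), mean(sb$mean_abs_error_unprobed))
})
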