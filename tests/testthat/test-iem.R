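test_that("training recovers exact weights and inversion is a left inverse", {
  set.seed(1)
  W <- matrix(runif(30 * 8), 30)
  C1 <- basis_response(make_basis(), (0:7) * 45)
  B1 <- W %*% C1
  What <- train_weights(B1, C1)
  expect_equal(unclass(What), W, tolerance = 1e-12, ignore_attr = TRUE)
  C2 <- matrix(rnorm(8 * 5), 8)
  expect_equal(invert_model(What, unclass(What) %*% C2), C2, tolerance = 1e-10)
  # scalar case: 1 electrode, 1 channel, B1 = 2 C1
  w <- train_weights(matrix(2 * (1:4), 1), matrix(as.numeric(1:4), 1))
  expect_equal(as.numeric(w), 2)
})

test_that("inversion matches an independent pseudo-inverse computation", {
  set.seed(2)
  W <- matrix(rnorm(4 * 3), 4)
  B2 <- matrix(rnorm(4 * 6), 4)
  expect_equal(invert_model(W, B2), MASS::ginv(W) %*% B2, tolerance = 1e-10)
})

test_that("rank deficiency raises explicit errors, not silent pseudo-inverses", {
  C1 <- matrix(1, 3, 6)                        # channels indistinguishable
  expect_error(train_weights(matrix(rnorm(12), 2, 6), C1), "rank deficient")
  W <- cbind(1:4, 1:4, rnorm(4))               # collinear weight columns
  expect_error(invert_model(W, matrix(rnorm(8), 4)), "rank deficient")
})

test_that("least-squares weights converge to truth as training size grows", {
  set.seed(3)
  basis <- make_basis()
  W <- matrix(runif(30 * 8), 30)
  err <- vapply(c(64, 1024), function(n) {
    ang <- runif(n, 0, 360)
    C1 <- basis_response(basis, ang)
    B1 <- W %*% C1 + matrix(rnorm(30 * n, 0, 0.3), 30)
    norm(unclass(train_weights(B1, C1)) - W, "F")
  }, numeric(1))
  expect_lt(err[2], err[1] / 2)
})

test_that("bin averaging matches brute-force group means", {
  set.seed(4)
  tr <- center_trials(3)
  p <- partition_trials(tr, seed = 5)
  pow <- matrix(rnorm(nrow(tr) * 6), nrow(tr))
  got <- average_by_bin(pow, p, set_id = 2)
  for (b in 0:7) {
    idx <- which(p$set == 2 & p$bin_probed == b)
    expect_equal(got[, b + 1], colMeans(pow[idx, , drop = FALSE]))
  }
  # pooling sets
  got12 <- average_by_bin(pow, p, set_id = 1:2)
  idx <- which(p$set %in% 1:2 & p$bin_probed == 0)
  expect_equal(got12[, 1], colMeans(pow[idx, , drop = FALSE]))
})

test_that("noiseless centred data reconstruct the basis CTF exactly", {
  set.seed(6)
  tr <- center_trials(3)
  W <- matrix(runif(30 * 8), 30)
  pow <- noiseless_power(tr, W)
  rec <- run_iem(pow, tr, regime = "within_condition", n_iterations = 1, seed = 7)
  expect_equal(rec$offsets, c(-135, -90, -45, 0, 45, 90, 135, 180))
  expect_equal(rec$profiles[1, , 1], perfect_ctf(), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("rotating all stimuli by one bin leaves the aligned CTF unchanged", {
  set.seed(8)
  tr <- sample_trial_positions(small_config(), "one_item", seed = 9)
  W <- matrix(runif(30 * 8), 30)
  pow <- noiseless_power(tr, W)
  tr_rot <- tr
  tr_rot$bin_probed <- (tr$bin_probed + 1L) %% 8L
  tr_rot$angle_probed <- (tr$angle_probed + 45) %% 360
  pow_rot <- noiseless_power(tr_rot, W)
  parts <- lapply(1:2, function(i) partition_trials(tr, seed = 20 + i)$set)
  rec <- run_iem(pow, tr, regime = "within_condition", n_iterations = 2,
                 partitions = parts)
  rec_rot <- run_iem(pow_rot, tr_rot, regime = "within_condition",
                     n_iterations = 2, partitions = parts)
  expect_equal(rec_rot$profiles, rec$profiles, tolerance = 1e-9)
})

test_that("iteration averaging is order invariant", {
  subj <- generate_subject(small_config(), seed = 10)
  parts <- lapply(1:3, function(i) {
    partition_trials(subj$trials, regime = "condition_neutral", seed = 30 + i)$set
  })
  a <- run_iem(subj$electrode_data, subj$trials, n_iterations = 3, partitions = parts)
  b <- run_iem(subj$electrode_data, subj$trials, n_iterations = 3, partitions = rev(parts))
  expect_equal(a$profiles, b$profiles)
})

test_that("condition-neutral reconstructions share training: swapping condition labels swaps profiles", {
  subj <- generate_subject(small_config(), seed = 12)
  parts <- lapply(1:2, function(i) {
    partition_trials(subj$trials, regime = "condition_neutral", seed = 40 + i)$set
  })
  rec <- run_iem(subj$electrode_data, subj$trials, n_iterations = 2, partitions = parts)
  swapped <- subj$trials
  swapped$condition <- ifelse(swapped$condition == "one_item", "two_item", "one_item")
  rec_sw <- run_iem(subj$electrode_data, swapped, n_iterations = 2, partitions = parts)
  # identical combined training; only the test rows swap identity
  expect_equal(rec$profiles["one_item", , ], rec_sw$profiles["two_item", , ])
  expect_equal(rec$profiles["two_item", , ], rec_sw$profiles["one_item", , ])
})

test_that("randomized position labels give no selectivity on average", {
  set.seed(13)
  subj <- generate_subject(small_config(noise_sd_one_item = 0.5),
                           condition = "one_item", seed = 14)
  slopes <- replicate(50, {
    rec <- run_iem(subj$electrode_data, subj$trials, regime = "within_condition",
                   n_iterations = 1, shuffle_labels = TRUE)
    ctf_slope(rec$profiles[1, , 1])
  })
  expect_lt(abs(mean(slopes)), 2 * sd(slopes) / sqrt(length(slopes)))
})

test_that("adding an independent second item leaves the probed CTF unchanged in expectation", {
  set.seed(15)
  diffs <- replicate(8, {
    subj <- generate_subject(small_config())
    rec <- run_iem(subj$electrode_data, subj$trials, n_iterations = 2)
    sl <- ctf_slopes(rec)
    sl$slope[sl$condition == "one_item"] - sl$slope[sl$condition == "two_item"]
  })
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)) + 0.01)
})

test_that("cross-training reconstructs the two-item test condition only", {
  subj <- generate_subject(small_config(), seed = 16)
  rec <- run_iem(subj$electrode_data, subj$trials, regime = "cross_training",
                 n_iterations = 1, seed = 17)
  expect_equal(rec$conditions, "two_item")
  one_only <- dplyr::filter(subj$trials, condition == "one_item")
  expect_error(
    run_iem(subj$electrode_data[subj$trials$condition == "one_item", ],
            one_only, regime = "cross_training", n_iterations = 1),
    "two-item"
  )
})
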