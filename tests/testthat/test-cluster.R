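iid_null_fn <- function(n_sub, n_time, sd = 1) {
  function(i) matrix(rnorm(n_sub * n_time, 0, sd), n_sub)
}

test_that("the cluster-forming threshold is recomputed from the sample size", {
  expect_equal(round(cluster_t_threshold(28), 3), 1.703)
  expect_equal(cluster_t_threshold(15), qt(0.95, 14))
  expect_error(cluster_t_threshold(1), "2 subjects")
})

test_that("a uniform strong effect forms one significant cluster covering every point", {
  set.seed(1)
  x <- matrix(rnorm(28 * 15, mean = 2, sd = 0.5), 28)
  res <- cluster_permutation_test(x, iid_null_fn(28, 15, 0.5), n_perm = 200, seed = 2)
  expect_equal(nrow(res$clusters), 1)
  expect_equal(res$clusters$members[[1]], 1:15)
  expect_true(res$clusters$significant)
  expect_lt(res$clusters$p, 0.05)
})

test_that("clusters are maximal contiguous supra-threshold runs", {
  tv <- c(0.2, 2, 3, 0.5, 2.5, 0.1, 1.8)
  cl <- ctfiem:::find_clusters(tv, 1.703)
  expect_equal(cl, list(2:3, 5L, 7L))
  expect_equal(ctfiem:::max_cluster_mass(tv, 1.703), 5)
  expect_equal(ctfiem:::find_clusters(rep(0, 5), 1.703), list())
})

test_that("time-frequency clusters use 4-connectivity (8 optional)", {
  tm <- matrix(0, 3, 3)
  tm[1, 1] <- 3; tm[2, 2] <- 3; tm[3, 3] <- 3   # diagonal: touching corners
  cl4 <- ctfiem:::find_clusters(tm, 1.703, connectivity = 4)
  expect_length(cl4, 3)
  cl8 <- ctfiem:::find_clusters(tm, 1.703, connectivity = 8)
  expect_length(cl8, 1)
  tm[2, 1] <- 3                                  # bridge joins two of them
  expect_length(ctfiem:::find_clusters(tm, 1.703, connectivity = 4), 2)
})

test_that("zero-variance points are treated as sub-threshold", {
  x <- matrix(rnorm(28 * 5), 28)
  x[, 3] <- 1   # identical across subjects: t undefined
  tv <- ctfiem:::pointwise_t(x)
  expect_equal(tv[3], 0)
})

test_that("the null max-mass distribution is invariant to subject ordering", {
  set.seed(3)
  x <- matrix(rnorm(20 * 10, 0.4), 20)
  res1 <- cluster_permutation_test(x, iid_null_fn(20, 10), n_perm = 150, seed = 7)
  res2 <- cluster_permutation_test(x[sample(20), ], iid_null_fn(20, 10),
                                   n_perm = 150, seed = 7)
  expect_equal(res1$null_distribution, res2$null_distribution)
  expect_equal(res1$clusters$mass, res2$clusters$mass)
})

test_that("label-shuffled IEM null slopes centre on zero", {
  set.seed(4)
  subj <- generate_subject(small_config(noise_sd_one_item = 0.5),
                           condition = "one_item", seed = 5)
  nf <- iem_null_fn(list(subj$electrode_data), list(subj$trials),
                    regime = "within_condition", n_iterations = 1)
  draws <- vapply(1:30, function(i) nf(i)[1, 1], numeric(1))
  expect_lt(abs(mean(draws)), 2 * sd(draws) / sqrt(30))
})
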