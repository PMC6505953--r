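#' One-sided t threshold for cluster formation
#'
#' The cluster-forming threshold is the critical t for a one-sided test at
#' level `alpha` with `n - 1` degrees of freedom (1.703 for 28 subjects at
#' alpha 0.05). It is recomputed from `n` rather than hard-coded so the
#' test remains calibrated for any sample size.
#'
#' @param n Number of subjects.
#' @param alpha One-sided tail probability.
#' @return The critical t value.
#' @export
cluster_t_threshold <- function(n, alpha = 0.05) {
  if (n < 2) abort("Need at least 2 subjects.")
  qt(1 - alpha, df = n - 1)
}

# One-sample t against 0 per column of a subjects x points matrix.
# Zero-variance points get t = 0 (treated as sub-threshold).
pointwise_t <- function(x) {
  n <- nrow(x)
  m <- colMeans(x)
  s <- sqrt((colSums(x^2) - n * m^2) / (n - 1))
  t <- m / (s / sqrt(n))
  t[!is.finite(t)] <- 0
  t
}

# Maximal contiguous runs above threshold. 1-D: adjacency in time.
# 2-D (time x frequency): 4-connectivity (or 8 with `connectivity = 8`).
find_clusters <- function(tvals, threshold, connectivity = 4) {
  if (is.matrix(tvals)) {
    find_clusters_2d(tvals, threshold, connectivity)
  } else {
    above <- tvals > threshold
    if (!any(above)) return(list())
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    Map(function(s, e) s:e, starts[r$values], ends[r$values])
  }
}

find_clusters_2d <- function(tmat, threshold, connectivity = 4) {
  above <- tmat > threshold
  if (!any(above)) return(list())
  nr <- nrow(tmat); nc <- ncol(tmat)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offs <- if (connectivity == 8) {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  clusters <- list()
  for (start in which(above)) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    members <- integer(0)
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      members <- c(members, cur)
      i <- (cur - 1L) %% nr + 1L
      j <- (cur - 1L) %/% nr + 1L
      for (o in seq_len(nrow(offs))) {
        ii <- i + offs[o, 1]; jj <- j + offs[o, 2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
          idx <- (jj - 1L) * nr + ii
          if (above[idx] && lab[idx] == 0L) {
            lab[idx] <- nxt
            queue <- c(queue, idx)
          }
        }
      }
    }
    clusters[[nxt]] <- sort(members)
  }
  clusters
}

max_cluster_mass <- function(tvals, threshold, connectivity = 4) {
  cl <- find_clusters(tvals, threshold, connectivity)
  if (!length(cl)) return(0)
  max(vapply(cl, function(m) sum(tvals[m]), numeric(1)))
}

#' Cluster-based permutation test for above-chance CTF selectivity
#'
#' Nonparametric inference over time (or time x frequency) with
#' family-wise error control. A one-sample t statistic against 0 is
#' computed at every point of the subjects x points slope array; clusters
#' of contiguous supra-threshold points are formed (1-D adjacency in time,
#' 4-connectivity in time x frequency by default) and each cluster's mass
#' is the sum of its t values. The null distribution of the maximum
#' cluster mass is built by calling `null_fn` `n_perm` times — typically a
#' wrapper that reruns the IEM with position labels randomized within
#' every training and test set (see [iem_null_fn()]) — and clusters whose
#' mass exceeds the `1 - alpha` quantile of that null are significant
#' (a one-tailed test at level `alpha`, corrected for multiple
#' comparisons).
#'
#' @param subject_slopes Subjects x time matrix (or subjects x time x
#'   frequency array) of CTF slopes.
#' @param null_fn Function of one argument (the permutation index)
#'   returning a same-shaped array of slopes under label randomization.
#' @param n_perm Number of permutations (values below 100 trigger a
#'   warning).
#' @param t_threshold Cluster-forming threshold; by default recomputed
#'   from the subject count via [cluster_t_threshold()].
#' @param alpha Family-wise alpha level.
#' @param connectivity 4 or 8, for time x frequency arrays.
#' @param seed Optional RNG seed (passed to nothing else: `null_fn` sees
#'   the seeded RNG stream).
#' @return A `cluster_result`: tibble of clusters (members, mass,
#'   significance, p), the null distribution, threshold, and settings.
#' @export
cluster_permutation_test <- function(subject_slopes, null_fn, n_perm = 1000,
                                     t_threshold = NULL, alpha = 0.05,
                                     connectivity = 4, seed = NULL) {
  x <- as.matrix_or_array(subject_slopes)
  n_sub <- dim(x)[1]
  if (n_sub < 2) abort("Need at least 2 subjects.")
  if (n_perm < 100) warn("`n_perm` < 100 gives a very coarse null distribution.")
  local_seed(seed)
  t_threshold <- t_threshold %||% cluster_t_threshold(n_sub, alpha)

  tv <- point_t_of(x)
  clusters <- find_clusters(tv, t_threshold, connectivity)
  null <- vapply(seq_len(n_perm), function(i) {
    xn <- as.matrix_or_array(null_fn(i))
    max_cluster_mass(point_t_of(xn), t_threshold, connectivity)
  }, numeric(1))
  crit <- unname(quantile(null, 1 - alpha))

  cl_tbl <- tibble(
    cluster = seq_along(clusters),
    members = clusters,
    mass = vapply(clusters, function(m) sum(tv[m]), numeric(1))
  )
  cl_tbl$p <- vapply(cl_tbl$mass, function(m) (1 + sum(null >= m)) / (1 + n_perm),
                     numeric(1))
  cl_tbl$significant <- cl_tbl$mass > crit

  structure(
    list(
      clusters = cl_tbl, t_values = tv, null_distribution = null,
      critical_mass = crit, t_threshold = t_threshold, alpha = alpha,
      n_perm = n_perm, connectivity = connectivity, n_subjects = n_sub
    ),
    class = "cluster_result"
  )
}

as.matrix_or_array <- function(x) {
  if (is.data.frame(x)) as.matrix(x) else x
}

point_t_of <- function(x) {
  if (length(dim(x)) == 3) {
    d <- dim(x)
    matrix(pointwise_t(matrix(x, d[1])), d[2], d[3])
  } else {
    pointwise_t(x)
  }
}

#' @export
print.cluster_result <- function(x, ...) {
  sig <- sum(x$clusters$significant)
  cat(sprintf(
    "<cluster_result> %d cluster(s), %d significant at FWER %g (threshold t = %.3f, %d permutations)\n",
    nrow(x$clusters), sig, x$alpha, x$t_threshold, x$n_perm
  ))
  invisible(x)
}

#' Label-randomization null runner for the cluster test
#'
#' Builds the `null_fn` used by [cluster_permutation_test()]: each call
#' reruns the IEM for every subject with position labels randomly permuted
#' within each training and test set, and returns the subjects x time
#' matrix of null CTF slopes for the requested condition.
#'
#' @param powers List of per-subject power inputs (see [run_iem()]).
#' @param trials List of per-subject trial tibbles.
#' @param condition Which reconstructed condition's slopes to extract.
#' @param ... Passed on to [run_iem()] (regime, n_iterations, basis, ...).
#' @return A function `f(i)` returning a subjects x time slope matrix.
#' @export
iem_null_fn <- function(powers, trials, condition = NULL, ...) {
  force(powers); force(trials); force(condition)
  function(i) {
    rows <- lapply(seq_along(powers), function(s) {
      rec <- run_iem(powers[[s]], trials[[s]], shuffle_labels = TRUE, ...)
      sl <- ctf_slopes(rec)
      cond <- condition %||% rec$conditions[1]
      sl$slope[sl$condition == cond]
    })
    do.call(rbind, rows)
  }
}
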