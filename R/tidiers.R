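#' Tidy a CTF reconstruction into a long tibble
#'
#' @param x A `ctf_reconstruction` from [run_iem()].
#' @param ... Unused.
#' @return A tibble with `condition`, `time`, `offset`, `response`.
#' @export
tidy.ctf_reconstruction <- function(x, ...) {
  grid <- expand.grid(
    condition = x$conditions, offset = x$offsets, time = x$times,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$response <- as.vector(x$profiles)
  as_tibble(grid)[, c("condition", "time", "offset", "response")]
}

#' Tidy methods for mixture fits
#'
#' @param x A `mixture_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter; `glance()`: one-row model
#'   summary.
#' @export
tidy.mixture_fit <- function(x, ...) {
  terms <- c("sd", "p_guess", if (x$model == "three_component") "p_swap")
  tibble(
    term = terms,
    estimate = vapply(terms, function(t) x[[t]], numeric(1))
  )
}

#' @rdname tidy.mixture_fit
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(
    log_likelihood = x$log_likelihood,
    converged = x$converged,
    n = x$n,
    model = x$model
  )
}

#' Tidy methods for cluster-based permutation results
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return `tidy()`: one row per cluster with extent, mass, p, and
#'   significance; `glance()`: one-row test summary.
#' @export
tidy.cluster_result <- function(x, ...) {
  cl <- x$clusters
  tibble(
    cluster = cl$cluster,
    n_points = lengths(cl$members),
    first_point = vapply(cl$members, min, integer(1)),
    last_point = vapply(cl$members, max, integer(1)),
    mass = cl$mass,
    p_value = cl$p,
    significant = cl$significant
  )
}

#' @rdname tidy.cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  tibble(
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$significant),
    t_threshold = x$t_threshold,
    critical_mass = x$critical_mass,
    alpha = x$alpha,
    n_perm = x$n_perm,
    n_subjects = x$n_subjects
  )
}

#' Tidy methods for simulation studies
#'
#' @param x An `iem_study` from [run_simulation_study()].
#' @param ... Unused.
#' @return `tidy()`: the per-sample tibble; `glance()`: the one-row
#'   summary (significant proportions and slope moments).
#' @export
tidy.iem_study <- function(x, ...) {
  x$samples
}

#' @rdname tidy.iem_study
#' @export
glance.iem_study <- function(x, ...) {
  x$summary
}
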