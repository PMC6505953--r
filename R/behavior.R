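#' Signed response error on the circle
#'
#' Circular difference between the reported and true angular position,
#' mapped to `(-180, 180]` degrees: 0 is a perfect response, +/-180 a
#' maximally imprecise one, and the 180-degree boundary maps to +180.
#'
#' @param reported,true Angles in degrees.
#' @return Signed errors in degrees.
#' @examples
#' response_error(10, 350)  # 20: wraparound
#' response_error(0, 180)   # +180: boundary convention
#' @export
response_error <- function(reported, true) {
  circ_diff(reported, true)
}

# Negative log-likelihood of the mixture. Parameters are unconstrained:
# log kappa, and stick-breaking logits for (p_guess, p_swap).
mixture_nll <- function(par, errors, nontarget = NULL) {
  kappa <- exp(par[1])
  p_guess <- stats::plogis(par[2])
  p_swap <- if (length(par) > 2) (1 - p_guess) * stats::plogis(par[3]) else 0
  p_target <- 1 - p_guess - p_swap
  lt <- vm_log_density(errors, kappa)
  comps <- cbind(
    log(p_target) + lt,
    log(p_guess) - log(2 * pi),
    if (!is.null(nontarget)) {
      log(p_swap) + vm_log_density(circ_diff(errors, nontarget), kappa)
    }
  )
  mx <- apply(comps, 1, max)
  ll <- sum(mx + log(rowSums(exp(comps - mx))))
  if (!is.finite(ll)) 1e10 else -ll
}

fit_mixture <- function(errors, nontarget = NULL, sd_floor = 0.5) {
  n <- length(errors)
  if (n < 20) abort("Need at least 20 observations to fit the mixture.")
  three <- !is.null(nontarget)
  log_kappa_max <- log(vm_kappa_from_sd(sd_floor))
  starts <- expand.grid(
    log_kappa = log(vapply(c(30, 12, 4), vm_kappa_from_sd, numeric(1))),
    logit_g = stats::qlogis(c(0.05, 0.35, 0.75)),
    logit_s = if (three) stats::qlogis(c(0.1, 0.4)) else 0
  )
  if (!three) starts <- starts[starts$logit_s == 0 & TRUE, 1:2, drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(as.numeric(starts[i, ]), mixture_nll, errors = errors,
            nontarget = nontarget, method = "L-BFGS-B",
            lower = c(-5, -12, if (three) -12),
            upper = c(log_kappa_max, 12, if (three) 12)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    return(structure(
      list(sd = NA_real_, p_guess = NA_real_,
           p_swap = if (three) NA_real_ else NA, kappa = NA_real_,
           log_likelihood = NA_real_, converged = FALSE, n = n,
           model = if (three) "three_component" else "two_component"),
      class = "mixture_fit"
    ))
  }
  kappa <- exp(best$par[1])
  p_guess <- stats::plogis(best$par[2])
  p_swap <- if (three) (1 - p_guess) * stats::plogis(best$par[3]) else NA_real_
  structure(
    list(
      sd = vm_sd_from_kappa(kappa),
      p_guess = p_guess,
      p_swap = p_swap,
      kappa = kappa,
      log_likelihood = -best$value,
      converged = best$convergence == 0,
      n = n,
      model = if (three) "three_component" else "two_component"
    ),
    class = "mixture_fit"
  )
}

#' Two-component mixture model of response error
#'
#' Maximum-likelihood fit of the standard delayed-estimation mixture: a
#' von Mises distribution centred on the correct value (trials on which
#' the probed location was remembered, with dispersion reported as
#' circular s.d. — higher values mean lower precision) plus a uniform
#' distribution (random guesses, with height `p_guess`). Optimization is
#' multi-start bound-constrained L-BFGS over (log concentration, guess
#' logit); the response space is the full 360-degree circle. The s.d. is
#' floored at 0.5 degrees so degenerate (all-identical) samples keep a
#' finite likelihood.
#'
#' @param errors Signed response errors in degrees (see
#'   [response_error()]); at least 20 observations.
#' @return A `mixture_fit` with `sd` (degrees), `p_guess`,
#'   `log_likelihood`, and a `converged` flag (non-convergence is flagged,
#'   not thrown). Supports [tidy()] and [glance()].
#' @examples
#' err <- generate_behavioral_errors(6, p_guess = 0.1, n_trials = 1000, seed = 1)
#' fit_mixture2(err$error)
#' @export
fit_mixture2 <- function(errors) {
  fit_mixture(errors)
}

#' Three-component mixture model with swap errors
#'
#' Extends [fit_mixture2()] with a third component: a von Mises centred on
#' the unprobed (non-target) item's location, capturing trials on which
#' the wrong item was reported ("swaps", weight `p_swap`). The target and
#' swap components share one dispersion parameter.
#'
#' @param errors_to_target Signed errors relative to the probed item
#'   (degrees).
#' @param nontarget_offsets Per-trial signed offset of the unprobed item
#'   relative to the probed item (degrees).
#' @return A `mixture_fit` with `sd`, `p_guess`, `p_swap`.
#' @export
fit_mixture3 <- function(errors_to_target, nontarget_offsets) {
  if (length(errors_to_target) != length(nontarget_offsets)) {
    abort("`errors_to_target` and `nontarget_offsets` must be the same length.")
  }
  fit_mixture(errors_to_target, nontarget = nontarget_offsets)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> %s, n = %d%s\n", x$model, x$n,
              if (x$converged) "" else " (NOT converged)"))
  cat(sprintf("  sd = %.2f deg, p_guess = %.3f%s, logLik = %.1f\n",
              x$sd, x$p_guess,
              if (is.na(x$p_swap)) "" else sprintf(", p_swap = %.3f", x$p_swap),
              x$log_likelihood))
  invisible(x)
}

#' Response error relative to probed vs unprobed item on same-bin trials
#'
#' For two-item trials on which both items occupied the same position bin
#' (and, separately, trials with items closer than `separation_cutoff`
#' degrees), computes each subject's mean absolute response error relative
#' to the probed and to the unprobed item, with a paired t test across
#' subjects. If observers remembered only one (or a merged) location on
#' these trials, the two errors should be equivalent; smaller error
#' relative to the probed item indicates both positions were retained.
#'
#' @param trials Two-item trial tibble with `angle_probed`,
#'   `angle_unprobed`, `bin_probed`, `bin_unprobed`, and optionally
#'   `subject_id`.
#' @param responses Reported angles in degrees, one per trial row.
#' @param separation_cutoff Angular separation (degrees) defining the
#'   close-items subset (default 10).
#' @return A list with `by_subject` (tibble: subject, subset, n_trials,
#'   mean per reference) and `tests` (tibble: paired t per subset).
#' @export
same_bin_analysis <- function(trials, responses, separation_cutoff = 10) {
  if (length(responses) != nrow(trials)) {
    abort("`responses` must have one entry per trial.")
  }
  two <- !is.na(trials$bin_unprobed)
  if (!any(two)) abort("No two-item trials supplied.")
  df <- tibble(
    subject = if ("subject_id" %in% names(trials)) trials$subject_id else 1L,
    err_probed = abs(response_error(responses, trials$angle_probed)),
    err_unprobed = abs(response_error(responses, trials$angle_unprobed)),
    same_bin = trials$bin_probed == trials$bin_unprobed,
    close = circ_dist(trials$angle_probed, trials$angle_unprobed) < separation_cutoff
  )[two, ]
  subsets <- list(same_bin = df$same_bin, close = df$close)
  by_subject <- purrr::map_dfr(names(subsets), function(nm) {
    d <- df[subsets[[nm]], ]
    if (!nrow(d)) abort(sprintf("No qualifying trials in subset '%s'.", nm))
    d |>
      dplyr::group_by(subject) |>
      dplyr::summarise(
        subset = nm, n_trials = dplyr::n(),
        mean_abs_error_probed = mean(err_probed),
        mean_abs_error_unprobed = mean(err_unprobed),
        .groups = "drop"
      )
  })
  tests <- by_subject |>
    dplyr::group_by(subset) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2) {
        return(tibble(estimate = mean(d$mean_abs_error_probed -
                                        d$mean_abs_error_unprobed),
                      statistic = NA_real_, df = NA_real_,
                      p_value = NA_real_))
      }
      window_compare(d$mean_abs_error_probed, d$mean_abs_error_unprobed)[
        , c("estimate", "statistic", "df", "p_value")]
    }) |>
    dplyr::ungroup()
  list(by_subject = by_subject, tests = tests)
}
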