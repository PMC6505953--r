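#' Simulation study of CTF selectivity across memory load
#'
#' The validation harness for the IEM pipeline: repeatedly generates
#' samples of synthetic subjects under a known ground truth and asks how
#' often a paired t test detects a difference in CTF selectivity between
#' the one-item and two-item conditions. Three canonical configurations
#' probe three questions:
#' * equal noise and amplitude (`sim_config()`) — does merely adding a
#'   second representation bias selectivity? (the significant proportion
#'   should sit at the nominal 5% type-I rate);
#' * extra two-item noise (`sim_config(noise_sd_two_item = 2)`) — does
#'   noise bias selectivity, or only make it more variable?;
#' * reduced two-item amplitude (`sim_config(amplitude_scale_two_item =
#'   0.9)`) — is a true 10% selectivity reduction reliably detected?
#'
#' Per sample: `config$n_subjects` subjects are generated
#' ([generate_subject()]), the condition-neutral IEM with bin-averaged
#' training matrices and leave-one-out folds is applied to each, and the
#' per-subject CTF slopes of the two conditions are compared with a
#' two-sided paired t test.
#'
#' The default `engine = "cpp"` runs a compiled implementation of exactly
#' this per-sample computation; `engine = "r"` runs the reference R
#' pipeline ([generate_subject()] + [run_iem()]) and is used for
#' cross-validation of the compiled path (and for non-default basis
#' sizes, which the compiled path does not support).
#'
#' @param config A [sim_config()].
#' @param n_samples Number of simulated samples.
#' @param seed RNG seed for the whole study; per-sample seeds are derived
#'   from it.
#' @param n_iterations IEM partition iterations per subject (default 10).
#' @param engine `"cpp"` (compiled) or `"r"` (reference implementation).
#' @param alpha Significance level for the per-sample paired t test
#'   (two-sided).
#' @return An `iem_study`: `samples` (per-sample tibble with mean slopes,
#'   t, p), `summary` (significant proportions split by direction), plus
#'   the settings. Supports [tidy()] and [glance()].
#' @examples
#' \donttest{
#' st <- run_simulation_study(sim_config(), n_samples = 20, seed = 1)
#' glance(st)
#' }
#' @export
run_simulation_study <- function(config = sim_config(), n_samples = 100,
                                 seed = NULL, n_iterations = 10,
                                 engine = c("cpp", "r"), alpha = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  engine <- match.arg(engine)
  n_samples <- assert_count(n_samples, "n_samples")
  local_seed(seed %||% config$seed)
  if (engine == "cpp" && config$n_channels != 8) {
    abort("The compiled engine supports the 8-channel design only; use engine = \"r\".")
  }

  if (engine == "cpp") {
    seeds <- split_seeds(n_samples)
    res <- cpp_sim_samples(
      n_samples, config$n_subjects, config$n_trials_per_condition,
      config$n_electrodes, config$basis_exponent,
      config$noise_sd_one_item, config$noise_sd_two_item,
      config$amplitude_scale_two_item, config$min_item_separation,
      n_iterations, seeds, neutral_projector(config)
    )
    slopes_one <- t(res$slopes_one)   # n_samples x n_subjects
    slopes_two <- t(res$slopes_two)
  } else {
    slopes_one <- matrix(NA_real_, n_samples, config$n_subjects)
    slopes_two <- matrix(NA_real_, n_samples, config$n_subjects)
    for (i in seq_len(n_samples)) {
      for (s in seq_len(config$n_subjects)) {
        subj <- generate_subject(config)
        rec <- run_iem(subj$electrode_data, subj$trials,
                       regime = "condition_neutral",
                       n_iterations = n_iterations, basis = subj$basis)
        sl <- ctf_slopes(rec)
        slopes_one[i, s] <- sl$slope[sl$condition == "one_item"]
        slopes_two[i, s] <- sl$slope[sl$condition == "two_item"]
      }
    }
  }

  d <- slopes_one - slopes_two
  n_sub <- config$n_subjects
  dm <- rowMeans(d)
  dsd <- sqrt(rowSums((d - dm)^2) / (n_sub - 1))
  tstat <- dm / (dsd / sqrt(n_sub))
  pval <- 2 * pt(-abs(tstat), df = n_sub - 1)
  samples <- tibble(
    sample = seq_len(n_samples),
    mean_slope_one_item = rowMeans(slopes_one),
    mean_slope_two_item = rowMeans(slopes_two),
    statistic = tstat,
    p_value = pval
  )
  sig <- pval < alpha
  summary <- tibble(
    n_samples = n_samples,
    prop_significant = mean(sig),
    prop_one_gt_two = mean(sig & tstat > 0),
    prop_two_gt_one = mean(sig & tstat < 0),
    mean_slope_one_item = mean(samples$mean_slope_one_item),
    mean_slope_two_item = mean(samples$mean_slope_two_item),
    var_mean_slope_one_item = stats::var(samples$mean_slope_one_item),
    var_mean_slope_two_item = stats::var(samples$mean_slope_two_item)
  )
  structure(
    list(samples = samples, summary = summary, config = config,
         n_iterations = n_iterations, engine = engine, alpha = alpha,
         seed = seed),
    class = "iem_study"
  )
}

# C'(CC')^-1 for the basis evaluated at the bin centres: the only piece of
# the training algebra that is constant across folds and samples.
neutral_projector <- function(config) {
  basis <- make_basis(config$n_channels, config$basis_exponent)
  C <- basis_response(basis, basis$centers)
  t(C) %*% solve(C %*% t(C))
}

#' @export
print.iem_study <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<iem_study> %d samples (%s engine): p < %g in %.2f%% (one > two %.2f%%, two > one %.2f%%)\n",
    s$n_samples, x$engine, x$alpha, 100 * s$prop_significant,
    100 * s$prop_one_gt_two, 100 * s$prop_two_gt_one
  ))
  cat(sprintf("  mean CTF slope: one-item %.4f, two-item %.4f\n",
              s$mean_slope_one_item, s$mean_slope_two_item))
  invisible(x)
}
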