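#' Run the end-to-end reconstruction pipeline from a config
#'
#' Orchestrates generation (or ingestion) -> IEM -> selectivity -> optional
#' cluster inference from a single declarative configuration, writing all
#' results and a log of every seed used. Reruns with the same config are
#' reproducible.
#'
#' The config is a JSON file or an equivalent nested list with blocks:
#' * `seed` — master seed; every stochastic stage draws its own seed from
#'   it and the log records them all.
#' * `synthetic` — self-contained mode: `config` (fields of
#'   [sim_config()]), `condition`, `tuning_window` (ms) and `times`
#'   (`from`/`to`/`by`, ms) for the time-resolved generator. One dataset
#'   is generated per subject.
#' * `input` — alternative to `synthetic`: lists `power_prefixes` and
#'   `trials_csvs`, one entry per subject, pointing at containers written
#'   by [write_epoched_power()]/[write_trial_table()]. Files are checked
#'   before any computation.
#' * `iem` — `regime`, `n_iterations`, `n_sets`.
#' * `windows` — named `c(from, to)` windows (ms) for window averages.
#' * `cluster_test` — optional: `n_perm`, `alpha`, `condition`.
#'
#' @param config Path to a JSON config or a list.
#' @param out_dir Optional output directory; when given, per-subject slope
#'   tables (CSV), aligned profiles (CSV), cluster results (JSON), and the
#'   run log (JSON) are written there.
#' @return A list with `slopes` (tibble: subject, condition, time, slope),
#'   `profiles` (tibble), `window_averages` (tibble or `NULL`), `cluster`
#'   (a `cluster_result` or `NULL`), and `log` (settings + seeds).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("Config file '%s' not found.", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- validate_pipeline_config(config)
  local_seed(cfg$seed)

  iem_args <- cfg$iem
  n_subjects <- cfg$n_subjects
  subject_seeds <- split_seeds(n_subjects)
  iem_seeds <- split_seeds(n_subjects)

  datasets <- lapply(seq_len(n_subjects), function(s) {
    if (!is.null(cfg$synthetic)) {
      sim <- cfg$synthetic
      ds <- generate_timecourse_dataset(
        sim$config, sim$tuning_window[1], sim$tuning_window[2],
        times = seq(sim$times$from, sim$times$to, by = sim$times$by),
        condition = sim$condition, seed = subject_seeds[s]
      )
      list(power = ds$power, trials = ds$trials)
    } else {
      list(power = read_epoched_power(cfg$input$power_prefixes[s]),
           trials = read_trial_table(cfg$input$trials_csvs[s]))
    }
  })

  recons <- lapply(seq_len(n_subjects), function(s) {
    run_iem(datasets[[s]]$power, datasets[[s]]$trials,
            regime = iem_args$regime, n_iterations = iem_args$n_iterations,
            n_sets = iem_args$n_sets, seed = iem_seeds[s])
  })

  slopes <- purrr::map_dfr(seq_len(n_subjects), function(s) {
    dplyr::mutate(ctf_slopes(recons[[s]]), subject = s, .before = 1)
  })
  profiles <- purrr::map_dfr(seq_len(n_subjects), function(s) {
    dplyr::mutate(tidy(recons[[s]]), subject = s, .before = 1)
  })

  window_averages <- NULL
  if (length(cfg$windows)) {
    window_averages <- purrr::map_dfr(names(cfg$windows), function(w) {
      win <- cfg$windows[[w]]
      slopes |>
        dplyr::filter(.data$time >= win[1], .data$time <= win[2]) |>
        dplyr::group_by(.data$subject, .data$condition) |>
        dplyr::summarise(slope = mean(.data$slope), .groups = "drop") |>
        dplyr::mutate(window = w)
    })
  }

  cluster <- NULL
  if (!is.null(cfg$cluster_test)) {
    ct <- cfg$cluster_test
    cond <- ct$condition %||% recons[[1]]$conditions[1]
    mat <- slopes |>
      dplyr::filter(.data$condition == cond) |>
      tidyr::pivot_wider(names_from = "time", values_from = "slope") |>
      dplyr::select(-"subject", -"condition") |>
      as.matrix()
    nf <- iem_null_fn(
      lapply(datasets, `[[`, "power"), lapply(datasets, `[[`, "trials"),
      condition = cond, regime = iem_args$regime,
      n_iterations = ct$null_iterations %||% 1, n_sets = iem_args$n_sets
    )
    cluster <- cluster_permutation_test(
      mat, nf, n_perm = ct$n_perm, alpha = ct$alpha %||% 0.05,
      seed = split_seeds(1)
    )
  }

  log <- list(
    config = config, n_subjects = n_subjects,
    subject_seeds = subject_seeds, iem_seeds = iem_seeds,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(slopes, file.path(out_dir, "ctf_slopes.csv"))
    readr::write_csv(profiles, file.path(out_dir, "ctf_profiles.csv"))
    if (!is.null(window_averages)) {
      readr::write_csv(window_averages, file.path(out_dir, "window_averages.csv"))
    }
    if (!is.null(cluster)) {
      jsonlite::write_json(
        list(t_threshold = cluster$t_threshold, alpha = cluster$alpha,
             n_perm = cluster$n_perm, critical_mass = cluster$critical_mass,
             clusters = tidy(cluster)),
        file.path(out_dir, "cluster_test.json"), auto_unbox = TRUE, digits = NA
      )
    }
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(slopes = slopes, profiles = profiles,
       window_averages = window_averages, cluster = cluster, log = log)
}

validate_pipeline_config <- function(config) {
  if (is.null(config$synthetic) == is.null(config$input)) {
    abort("Config must contain exactly one of `synthetic` or `input`.")
  }
  out <- list(seed = config$seed)
  if (!is.null(config$synthetic)) {
    sim <- config$synthetic
    sim$config <- do.call(sim_config, as.list(sim$config %||% list()))
    sim$condition <- sim$condition %||% "one_item"
    if (length(sim$tuning_window %||% numeric(0)) != 2) {
      abort("`synthetic$tuning_window` must be c(onset, offset) in ms.")
    }
    sim$times <- sim$times %||% list(from = -500, to = 1480, by = 20)
    out$synthetic <- sim
    out$n_subjects <- sim$config$n_subjects
  } else {
    inp <- config$input
    if (length(inp$power_prefixes) != length(inp$trials_csvs)) {
      abort("`input$power_prefixes` and `input$trials_csvs` must be the same length.")
    }
    missing <- c(
      paste0(inp$power_prefixes, ".csv")[!file.exists(paste0(inp$power_prefixes, ".csv"))],
      paste0(inp$power_prefixes, ".json")[!file.exists(paste0(inp$power_prefixes, ".json"))],
      inp$trials_csvs[!file.exists(inp$trials_csvs)]
    )
    if (length(missing)) {
      abort(paste0("Missing input file(s): ", paste(missing, collapse = ", ")))
    }
    out$input <- inp
    out$n_subjects <- length(inp$power_prefixes)
  }
  iem <- config$iem %||% list()
  out$iem <- list(
    regime = iem$regime %||% "within_condition",
    n_iterations = iem$n_iterations %||% 10,
    n_sets = iem$n_sets %||% 3
  )
  out$windows <- lapply(config$windows %||% list(), unlist)
  out$cluster_test <- config$cluster_test
  out
}
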