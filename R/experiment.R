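#' Deterministic seed mixing
#'
#' Collapses a sequence of integers (and/or short strings, hashed by
#' character codes) into a single seed in `[1, 2^31 - 2]`, so every level of
#' the simulation (population, sample, criterion) gets its own reproducible
#' substream derived from the master seed.
#'
#' @param ... integers or strings.
#' @return a single integer seed.
#' @export
mix_seed <- function(...) {
  parts <- list(...)
  h <- 0
  for (p in parts) {
    xs <- if (is.character(p)) utf8ToInt(paste(p, collapse = "|")) else as.numeric(p)
    for (x in xs) h <- (h * 69069 + x + 1) %% 2147483629
  }
  as.integer(h + 1)
}

#' Enumerate the scenario grid
#'
#' The factorial design crosses communality level (low: 0.2/0.3/0.4, high:
#' 0.6/0.7/0.8), interfactor correlation (0, 0.5) and sample size (100,
#' 1000), giving 8 cells. The population matrix depends only on communality
#' and interfactor correlation, so the two sample sizes of a (communality,
#' correlation) pair share one deterministically seeded population -- four
#' distinct population correlation matrices in total.
#'
#' @param config a [default_config()] (or modified copy).
#' @return data frame with one row per cell: `cell`, `communality`
#'   (`"low"`/`"high"`), `theta`, `n_obs`, `population_seed`.
#' @export
build_scenario_grid <- function(config = default_config()) {
  grid <- expand.grid(communality = c("low", "high"),
                      theta = c(0, 0.5),
                      n_obs = c(100L, 1000L),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$communality == "high", grid$theta, grid$n_obs), ]
  grid$population_seed <- mapply(function(comm, th)
    mix_seed(config$master_seed, "population", comm, round(th * 10)),
    grid$communality, grid$theta)
  grid$cell <- sprintf("%s_t%02d_n%d", grid$communality,
                       as.integer(grid$theta * 10), grid$n_obs)
  rownames(grid) <- NULL
  grid[, c("cell", "communality", "theta", "n_obs", "population_seed")]
}

#' Default simulation configuration
#'
#' Mirrors the study design: J = 20 items, 3 major factors, 200 minor factors
#' with common ratio 0.8, communalities sampled from 0.2/0.3/0.4 (low) or
#' 0.6/0.7/0.8 (high), interfactor correlations 0 and 0.5, N of 100 and
#' 1000, 1000 replications per cell, all five analysis arms and nine
#' criteria, and k = 100 comparison datasets inside (revised) parallel
#' analysis.
#'
#' @param reps replications per cell.
#' @param master_seed master seed from which every substream is derived.
#' @param arms,criteria subsets of arm/criterion ids.
#' @return a config list.
#' @export
default_config <- function(reps = 1000L, master_seed = 42L,
                           arms = names(analysis_arms()),
                           criteria = all_criteria()) {
  list(n_items = 20L, n_major = 3L, n_minor = 200L,
       common_ratio = 0.8,
       communality_levels = list(low = c(0.2, 0.3, 0.4),
                                 high = c(0.6, 0.7, 0.8)),
       true_factors = 3L,
       reps = as.integer(reps),
       master_seed = as.integer(master_seed),
       arms = arms, criteria = criteria,
       k_parallel = 100L, gamma = 0.5,
       n_lambda = 100L, lambda_min_ratio = 0.01,
       walktrap_steps = 4L)
}

#' Criterion identifiers
#'
#' EV: Kaiser rule; AF: acceleration factor; AFEV: acceleration factor with
#' Kaiser bound; PAM / PA95: parallel analysis against mean / 95th-percentile
#' reference; RPA / RPAEV: revised parallel analysis without / with Kaiser
#' bound; MAP: minimum average partial; EGA: exploratory graph analysis.
#'
#' @return character vector of ids.
#' @export
all_criteria <- function() {
  c("EV", "AF", "AFEV", "PAM", "PA95", "RPA", "RPAEV", "MAP", "EGA")
}

#' Build the population model of a scenario cell
#'
#' @param cell one row of [build_scenario_grid()].
#' @param config the configuration the grid was built from.
#' @return a `population_model`.
#' @export
cell_population <- function(cell, config = default_config()) {
  spec <- population_spec(
    n_items = config$n_items, n_major = config$n_major,
    n_minor = config$n_minor,
    communality_levels = config$communality_levels[[cell$communality]],
    interfactor_corr = cell$theta,
    common_ratio = config$common_ratio,
    seed = cell$population_seed)
  assemble_population(spec)
}

#' Run one replication of one scenario cell
#'
#' Draws one continuous sample of the cell's size, dichotomizes copies at the
#' 50-50 and 75-25 thresholds, computes each requested arm's correlation
#' matrix once, and evaluates every requested criterion, each under its own
#' seed derived from (master seed, cell, replication, arm, criterion) so
#' criteria never share randomness and any single record can be reproduced in
#' isolation. Criterion failures are captured as `status = "missing"` rows
#' rather than propagated.
#'
#' @param cell one row of [build_scenario_grid()].
#' @param rep_index replication number.
#' @param config the configuration.
#' @param model optional prebuilt `population_model` for the cell.
#' @return data frame of trial records with columns `cell`, `communality`,
#'   `theta`, `n_obs`, `arm`, `rep`, `criterion`, `m_hat`, `correct`, `bias`,
#'   `status`.
#' @export
run_trial <- function(cell, rep_index, config = default_config(),
                      model = NULL) {
  if (is.null(model)) model <- cell_population(cell, config)
  true_m <- config$true_factors
  set.seed(mix_seed(config$master_seed, "sample", cell$cell, rep_index))
  Z <- draw_continuous_sample(model, cell$n_obs)
  arm_data <- list(cont = Z,
                   d50 = dichotomize(Z, 0),
                   d75 = dichotomize(Z, stats::qnorm(0.75)))
  arms <- analysis_arms(config$arms)
  out <- vector("list", length(arms) * length(config$criteria))
  slot <- 0L
  for (arm in arms) {
    dat <- switch(substr(arm$id, 1, 3),
                  con = arm_data$cont, d50 = arm_data$d50, d75 = arm_data$d75)
    Rarm <- tryCatch(arm_correlation(dat, arm), error = function(e) NULL)
    for (crit in config$criteria) {
      set.seed(mix_seed(config$master_seed, "criterion", cell$cell, rep_index,
                        arm$id, crit))
      m_hat <- if (is.null(Rarm)) NULL else
        tryCatch(evaluate_criterion(crit, dat, arm, Rarm, config),
                 error = function(e) NULL)
      slot <- slot + 1L
      out[[slot]] <- data.frame(
        cell = cell$cell, communality = cell$communality,
        theta = cell$theta, n_obs = cell$n_obs,
        arm = arm$id, rep = rep_index, criterion = crit,
        m_hat = if (is.null(m_hat)) NA_integer_ else as.integer(m_hat),
        correct = if (is.null(m_hat)) NA else m_hat == true_m,
        bias = if (is.null(m_hat)) NA_integer_ else as.integer(m_hat - true_m),
        status = if (is.null(m_hat)) "missing" else "ok",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Evaluate one retention criterion on arm-processed data
#'
#' Uniform entry point used by [run_trial()]; criteria are pure functions of
#' the arm correlation matrix except the parallel-analysis family and EGA,
#' which also consume the data dimensions and the current RNG stream.
#'
#' @param criterion one id from [all_criteria()].
#' @param data observed data in the arm's representation.
#' @param arm one element of [analysis_arms()].
#' @param obs_corr precomputed arm correlation (recomputed when `NULL`).
#' @param config configuration carrying the criterion parameters.
#' @return integer retained-factor count.
#' @export
evaluate_criterion <- function(criterion, data, arm, obs_corr = NULL,
                               config = default_config()) {
  if (is.null(obs_corr)) obs_corr <- arm_correlation(data, arm)
  spec <- eigen_spectrum(obs_corr)
  switch(criterion,
    EV = kaiser_count(spec),
    AF = acceleration_factor(spec),
    AFEV = combine_with_kaiser(acceleration_factor(spec), kaiser_count(spec)),
    PAM = parallel_analysis(data, arm, reference = "mean",
                            k = config$k_parallel, obs_corr = obs_corr),
    PA95 = parallel_analysis(data, arm, reference = "p95",
                             k = config$k_parallel, obs_corr = obs_corr),
    RPA = revised_parallel_analysis(data, arm, k = config$k_parallel,
                                    with_kaiser = FALSE, obs_corr = obs_corr),
    RPAEV = combine_with_kaiser(
      revised_parallel_analysis(data, arm, k = config$k_parallel,
                                with_kaiser = FALSE, obs_corr = obs_corr),
      kaiser_count(spec)),
    MAP = map_count(obs_corr),
    EGA = ega_count(data, arm, gamma = config$gamma,
                    n_lambda = config$n_lambda,
                    lambda_min_ratio = config$lambda_min_ratio,
                    steps = config$walktrap_steps),
    stop("unknown criterion: ", criterion))
}

#' Run the full Monte-Carlo experiment
#'
#' Iterates every scenario cell and replication, writing one record per
#' (cell, replication, arm, criterion). The result is a pure function of the
#' configuration (including its master seed): records are computed with
#' per-trial substreams, so serial and forked-parallel execution produce
#' identical tables.
#'
#' @param config a [default_config()].
#' @param out_dir optional directory; when given, `records.csv` and
#'   `manifest.json` are written there.
#' @param cores forked workers via `parallel::mclapply` (1 = serial).
#' @param progress print a line per cell.
#' @return data frame of all trial records.
#' @export
run_experiment <- function(config = default_config(), out_dir = NULL,
                           cores = 1L, progress = FALSE) {
  grid <- build_scenario_grid(config)
  all_records <- vector("list", nrow(grid))
  for (ci in seq_len(nrow(grid))) {
    cell <- grid[ci, ]
    model <- cell_population(cell, config)
    runner <- function(r) run_trial(cell, r, config, model = model)
    recs <- if (cores > 1L)
      parallel::mclapply(seq_len(config$reps), runner, mc.cores = cores)
    else lapply(seq_len(config$reps), runner)
    all_records[[ci]] <- do.call(rbind, recs)
    if (progress)
      message(sprintf("cell %s: %d replications done", cell$cell, config$reps))
  }
  records <- do.call(rbind, all_records)
  rownames(records) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(out_dir, "records.csv"),
                     row.names = FALSE)
    manifest <- list(config = config,
                     grid = grid,
                     n_records = nrow(records),
                     r_version = as.character(getRversion()),
                     timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  records
}
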