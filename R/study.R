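#' Configuration of a scenario-grid simulation study
#'
#' Describes a full sample-size simulation study: the underlying trajectory
#' shape, the observation schedule and drop-out time, and the grids of
#' error-precision, drop-out probability and fitted sample size, crossed
#' with replicate datasets. The defaults reproduce the cognitive-decline
#' design: shape (25, -1, -2) with change-point 5, five waves at
#' (0, 2, 4, 6, 8), drop-out at time 4, equal class probability 0.5,
#' `tau` in \{0.05, 0.1, 0.2\}, `p_d` in \{0.1, 0.3, 0.5, 0.7, 0.9\},
#' `k` in \{25, 50, 75, 100, 125, 150, 200, 300, 500\}, and 150 replicate
#' cohorts of 500 individuals per (`tau`, `p_d`) cell — 20,250 chains in
#' all. Each replicate cohort is simulated once at `n_individuals` and
#' reused across every `k` via [subset_first_k()], preserving the
#' within-replicate correlation across sample sizes.
#'
#' @param alpha,beta,delta,change_point True trajectory shape.
#' @param times Observation schedule.
#' @param t_d Drop-out time.
#' @param p_r Change-class probability.
#' @param tau_grid,pd_grid,k_grid Scenario grids.
#' @param n_reps Replicate datasets per (`tau`, `p_d`) cell.
#' @param n_individuals Individuals per simulated cohort (max of `k_grid`
#'   at least).
#' @param settings [chain_settings()] used for every fit (its `seed` is
#'   ignored; per-task seeds are derived from `master_seed`).
#' @param h Detection thresholds passed to the summaries.
#' @param delta_hastings Passed to [run_chain()] for every fit: `TRUE`
#'   (default) targets the exact posterior; `FALSE` reproduces the
#'   original-study variant of the change-magnitude proposal (no
#'   asymmetric-proposal correction).
#' @param master_seed Integer from which every task's dataset and chain
#'   seeds are derived deterministically, so any single task can be
#'   regenerated in isolation.
#' @param out_dir Directory for checkpoints and outputs (`NULL` for none).
#' @param workers Parallel worker processes for [run_study()].
#' @return An object of class `cp_study_config`.
#' @export
study_config <- function(alpha = 25, beta = -1, delta = -2, change_point = 5,
                         times = c(0, 2, 4, 6, 8), t_d = 4, p_r = 0.5,
                         tau_grid = c(0.05, 0.1, 0.2),
                         pd_grid = c(0.1, 0.3, 0.5, 0.7, 0.9),
                         k_grid = c(25, 50, 75, 100, 125, 150, 200, 300, 500),
                         n_reps = 150, n_individuals = 500,
                         settings = chain_settings(),
                         h = c(-0.05, -2, -3), delta_hastings = TRUE,
                         master_seed = 1, out_dir = NULL, workers = 1L) {
  stopifnot(length(tau_grid) >= 1L, all(tau_grid > 0),
            length(pd_grid) >= 1L, all(pd_grid >= 0 & pd_grid <= 1),
            length(k_grid) >= 1L, all(k_grid == round(k_grid)),
            n_reps >= 1L, n_individuals >= 1L,
            inherits(settings, "cp_chain_settings"))
  if (any(k_grid > n_individuals))
    stop("every k in 'k_grid' must be at most 'n_individuals'")
  structure(
    list(alpha = alpha, beta = beta, delta = delta,
         change_point = change_point, times = times, t_d = t_d, p_r = p_r,
         tau_grid = tau_grid, pd_grid = pd_grid, k_grid = k_grid,
         n_reps = as.integer(n_reps),
         n_individuals = as.integer(n_individuals),
         settings = settings, h = h,
         delta_hastings = isTRUE(delta_hastings),
         master_seed = as.integer(master_seed), out_dir = out_dir,
         workers = as.integer(workers)),
    class = "cp_study_config"
  )
}

# Deterministic per-task seeds below 2^31. The dataset seed depends only on
# (scenario, replicate) so all k-subsets of a replicate share one cohort;
# the chain seed additionally depends on k.
.task_seeds <- function(config, scenario_idx, rep, k_idx) {
  base <- config$master_seed %% 65536L
  dataset <- (base * 8192 + (scenario_idx - 1) * 512 + rep) %% 2^30
  chain <- 2^30 + (base * 131072 + (scenario_idx - 1) * 8192 +
                     (rep - 1) * 32 + k_idx) %% 2^30
  list(dataset = as.integer(dataset), chain = as.integer(chain))
}

.scenario_of <- function(config, tau, p_d) {
  cp_scenario(n = config$n_individuals,
              shape = cp_shape(config$alpha, config$beta, config$delta,
                               config$change_point, tau),
              p_r = config$p_r, p_d = p_d, times = config$times,
              t_d = config$t_d)
}

#' Enumerate the task grid of a study
#'
#' Expands the configuration into one task per (scenario, replicate, k)
#' combination — `length(tau_grid) * length(pd_grid) * n_reps *
#' length(k_grid)` rows (20,250 under the defaults) — each carrying its
#' deterministic dataset and chain seeds.
#'
#' @param config A [study_config()] object.
#' @return Data frame with columns `scenario_idx`, `tau`, `p_d`, `rep`,
#'   `k`, `dataset_seed`, `chain_seed`.
#' @export
build_grid <- function(config) {
  stopifnot(inherits(config, "cp_study_config"))
  cells <- expand.grid(tau = config$tau_grid, p_d = config$pd_grid,
                       KEEP.OUT.ATTRS = FALSE)
  cells$scenario_idx <- seq_len(nrow(cells))
  grid <- merge(
    merge(cells, data.frame(rep = seq_len(config$n_reps))),
    data.frame(k = config$k_grid)
  )
  grid <- grid[order(grid$scenario_idx, grid$rep, grid$k), ]
  k_idx <- match(grid$k, config$k_grid)
  seeds <- mapply(function(s, r, ki) unlist(.task_seeds(config, s, r, ki)),
                  grid$scenario_idx, grid$rep, k_idx)
  grid$dataset_seed <- seeds["dataset", ]
  grid$chain_seed <- seeds["chain", ]
  rownames(grid) <- NULL
  grid[, c("scenario_idx", "tau", "p_d", "rep", "k",
           "dataset_seed", "chain_seed")]
}

# Run one (scenario, replicate) unit: simulate the cohort once, fit every
# k-subset, return replicate records (one row per k).
.run_replicate <- function(config, tau, p_d, scenario_idx, rep) {
  scenario <- .scenario_of(config, tau, p_d)
  seeds0 <- .task_seeds(config, scenario_idx, rep, 1L)
  dataset <- simulate_dataset(scenario, seed = seeds0$dataset)
  rows <- lapply(seq_along(config$k_grid), function(ki) {
    k <- config$k_grid[ki]
    seeds <- .task_seeds(config, scenario_idx, rep, ki)
    sett <- config$settings
    sett$seed <- seeds$chain
    sub <- subset_first_k(dataset, k)
    chain <- run_chain(sub, sett, change_point = config$change_point,
                       p_r = config$p_r,
                       delta_hastings = config$delta_hastings)
    rec <- replicate_record(chain, sub, scenario, h = config$h)
    rec$rep <- rep
    rec$scenario_idx <- scenario_idx
    rec
  })
  do.call(rbind, rows)
}

#' Run a scenario-grid study
#'
#' Executes every (scenario, replicate, k) task of the configuration:
#' simulates each replicate cohort once, fits every k-subset with its own
#' deterministic chain seed, reduces each fit to a [replicate_record()],
#' and aggregates records into one [summarize_scenario()]-style row per
#' (`tau`, `p_d`, `k`) cell. Results are identical for a given
#' `master_seed` regardless of worker count or execution order.
#'
#' When `config$out_dir` is set, per-replicate record files are
#' checkpointed under `<out_dir>/records/` and finished units are skipped
#' on re-run, so an interrupted study resumes; the aggregated table is
#' written to `<out_dir>/summary.csv` and a manifest of any failed units to
#' `<out_dir>/manifest.json`. Unit failures are reported in the manifest
#' (and as a warning) without aborting the rest of the grid.
#'
#' @param config A [study_config()] object.
#' @return Data frame of scenario summaries, one row per
#'   (`tau`, `p_d`, `k`), including the `expected_post_cp_n` design column
#'   `k * (1 - p_d)`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "cp_study_config"))
  rec_dir <- NULL
  if (!is.null(config$out_dir)) {
    rec_dir <- file.path(config$out_dir, "records")
    dir.create(rec_dir, recursive = TRUE, showWarnings = FALSE)
  }
  cells <- expand.grid(tau = config$tau_grid, p_d = config$pd_grid,
                       KEEP.OUT.ATTRS = FALSE)
  cells$scenario_idx <- seq_len(nrow(cells))
  units <- merge(cells, data.frame(rep = seq_len(config$n_reps)))
  units <- units[order(units$scenario_idx, units$rep), ]

  one_unit <- function(u) {
    ckpt <- if (!is.null(rec_dir))
      file.path(rec_dir, sprintf("s%03d_r%04d.csv", u$scenario_idx, u$rep))
    if (!is.null(ckpt) && file.exists(ckpt))
      return(list(ok = TRUE, rows = utils::read.csv(ckpt,
                                                    check.names = FALSE)))
    res <- tryCatch(
      .run_replicate(config, u$tau, u$p_d, u$scenario_idx, u$rep),
      error = function(e) e)
    if (inherits(res, "error"))
      return(list(ok = FALSE, unit = u, message = conditionMessage(res)))
    if (!is.null(ckpt)) utils::write.csv(res, ckpt, row.names = FALSE)
    list(ok = TRUE, rows = res)
  }

  unit_list <- split(units, seq_len(nrow(units)))
  results <- if (config$workers > 1L) {
    parallel::mclapply(unit_list, one_unit, mc.cores = config$workers)
  } else {
    lapply(unit_list, one_unit)
  }

  failures <- Filter(function(r) !isTRUE(r$ok), results)
  if (length(failures) > 0L)
    warning(length(failures), " task unit(s) failed; see manifest")
  rows <- do.call(rbind, lapply(Filter(function(r) isTRUE(r$ok), results),
                                `[[`, "rows"))
  summary_tab <- do.call(rbind, lapply(split(
    rows, interaction(rows$scenario_idx, rows$k, drop = TRUE)),
    function(g) {
      scen <- .scenario_of(config, g$tau_true[1], g$p_d[1])
      aggregate_records(g, scen, k = g$k[1])
    }))
  summary_tab <- summary_tab[order(summary_tab$tau_true, summary_tab$p_d,
                                   summary_tab$k), ]
  rownames(summary_tab) <- NULL
  if (!is.null(config$out_dir)) {
    utils::write.csv(summary_tab, file.path(config$out_dir, "summary.csv"),
                     row.names = FALSE)
    manifest <- list(
      n_units = nrow(units),
      n_failed = length(failures),
      failures = lapply(failures, function(f)
        list(scenario_idx = f$unit$scenario_idx, rep = f$unit$rep,
             message = f$message)))
    jsonlite::write_json(manifest, file.path(config$out_dir,
                                             "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  summary_tab
}
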