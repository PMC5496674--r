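#' Mean absolute error of per-replicate estimates
#'
#' Averages the absolute deviations of per-replicate point estimates
#' (posterior medians) from the scenario's true parameter value:
#' `mean(|estimate_l - truth|)`.
#'
#' @param estimates Numeric vector of per-replicate posterior medians.
#' @param truth Scalar true value for the scenario.
#' @return Non-negative scalar.
#' @export
mae_over_reps <- function(estimates, truth) {
  if (length(estimates) == 0L) stop("'estimates' must be non-empty")
  stopifnot(is.numeric(estimates), is.numeric(truth), length(truth) == 1L)
  mean(abs(estimates - truth))
}

#' Highest posterior density interval and average length criterion
#'
#' `hpd_interval()` estimates the `level` HPD interval from posterior
#' samples by the empirical shortest-window rule: among all contiguous
#' windows of the sorted samples containing `ceiling(level * N)` of them,
#' it returns the narrowest (ties broken by the smallest lower bound).
#' `alc()` is the width of that interval; averaged over replicates it is
#' the average length criterion used as a Bayesian precision target in
#' sample-size design. Note the shortest single interval is reported even
#' when the posterior is multimodal, where an HPD region would be a union
#' of intervals.
#'
#' @param samples Numeric vector of posterior draws (at least 20).
#' @param level Coverage level in (0, 1).
#' @return `hpd_interval()`: named numeric `c(lower, upper)`; `alc()`:
#'   scalar width.
#' @examples
#' hpd_interval(0:99, 0.95)  # c(0, 94)
#' @export
hpd_interval <- function(samples, level = 0.95) {
  stopifnot(is.numeric(samples), is.numeric(level), length(level) == 1L,
            level > 0, level < 1)
  n <- length(samples)
  if (n < 20) stop("need at least 20 samples for an HPD interval")
  x <- sort(samples)
  m <- ceiling(level * n)
  widths <- x[m:n] - x[seq_len(n - m + 1)]
  i <- which.min(widths)  # which.min takes the first minimum: smallest lower bound
  c(lower = x[i], upper = x[i + m - 1])
}

#' @rdname hpd_interval
#' @export
alc <- function(samples, level = 0.95) {
  unname(diff(hpd_interval(samples, level)))
}

#' Posterior probability that the change-magnitude is below a threshold
#'
#' The fraction of retained draws strictly below `h`. With a prior
#' restricted to the negative reals, `P(delta < 0) = 1` by construction, so
#' change-point detection is read off at a small negative threshold
#' (default `h = -0.05`): `P(delta < h)` near 1 indicates the posterior has
#' moved decisively away from zero.
#'
#' @param samples Numeric vector of posterior draws (typically of delta).
#' @param h Threshold (scalar).
#' @return Fraction in \[0, 1\].
#' @export
prob_below <- function(samples, h = -0.05) {
  if (length(samples) == 0L) stop("'samples' must be non-empty")
  stopifnot(is.numeric(samples), is.numeric(h), length(h) == 1L)
  mean(samples < h)
}

#' ROC curve and AUROC of posterior change probabilities
#'
#' `roc_curve()` sweeps the assignment threshold over all distinct scores
#' and returns the (false positive rate, true positive rate) points, from
#' (0, 0) to (1, 1). `auroc()` computes the area under that curve by the
#' rank (Mann-Whitney) statistic, with tied scores contributing half — which
#' equals the trapezoidal area under the swept curve. An AUROC of 1 is a
#' perfect classifier; 0.5 is random assignment.
#'
#' @param scores Numeric vector of per-individual posterior change
#'   probabilities (any monotone score works).
#' @param labels True binary labels (0/1), same length. Both classes must
#'   be present; otherwise an error of class `stickcp_degenerate_labels` is
#'   signalled, which summary aggregation converts to a missing value.
#' @return `roc_curve()`: data frame with columns `fpr`, `tpr` (threshold
#'   decreasing); `auroc()`: scalar in \[0, 1\].
#' @export
roc_curve <- function(scores, labels) {
  .check_roc_input(scores, labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # cumulative counts at each distinct-score cut (ties enter together)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l)[last_of_tie]
  fp <- cumsum(1 - l)[last_of_tie]
  data.frame(fpr = c(0, fp / sum(1 - l)), tpr = c(0, tp / sum(l)))
}

#' @rdname roc_curve
#' @export
auroc <- function(scores, labels) {
  .check_roc_input(scores, labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)  # midranks: ties get half credit
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.check_roc_input <- function(scores, labels) {
  stopifnot(is.numeric(scores), length(scores) == length(labels),
            all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2L)
    stop(structure(
      class = c("stickcp_degenerate_labels", "error", "condition"),
      list(message = "both classes must be present in 'labels'",
           call = sys.call(-1))))
}

#' Individuals with observations past the change-point
#'
#' Classification into change / no change is only well defined for
#' individuals actually observed after the change-point; individuals lost
#' to follow-up before `c` carry no information about their own label (under
#' MCAR drop-out their posterior change probability is exactly the prior
#' `p_r`), so including them drags the AUROC towards 0.5. This helper
#' returns the indices (positions in `unique(data$long$id)` order) of
#' individuals with at least one observation at `t > c`.
#'
#' @param data A [cp_data] object.
#' @param change_point The change-point time `c`; defaults to the
#'   scenario's.
#' @return Integer vector of indices (possibly empty).
#' @export
post_cp_indices <- function(data,
                            change_point = data$scenario$shape$change_point) {
  stopifnot(inherits(data, "cp_data"))
  ids <- unique(data$long$id)
  past <- unique(data$long$id[data$long$time > change_point])
  which(ids %in% past)
}

#' Aggregate replicate chains into a scenario summary
#'
#' Computes the per-scenario summary measures over replicates: for each of
#' `alpha`, `beta`, `delta`, `tau` the mean absolute error of the posterior
#' median ([mae_over_reps()]), the mean posterior variance, and the mean
#' 95% ALC; the mean detection probability `P(delta < h)` for each
#' threshold in `h`; and the AUROC of the posterior change probabilities
#' against the true labels, over all individuals and over the subset with
#' observations past the change-point. For `tau` the relative (scaled)
#' summaries, divided by the scenario's true `tau`, are also reported so
#' that scenarios with different precisions are comparable.
#'
#' Replicates where an AUROC is undefined (all individuals in one class)
#' are recorded as missing and reduce that AUROC's effective replicate
#' count rather than failing the aggregation.
#'
#' @param chains List of `cp_chain` objects, one per replicate.
#' @param datasets List of [cp_data] objects aligned with `chains` (source
#'   of the truth tables; each must contain the individuals its chain
#'   fitted).
#' @param scenario The generating [cp_scenario()] (source of true values).
#' @param k Fitted sample size (defaults to the first chain's `n_fitted`).
#' @param h Numeric vector of detection thresholds.
#' @param level HPD coverage level for the ALC.
#' @return A one-row data frame (class `cp_scenario_summary`) with columns
#'   `tau_true`, `p_d`, `k`, `expected_post_cp_n`, `n_reps`,
#'   `mae_/var_/alc_` for each parameter, `mae_tau_rel`, `var_tau_rel`,
#'   `alc_tau_rel`, one `p_below_*` column per threshold, `auroc_all`,
#'   `auroc_post_cp` and their effective replicate counts.
#' @export
summarize_scenario <- function(chains, datasets, scenario,
                               k = chains[[1]]$n_fitted,
                               h = c(-0.05, -2, -3), level = 0.95) {
  stopifnot(length(chains) >= 1L, length(chains) == length(datasets),
            inherits(scenario, "cp_scenario"))
  recs <- do.call(rbind, mapply(
    function(ch, d) replicate_record(ch, d, scenario, h = h, level = level),
    chains, datasets, SIMPLIFY = FALSE))
  aggregate_records(recs, scenario, k = k)
}

#' Per-replicate summary record of one fitted chain
#'
#' Reduces one replicate's posterior chain to the quantities the scenario
#' summary averages: posterior medians, variances and 95% ALCs of the four
#' parameters, the detection probabilities `P(delta < h)`, and the AUROC of
#' the posterior change probabilities over all fitted individuals and over
#' the post-change-point subset (`NA` when only one class is present).
#' [summarize_scenario()] is the mean of these records over replicates, so
#' study runners can checkpoint records and aggregate later.
#'
#' @inheritParams summarize_scenario
#' @param chain One `cp_chain`.
#' @param dataset The [cp_data] the chain was fitted to (or its superset;
#'   truth labels are matched by individual id).
#' @return A one-row data frame.
#' @export
replicate_record <- function(chain, dataset, scenario,
                             h = c(-0.05, -2, -3), level = 0.95) {
  stopifnot(inherits(chain, "cp_chain"), inherits(dataset, "cp_data"),
            inherits(scenario, "cp_scenario"))
  out <- list(tau_true = scenario$shape$tau, p_d = scenario$p_d,
              k = chain$n_fitted)
  for (p in names(chain$draws)) {
    out[[paste0("med_", p)]] <- stats::median(chain$draws[[p]])
    out[[paste0("var_", p)]] <- stats::var(chain$draws[[p]])
    out[[paste0("alc_", p)]] <- alc(chain$draws[[p]], level = level)
  }
  for (hh in h)
    out[[paste0("p_below_", hh)]] <- prob_below(chain$draws$delta, hh)
  scores <- unname(chain$label_prob)
  labs <- dataset$truth$true_label[match(names(chain$label_prob),
                                         dataset$truth$id)]
  safe_auc <- function(idx) {
    if (length(idx) == 0L) return(NA_real_)
    tryCatch(auroc(scores[idx], labs[idx]),
             stickcp_degenerate_labels = function(e) NA_real_)
  }
  fitted <- dataset
  fitted$long <- dataset$long[
    as.character(dataset$long$id) %in% names(chain$label_prob), ,
    drop = FALSE]
  out$auroc_all <- safe_auc(seq_along(scores))
  out$auroc_post_cp <-
    safe_auc(post_cp_indices(fitted, scenario$shape$change_point))
  as.data.frame(out, check.names = FALSE)
}

#' @rdname replicate_record
#' @param records Data frame of rows from `replicate_record()` for one
#'   (scenario, k) cell.
#' @export
aggregate_records <- function(records, scenario, k = records$k[1]) {
  stopifnot(nrow(records) >= 1L, inherits(scenario, "cp_scenario"))
  truth <- list(alpha = scenario$shape$alpha, beta = scenario$shape$beta,
                delta = scenario$shape$delta, tau = scenario$shape$tau)
  out <- list(tau_true = scenario$shape$tau, p_d = scenario$p_d, k = k,
              expected_post_cp_n = expected_post_cp_n(k, scenario$p_d),
              n_reps = nrow(records))
  for (p in names(truth)) {
    out[[paste0("mae_", p)]] <-
      mae_over_reps(records[[paste0("med_", p)]], truth[[p]])
    out[[paste0("var_", p)]] <- mean(records[[paste0("var_", p)]])
    out[[paste0("alc_", p)]] <- mean(records[[paste0("alc_", p)]])
  }
  out$mae_tau_rel <- out$mae_tau / truth$tau
  out$var_tau_rel <- out$var_tau / truth$tau
  out$alc_tau_rel <- out$alc_tau / truth$tau
  for (col in grep("^p_below_", names(records), value = TRUE))
    out[[col]] <- mean(records[[col]])
  out$auroc_all <- mean(records$auroc_all, na.rm = TRUE)
  out$n_reps_auroc_all <- sum(!is.na(records$auroc_all))
  out$auroc_post_cp <- mean(records$auroc_post_cp, na.rm = TRUE)
  out$n_reps_auroc_post_cp <- sum(!is.na(records$auroc_post_cp))
  structure(as.data.frame(out, check.names = FALSE),
            class = c("cp_scenario_summary", "data.frame"))
}

#' LOWESS trend utility for summary plots
#'
#' Thin wrapper around [stats::lowess()] for drawing smoothed trends of a
#' summary measure against the expected post-change-point sample size, as
#' used when plotting scenario grids.
#'
#' @param x,y Numeric vectors (e.g. expected post-change-point sample size
#'   and a summary measure).
#' @param span Smoother span `f` passed to [stats::lowess()].
#' @return Data frame with columns `x`, `y` of smoothed values.
#' @export
smooth_trend <- function(x, y, span = 2 / 3) {
  stopifnot(length(x) == length(y))
  s <- stats::lowess(x, y, f = span)
  data.frame(x = s$x, y = s$y)
}
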