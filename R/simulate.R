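#' Define a simulation scenario
#'
#' A scenario is one design cell of a longitudinal cohort simulation: the
#' first-wave sample size, the underlying trajectory shape, the probability
#' of change-class membership, a fixed observation schedule, and a monotone
#' completely-at-random (MCAR) drop-out mechanism with a single drop-out
#' time `t_d` and per-individual drop-out probability `p_d`. Individuals who
#' drop out are observed at all scheduled times up to and including `t_d`
#' and never again; drop-out is independent of class membership and of the
#' outcomes.
#'
#' @param n Number of individuals at the first wave.
#' @param shape A [cp_shape()] object (defaults to the
#'   cognitive-decline-inspired shape: alpha 25, beta -1, delta -2, c 5).
#' @param p_r Probability of change-class membership, in \[0, 1\].
#' @param p_d Drop-out probability, in \[0, 1\].
#' @param times Fixed observation schedule (strictly increasing, first time 0).
#' @param t_d Drop-out time; must be one of `times`.
#' @return An object of class `cp_scenario`.
#' @examples
#' sc <- cp_scenario(n = 75, p_d = 0.5)
#' @export
cp_scenario <- function(n, shape = cp_shape(), p_r = 0.5, p_d = 0.1,
                        times = c(0, 2, 4, 6, 8), t_d = 4) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, n == round(n),
            inherits(shape, "cp_shape"),
            is.numeric(p_r), length(p_r) == 1L, p_r >= 0, p_r <= 1,
            is.numeric(p_d), length(p_d) == 1L, p_d >= 0, p_d <= 1,
            is.numeric(times), length(times) >= 1L)
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing")
  if (times[1] != 0) stop("first observation time must be 0")
  if (!t_d %in% times) stop("'t_d' must be one of the scheduled times")
  if (shape$change_point <= t_d)
    warning("change-point at or before the drop-out time: dropped-out ",
            "individuals will have post-change-point observations")
  structure(
    list(n = as.integer(n), shape = shape, p_r = p_r, p_d = p_d,
         times = times, t_d = t_d),
    class = "cp_scenario"
  )
}

#' @export
print.cp_scenario <- function(x, ...) {
  cat(sprintf("Scenario: n = %d, p_r = %g, p_d = %g, t_d = %g, times = (%s)\n",
              x$n, x$p_r, x$p_d, x$t_d, paste(x$times, collapse = ", ")))
  print(x$shape)
  invisible(x)
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so simulation calls do not perturb it.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Simulate one longitudinal dataset under a scenario
#'
#' For each individual independently: a class label is drawn Bernoulli(p_r),
#' a drop-out flag Bernoulli(p_d) (independent of the label and of all
#' outcomes — MCAR), observation times are the full schedule for retained
#' individuals or the times up to `t_d` for drop-outs, and outcomes are the
#' noise-free trajectory mean plus independent Normal(0, 1/tau) errors.
#'
#' The true labels and drop-out flags are stored in a separate `truth` table
#' so that fitting functions can be handed the observations alone; they are
#' never consulted by [run_chain()].
#'
#' @param scenario A [cp_scenario()] object.
#' @param seed Integer seed; with the same seed the dataset is
#'   bit-reproducible. If `NULL`, the current RNG stream is used.
#' @return An object of class `cp_data`: a list with
#'   \describe{
#'     \item{`long`}{data frame `id`, `time`, `outcome` (long format).}
#'     \item{`truth`}{data frame `id`, `true_label`, `dropped_out`.}
#'     \item{`scenario`}{the generating scenario.}
#'     \item{`seed`}{the seed used (or `NA`).}
#'   }
#' @examples
#' d <- simulate_dataset(cp_scenario(n = 50, p_d = 0.5), seed = 1)
#' table(d$truth$dropped_out)
#' @export
simulate_dataset <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "cp_scenario"))
  gen <- function() {
    n <- scenario$n
    labels <- stats::rbinom(n, 1L, scenario$p_r)
    dropped <- stats::rbinom(n, 1L, scenario$p_d)
    pre_times <- scenario$times[scenario$times <= scenario$t_d]
    times_i <- lapply(seq_len(n), function(i)
      if (dropped[i] == 1L) pre_times else scenario$times)
    m_i <- lengths(times_i)
    id <- rep.int(seq_len(n), m_i)
    tt <- unlist(times_i, use.names = FALSE)
    mu <- cp_mean(scenario$shape, labels[id], tt)
    y <- mu + stats::rnorm(length(tt), sd = 1 / sqrt(scenario$shape$tau))
    list(long = data.frame(id = id, time = tt, outcome = y),
         truth = data.frame(id = seq_len(n), true_label = labels,
                            dropped_out = dropped))
  }
  parts <- if (is.null(seed)) gen() else with_seed(seed, gen())
  structure(
    list(long = parts$long, truth = parts$truth, scenario = scenario,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "cp_data"
  )
}

#' @export
print.cp_data <- function(x, ...) {
  cat(sprintf("Longitudinal dataset: %d individuals, %d observations\n",
              nrow(x$truth), nrow(x$long)))
  invisible(x)
}

#' Restrict a dataset to its first k individuals
#'
#' Sample-size sub-studies reuse one simulated cohort: the subset of size
#' `k` is simply the first `k` individuals in generation order, so subsets
#' are nested (`subset_first_k(subset_first_k(d, 300), 100)` equals
#' `subset_first_k(d, 100)`).
#'
#' @param data A [cp_data] object.
#' @param k Number of individuals to keep, `1 <= k <= n`.
#' @return A `cp_data` object containing the first `k` individuals.
#' @export
subset_first_k <- function(data, k) {
  stopifnot(inherits(data, "cp_data"))
  n <- nrow(data$truth)
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 1 || k > n)
    stop("'k' must be an integer in [1, ", n, "]")
  keep <- data$truth$id[seq_len(k)]
  out <- data
  out$long <- data$long[data$long$id %in% keep, , drop = FALSE]
  out$truth <- data$truth[seq_len(k), , drop = FALSE]
  rownames(out$long) <- NULL
  rownames(out$truth) <- NULL
  out
}

#' Expected post-change-point sample size
#'
#' With a single drop-out time before the change-point and drop-out
#' probability `p_d`, the expected number of individuals still under
#' observation after the change-point is `n * (1 - p_d)`. This univariate
#' design metric lets first-wave size and attrition be traded off: for
#' example `n = 100, p_d = 0.1` and `n = 300, p_d = 0.7` both give 90.
#'
#' @param n First-wave sample size(s).
#' @param p_d Drop-out probability(ies) in \[0, 1\].
#' @return `n * (1 - p_d)`, vectorized.
#' @examples
#' expected_post_cp_n(100, 0.1)  # 90
#' expected_post_cp_n(300, 0.7)  # 90
#' @export
expected_post_cp_n <- function(n, p_d) {
  stopifnot(is.numeric(n), all(n >= 0), is.numeric(p_d),
            all(p_d >= 0 & p_d <= 1))
  n * (1 - p_d)
}

#' Write / read a simulated dataset as plain-text files
#'
#' `write_cp_data()` writes three files under `prefix`: `<prefix>_data.csv`
#' (long-format observations: `id`, `time`, `outcome`),
#' `<prefix>_truth.csv` (the true labels and drop-out flags, kept apart so a
#' fit can be run blinded), and `<prefix>_scenario.json` (the generating
#' scenario). `read_cp_data()` reads them back; with `truth = FALSE` the
#' truth table is left out entirely, which is the form handed to fitting
#' code.
#'
#' @param data A [cp_data] object.
#' @param prefix File path prefix (directory must exist).
#' @param truth Logical: read the truth table?
#' @return `write_cp_data()` returns `prefix` invisibly; `read_cp_data()`
#'   returns a `cp_data` object (with `truth = NULL` if not requested).
#' @export
write_cp_data <- function(data, prefix) {
  stopifnot(inherits(data, "cp_data"))
  utils::write.csv(data$long, paste0(prefix, "_data.csv"), row.names = FALSE)
  utils::write.csv(data$truth, paste0(prefix, "_truth.csv"), row.names = FALSE)
  sc <- data$scenario
  meta <- list(
    n = sc$n, p_r = sc$p_r, p_d = sc$p_d, times = sc$times, t_d = sc$t_d,
    shape = list(alpha = sc$shape$alpha, beta = sc$shape$beta,
                 delta = sc$shape$delta, change_point = sc$shape$change_point,
                 tau = sc$shape$tau),
    seed = data$seed
  )
  jsonlite::write_json(meta, paste0(prefix, "_scenario.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_cp_data
#' @export
read_cp_data <- function(prefix, truth = TRUE) {
  meta <- jsonlite::read_json(paste0(prefix, "_scenario.json"),
                              simplifyVector = TRUE)
  scenario <- cp_scenario(
    n = meta$n,
    shape = cp_shape(meta$shape$alpha, meta$shape$beta, meta$shape$delta,
                     meta$shape$change_point, meta$shape$tau),
    p_r = meta$p_r, p_d = meta$p_d, times = meta$times, t_d = meta$t_d
  )
  structure(
    list(long = utils::read.csv(paste0(prefix, "_data.csv")),
         truth = if (truth) utils::read.csv(paste0(prefix, "_truth.csv")),
         scenario = scenario,
         seed = if (is.null(meta$seed)) NA_integer_ else meta$seed),
    class = "cp_data"
  )
}
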