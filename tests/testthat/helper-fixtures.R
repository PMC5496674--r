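# Hand-built longitudinal fixtures (bypassing the simulator) for oracle
# tests: construct a cp_data object from per-individual times and outcomes.
make_cp_data <- function(times_list, outcomes_list, labels = NULL,
                         dropped = NULL, scenario = NULL) {
  n <- length(times_list)
  stopifnot(length(outcomes_list) == n)
  id <- rep.int(seq_len(n), lengths(times_list))
  structure(
    list(long = data.frame(id = id,
                           time = unlist(times_list, use.names = FALSE),
                           outcome = unlist(outcomes_list, use.names = FALSE)),
         truth = data.frame(
           id = seq_len(n),
           true_label = if (is.null(labels)) rep(NA_integer_, n) else labels,
           dropped_out = if (is.null(dropped)) rep(NA_integer_, n) else dropped),
         scenario = scenario, seed = NA_integer_),
    class = "cp_data"
  )
}

# Default shape used throughout: the cognitive-decline design truth.
default_shape <- function(tau = 0.2) cp_shape(25, -1, -2, 5, tau)

# Short chain settings for tests that only need a mixed chain, not the
# full-length default.
short_settings <- function(seed, iterations = 2e4, burn_in = 1e3, thin = 10) {
  chain_settings(iterations = iterations, burn_in = burn_in, thin = thin,
                 seed = seed)
}
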