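#' Proposal dispersion scaling with sample size
#'
#' With more individuals the posterior tightens, so a fixed random-walk
#' proposal would mix very differently across sample sizes. All proposal
#' standard deviations are therefore multiplied by
#' `f(n) = log(25) / log(n)`, anchored so that `f(25) = 1` (25 being the
#' smallest sample size the default study grid considers) and decreasing
#' slowly towards zero as `n` grows.
#'
#' @param n Number of fitted individuals, `n >= 2`.
#' @return `log(25) / log(n)`; lies in (0, 1\] for `n >= 25`. For
#'   `2 <= n < 25` the factor exceeds 1 and a warning is issued.
#' @examples
#' f_scale(25)   # 1
#' f_scale(625)  # 0.5
#' @export
f_scale <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L)
  if (n < 2) stop("'n' must be at least 2")
  f <- log(25) / log(n)
  if (n < 25)
    warning("n < 25: proposal scaling factor exceeds 1 (f(n) = ",
            signif(f, 4), ")")
  f
}

#' Prior specification for the trajectory parameters
#'
#' Uninformative but proper priors: Normal(0, sd 10) on the intercept and
#' slope, a half-normal with scale 10 restricted to the negative reals on
#' the change-magnitude (the direction of change is known a priori), and
#' Gamma(shape 1, rate 1) on the error precision. Latent labels get
#' independent Bernoulli(`p_r`) priors, supplied separately to the sampler.
#'
#' @param sd_alpha,sd_beta Normal prior standard deviations for intercept
#'   and slope.
#' @param scale_delta Half-normal scale for the change-magnitude.
#' @param tau_shape,tau_rate Gamma prior shape and rate for the precision.
#' @return A named list of class `cp_priors`.
#' @export
cp_priors <- function(sd_alpha = 10, sd_beta = 10, scale_delta = 10,
                      tau_shape = 1, tau_rate = 1) {
  stopifnot(sd_alpha > 0, sd_beta > 0, scale_delta > 0, tau_shape > 0,
            tau_rate > 0)
  structure(list(sd_alpha = sd_alpha, sd_beta = sd_beta,
                 scale_delta = scale_delta, tau_shape = tau_shape,
                 tau_rate = tau_rate),
            class = "cp_priors")
}

#' Joint log prior density of the trajectory parameters
#'
#' Sum of the log prior densities under [cp_priors()]. Values outside the
#' support (`delta >= 0` or `tau <= 0`) return `-Inf`, which is how the
#' samplers reject proposals that leave the support.
#'
#' @param shape A [cp_shape()] object, or any list with elements `alpha`,
#'   `beta`, `delta`, `tau` (a plain list may carry out-of-support values).
#' @param priors A [cp_priors()] object.
#' @return Scalar log prior density (possibly `-Inf`).
#' @export
log_prior <- function(shape, priors = cp_priors()) {
  stopifnot(inherits(priors, "cp_priors"))
  if (shape$delta >= 0 || shape$tau <= 0) return(-Inf)
  stats::dnorm(shape$alpha, 0, priors$sd_alpha, log = TRUE) +
    stats::dnorm(shape$beta, 0, priors$sd_beta, log = TRUE) +
    log(2) + stats::dnorm(shape$delta / priors$scale_delta, log = TRUE) -
    log(priors$scale_delta) +
    stats::dgamma(shape$tau, shape = priors$tau_shape,
                  rate = priors$tau_rate, log = TRUE)
}

#' MCMC chain settings
#'
#' Defaults follow common practice for this model class: `1e5` iterations,
#' the first `1e3` discarded as burn-in, and every 50th retained thereafter
#' (1980 retained draws), which keeps the auto-correlation of the retained
#' sample low. Proposal base scales are multiplied by [f_scale()] of the
#' fitted sample size.
#'
#' @param iterations Total MCMC sweeps.
#' @param burn_in Initial sweeps discarded.
#' @param thin Keep every `thin`-th sweep after burn-in.
#' @param base_scales Named numeric: random-walk proposal base scales for
#'   `alpha`, `beta`, `tau` (Gaussian sd) and `delta` (log-normal log-sd).
#' @param priors A [cp_priors()] object.
#' @param seed Integer seed for the chain (initial values and all proposal
#'   randomness). `NULL` uses the current RNG stream.
#' @return An object of class `cp_chain_settings`.
#' @export
chain_settings <- function(iterations = 1e5, burn_in = 1e3, thin = 50,
                           base_scales = c(alpha = 1.2, beta = 0.85,
                                           delta = 1.0, tau = 0.85),
                           priors = cp_priors(), seed = NULL) {
  stopifnot(iterations == round(iterations), burn_in == round(burn_in),
            thin == round(thin), thin >= 1, burn_in >= 0,
            inherits(priors, "cp_priors"))
  if (burn_in >= iterations) stop("'burn_in' must be smaller than 'iterations'")
  nm <- c("alpha", "beta", "delta", "tau")
  if (!all(nm %in% names(base_scales)) || any(base_scales <= 0))
    stop("'base_scales' must be positive and named alpha, beta, delta, tau")
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 base_scales = base_scales[nm], priors = priors,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "cp_chain_settings")
}

#' One Metropolis-Hastings update of a single trajectory parameter
#'
#' Performs a single MH step on `alpha`, `beta`, `delta` or `tau`,
#' conditional on the rest of `state` (including the labels). `alpha`,
#' `beta` and `tau` use symmetric Gaussian random walks with sd
#' `f_scale(n) * base_scale`; proposals of `tau <= 0` are rejected through
#' the prior's zero density. `delta` uses the multiplicative proposal
#' `delta' = delta * X` with `X` log-normal (log-sd `f_scale(n) *
#' base_scale`), which preserves the negative sign; the acceptance ratio
#' includes the asymmetric-proposal correction `|delta'| / |delta|` so the
#' chain targets the stated posterior exactly.
#'
#' This is the reference R implementation of the update used inside
#' [run_chain()]'s compiled sweep; it is exported so single steps can be
#' composed and checked directly.
#'
#' @param which One of `"alpha"`, `"beta"`, `"delta"`, `"tau"`.
#' @param state Named list with `alpha`, `beta`, `delta`, `tau` and
#'   `labels` (binary vector, one per individual).
#' @param data A [cp_data] object (only `data$long` is read).
#' @param change_point The fixed change-point time `c`.
#' @param settings A [chain_settings()] object (proposal scales, priors).
#' @return List with `value` (the new parameter value), `accepted`
#'   (logical) and `state` (the state with the update applied).
#' @export
mh_update_scalar <- function(which, state, data, change_point,
                             settings = chain_settings()) {
  if (!which %in% c("alpha", "beta", "delta", "tau"))
    stop("unknown parameter name: ", which)
  n <- length(unique(data$long$id))
  f <- suppressWarnings(f_scale(n))
  sc <- f * settings$base_scales[[which]]
  cur <- state[[which]]
  log_hastings <- 0
  if (which == "delta") {
    lx <- stats::rnorm(1, 0, sc)
    prop <- cur * exp(lx)
    log_hastings <- lx  # log(|delta'| / |delta|)
  } else {
    prop <- stats::rnorm(1, cur, sc)
  }
  prop_state <- state
  prop_state[[which]] <- prop
  lp_prop <- .log_target(prop_state, data, change_point, settings$priors)
  lp_cur <- .log_target(state, data, change_point, settings$priors)
  accept <- log(stats::runif(1)) < (lp_prop - lp_cur + log_hastings)
  out_state <- if (accept) prop_state else state
  list(value = out_state[[which]], accepted = accept, state = out_state)
}

# Unnormalized log posterior of the trajectory parameters given labels.
.log_target <- function(state, data, change_point, priors) {
  shape_raw <- list(alpha = state$alpha, beta = state$beta,
                    delta = state$delta, tau = state$tau)
  lp <- log_prior(shape_raw, priors)
  if (!is.finite(lp)) return(-Inf)
  shape <- cp_shape(state$alpha, state$beta, state$delta, change_point,
                    state$tau)
  lp + cp_loglik(data, shape, state$labels)
}

#' Full-conditional change probability and Gibbs draw of the labels
#'
#' Under data augmentation each latent label has an exact full conditional:
#' `P(r_i = 1 | .) = p_r * L_i1 / (p_r * L_i1 + (1 - p_r) * L_i0)`, where
#' `L_i1`, `L_i0` are individual `i`'s likelihoods under each class.
#' Observations at or before the change-point contribute identically to
#' both classes and cancel, so an individual with no observations past `c`
#' has conditional probability exactly `p_r`. Computed on the log scale.
#'
#' `label_change_prob()` returns the probabilities; `update_labels()` draws
#' one Bernoulli label per individual from them.
#'
#' @param data A [cp_data] object (only `data$long` is read).
#' @param shape A [cp_shape()] object (current trajectory parameters).
#' @param p_r Prior change-class probability.
#' @return `label_change_prob()`: numeric vector of conditional
#'   probabilities, one per individual (in `unique(data$long$id)` order).
#'   `update_labels()`: binary integer vector of the same length.
#' @export
label_change_prob <- function(data, shape, p_r) {
  stopifnot(inherits(shape, "cp_shape"), p_r >= 0, p_r <= 1)
  long <- data$long
  ids <- unique(long$id)
  post <- long$time > shape$change_point
  r0 <- long$outcome - cp_mean(shape, 0, long$time)
  r1 <- long$outcome - cp_mean(shape, 1, long$time)
  # only post-change-point observations differ between classes
  dss <- vapply(ids, function(i) {
    sel <- post & long$id == i
    sum(r1[sel]^2) - sum(r0[sel]^2)
  }, numeric(1))
  if (p_r <= 0) return(rep(0, length(ids)))
  if (p_r >= 1) return(rep(1, length(ids)))
  log_odds <- log(p_r) - log1p(-p_r) - 0.5 * shape$tau * dss
  # individuals with no post-c information sit exactly at the prior
  ifelse(dss == 0, p_r, stats::plogis(log_odds))
}

#' @rdname label_change_prob
#' @export
update_labels <- function(data, shape, p_r) {
  p <- label_change_prob(data, shape, p_r)
  as.integer(stats::runif(length(p)) < p)
}

#' Run the data-augmented MCMC sampler
#'
#' Fits the two-class broken-stick model by Metropolis-Hastings within
#' Gibbs: per sweep, one MH update each for `alpha`, `beta`, `delta`,
#' `tau` (see [mh_update_scalar()] for the proposal families), then an
#' exact Gibbs draw of every latent class label from its full conditional.
#' The change-point `c` and the class prior `p_r` are treated as known.
#' The sweep itself runs in compiled code; `set.seed`-compatible R
#' randomness makes chains reproducible.
#'
#' The sampler is blinded: it reads only observation times and outcomes
#' (`data$long`), never the simulation truth table.
#'
#' Initial values: `alpha` at the mean first-wave outcome, `beta` at the
#' pooled least-squares slope of the pre-change-point observations,
#' `delta = -0.1`, `tau = 1`, labels drawn Bernoulli(`p_r`). Any parameter
#' named in `fixed` is held at the given value and never updated.
#'
#' @param data A [cp_data] object.
#' @param settings A [chain_settings()] object.
#' @param change_point The fixed change-point time `c`; defaults to the
#'   value recorded in `data$scenario`.
#' @param p_r Prior change-class probability; defaults to the scenario's.
#' @param fixed Optional named numeric vector holding a subset of
#'   `alpha`, `beta`, `delta`, `tau` at fixed values (useful for
#'   conditional-posterior checks).
#' @param delta_hastings Logical, default `TRUE`: include the
#'   `|delta'| / |delta|` asymmetric-proposal correction in the
#'   change-magnitude update, so the chain targets the stated posterior
#'   exactly. `FALSE` omits the correction — the chain then targets the
#'   modified density proportional to `posterior(delta) / |delta|`, which
#'   is improper at 0 (a flat plateau in `log|delta|`) and piles mass
#'   arbitrarily close to zero whenever the data only weakly support a
#'   change. This variant is provided for replicating and probing
#'   published detection-probability curves produced by uncorrected
#'   multiplicative proposals; do not use it for inference.
#' @return An object of class `cp_chain`: list with `draws` (data frame of
#'   retained `alpha`, `beta`, `delta`, `tau` draws), `label_prob`
#'   (per-individual posterior change probability, the mean of retained
#'   label draws), `acceptance` (per-parameter acceptance rates),
#'   `n_fitted`, `change_point`, `p_r`, `init`, `settings`.
#' @examples
#' d <- simulate_dataset(cp_scenario(n = 40, p_d = 0.1), seed = 1)
#' ch <- run_chain(d, chain_settings(iterations = 2000, burn_in = 200,
#'                                   thin = 5, seed = 1))
#' apply(ch$draws, 2, stats::median)
#' @export
run_chain <- function(data, settings = chain_settings(),
                      change_point = data$scenario$shape$change_point,
                      p_r = data$scenario$p_r, fixed = NULL,
                      delta_hastings = TRUE) {
  stopifnot(inherits(data, "cp_data"), inherits(settings, "cp_chain_settings"))
  long <- data$long
  if (is.null(long) || nrow(long) == 0L) stop("empty dataset")
  if (is.null(change_point) || is.null(p_r))
    stop("'change_point' and 'p_r' must be supplied when the dataset ",
         "carries no scenario")
  ids <- unique(long$id)
  n <- length(ids)
  fixed_names <- c("alpha", "beta", "delta", "tau")
  fixed_mask <- fixed_names %in% names(fixed)
  if (!is.null(fixed) && !all(names(fixed) %in% fixed_names))
    stop("'fixed' may only name alpha, beta, delta, tau")

  run <- function() {
    init <- list(
      alpha = mean(long$outcome[long$time == min(long$time)]),
      beta = {
        pre <- long$time <= change_point
        stats::cov(long$time[pre], long$outcome[pre]) /
          stats::var(long$time[pre])
      },
      delta = -0.1, tau = 1,
      labels = stats::rbinom(n, 1L, p_r)
    )
    for (nm in names(fixed)) init[[nm]] <- unname(fixed[[nm]])
    pri <- settings$priors
    res <- .cp_chain_cpp(
      long$outcome, long$time, match(long$id, ids) - 1L,
      n, change_point, p_r,
      settings$iterations, settings$burn_in, settings$thin,
      init$alpha, init$beta, init$delta, init$tau, init$labels,
      unname(settings$base_scales),
      c(pri$sd_alpha, pri$sd_beta, pri$scale_delta, pri$tau_shape,
        pri$tau_rate),
      suppressWarnings(f_scale(n)), fixed_mask, isTRUE(delta_hastings))
    list(init = init, res = res)
  }
  out <- if (is.null(settings$seed)) run() else with_seed(settings$seed, run())
  res <- out$res
  structure(
    list(draws = data.frame(alpha = res$alpha, beta = res$beta,
                            delta = res$delta, tau = res$tau),
         label_prob = stats::setNames(res$label_prob, ids),
         acceptance = stats::setNames(res$acceptance, fixed_names),
         n_fitted = n, change_point = change_point, p_r = p_r,
         init = out$init[fixed_names], settings = settings),
    class = "cp_chain"
  )
}

#' @export
print.cp_chain <- function(x, ...) {
  cat(sprintf("Posterior chain: %d retained draws, %d individuals\n",
              nrow(x$draws), x$n_fitted))
  med <- apply(x$draws, 2, stats::median)
  cat("  posterior medians:",
      paste(sprintf("%s = %.3g", names(med), med), collapse = ", "), "\n")
  cat("  acceptance rates:",
      paste(sprintf("%s = %.2f", names(x$acceptance), x$acceptance),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a posterior chain as plain-text files
#'
#' `write_cp_chain()` writes `<prefix>_draws.csv` (retained parameter
#' draws), `<prefix>_labels.csv` (per-individual posterior change
#' probabilities) and `<prefix>_meta.json` (settings, acceptance rates,
#' initial values). `read_cp_chain()` reads them back.
#'
#' @param chain A `cp_chain` object from [run_chain()].
#' @param prefix File path prefix.
#' @return `write_cp_chain()` returns `prefix` invisibly; `read_cp_chain()`
#'   a `cp_chain` object.
#' @export
write_cp_chain <- function(chain, prefix) {
  stopifnot(inherits(chain, "cp_chain"))
  utils::write.csv(chain$draws, paste0(prefix, "_draws.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(id = names(chain$label_prob),
                              label_prob = unname(chain$label_prob)),
                   paste0(prefix, "_labels.csv"), row.names = FALSE)
  s <- chain$settings
  meta <- list(iterations = s$iterations, burn_in = s$burn_in,
               thin = s$thin, base_scales = as.list(s$base_scales),
               priors = unclass(s$priors), seed = s$seed,
               change_point = chain$change_point, p_r = chain$p_r,
               n_fitted = chain$n_fitted,
               acceptance = as.list(chain$acceptance),
               init = chain$init)
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_cp_chain
#' @export
read_cp_chain <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  labs <- utils::read.csv(paste0(prefix, "_labels.csv"))
  structure(
    list(draws = utils::read.csv(paste0(prefix, "_draws.csv")),
         label_prob = stats::setNames(labs$label_prob, labs$id),
         acceptance = unlist(meta$acceptance),
         n_fitted = meta$n_fitted, change_point = meta$change_point,
         p_r = meta$p_r, init = meta$init,
         settings = chain_settings(meta$iterations, meta$burn_in, meta$thin,
                                   unlist(meta$base_scales),
                                   do.call(cp_priors, meta$priors),
                                   seed = meta$seed)),
    class = "cp_chain"
  )
}
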