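#' Trajectory shape parameters for the two-class broken-stick model
#'
#' Bundles the fixed-effect parameters of a broken-stick trajectory with two
#' latent classes. Individuals in the no-change class follow the line
#' \eqn{\alpha + \beta t} throughout; individuals in the change class follow
#' the same line up to the common change-point \eqn{c} and thereafter the
#' line \eqn{\alpha' + (\beta + \delta) t} with \eqn{\alpha' = \alpha -
#' \delta c}, so the two segments join with no discontinuity at \eqn{t = c}.
#' Observation error is Gaussian with precision \eqn{\tau = 1/\sigma^2}.
#'
#' The change-magnitude \eqn{\delta} is restricted to the negative reals: the
#' direction of change (accelerated decline) is taken as known a priori,
#' which also sidesteps the label-switching non-identifiability of a
#' two-class mixture.
#'
#' @param alpha Intercept at `t = 0` (outcome units).
#' @param beta Pre-change slope (outcome units per time unit).
#' @param delta Change-magnitude: the increment added to the slope after the
#'   change-point. Must be strictly negative.
#' @param change_point Time `c` of the slope change, common to all change-class
#'   individuals. Must be non-negative.
#' @param tau Error precision `1/sigma^2`. Must be strictly positive.
#'
#' @return An object of class `cp_shape`: a named list with the five
#'   parameters plus the derived change-class intercept `alpha_change`
#'   (\eqn{\alpha - \delta c}).
#' @examples
#' sh <- cp_shape(alpha = 25, beta = -1, delta = -2, change_point = 5, tau = 0.2)
#' sh$alpha_change  # 35: the post-change segment extrapolated back to t = 0
#' @export
cp_shape <- function(alpha = 25, beta = -1, delta = -2, change_point = 5,
                     tau = 0.2) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta),
            is.numeric(delta), length(delta) == 1L, is.finite(delta),
            is.numeric(change_point), length(change_point) == 1L,
            is.finite(change_point), change_point >= 0,
            is.numeric(tau), length(tau) == 1L, is.finite(tau))
  if (tau <= 0) stop("'tau' (error precision) must be strictly positive")
  if (delta >= 0) stop("'delta' (change-magnitude) must be strictly negative")
  structure(
    list(alpha = alpha, beta = beta, delta = delta,
         change_point = change_point, tau = tau,
         alpha_change = alpha - delta * change_point),
    class = "cp_shape"
  )
}

#' @export
print.cp_shape <- function(x, ...) {
  cat("Broken-stick shape parameters:\n")
  cat(sprintf("  alpha = %g, beta = %g, delta = %g, c = %g, tau = %g (sigma = %.3g)\n",
              x$alpha, x$beta, x$delta, x$change_point, x$tau, 1 / sqrt(x$tau)))
  invisible(x)
}

#' Noise-free mean trajectory value
#'
#' Evaluates the deterministic mean of the broken-stick model at time(s) `t`
#' for an individual with the given class label: `alpha + beta * t` for the
#' no-change class (and for the change class up to the change-point), and
#' `(alpha - delta * c) + (beta + delta) * t` for the change class past the
#' change-point. The two branches agree exactly at `t = c`.
#'
#' @param shape A [cp_shape()] object.
#' @param label Class label, 0 (no change) or 1 (change). Scalar or vector
#'   recycled against `t`.
#' @param t Observation time(s), non-negative.
#' @return Numeric vector of mean outcome values, same length as `t`.
#' @examples
#' sh <- cp_shape(25, -1, -2, 5, 0.2)
#' cp_mean(sh, label = 0, t = 8)       # 17
#' cp_mean(sh, label = 1, t = c(5, 8)) # 20 11
#' @export
cp_mean <- function(shape, label, t) {
  stopifnot(inherits(shape, "cp_shape"), all(label %in% c(0, 1)),
            is.numeric(t), all(t >= 0))
  post <- label == 1 & t > shape$change_point
  ifelse(post,
         shape$alpha_change + (shape$beta + shape$delta) * t,
         shape$alpha + shape$beta * t)
}

#' Gaussian log-likelihood of longitudinal data given labels
#'
#' Sums, over every observation of every individual, the normal log-density
#' with mean [cp_mean()] under the individual's class label and precision
#' `shape$tau`. All error terms are independent between and within
#' individuals.
#'
#' @param data A [cp_data] object (see [simulate_dataset()]), or any list with
#'   a `long` data frame holding columns `id`, `time`, `outcome`.
#' @param shape A [cp_shape()] object (`tau > 0` enforced at construction).
#' @param labels Binary vector with one label per individual, aligned with
#'   the order of unique `id`s in `data$long`.
#' @return The scalar log-likelihood.
#' @export
cp_loglik <- function(data, shape, labels) {
  stopifnot(inherits(shape, "cp_shape"))
  long <- data$long
  ids <- unique(long$id)
  if (length(labels) != length(ids))
    stop("'labels' must have one entry per individual")
  if (!all(labels %in% c(0, 1))) stop("'labels' must be binary")
  lab_obs <- labels[match(long$id, ids)]
  mu <- cp_mean(shape, lab_obs, long$time)
  sum(stats::dnorm(long$outcome, mean = mu, sd = 1 / sqrt(shape$tau),
                   log = TRUE))
}
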