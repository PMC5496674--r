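test_that("proposal scaling factor is log(25)/log(n)", {
  expect_equal(f_scale(25), 1)
  expect_equal(f_scale(625), 0.5)
  expect_equal(f_scale(500), log(25) / log(500), tolerance = 1e-12)
  expect_error(f_scale(1), "at least 2")
  expect_warning(f_scale(10), "exceeds 1")
})

test_that("log prior matches the closed-form component densities", {
  pri <- cp_priors()
  val <- log_prior(list(alpha = 0.7, beta = -1.2, delta = -0.001, tau = 1),
                   pri)
  oracle <- dnorm(0.7, 0, 10, log = TRUE) + dnorm(-1.2, 0, 10, log = TRUE) +
    (log(2) + dnorm(-0.001 / 10, log = TRUE) - log(10)) +
    dgamma(1, 1, 1, log = TRUE)
  expect_equal(val, oracle, tolerance = 1e-12)

  # support sentinels
  expect_identical(log_prior(list(alpha = 0, beta = 0, delta = 1, tau = 1)),
                   -Inf)
  expect_identical(log_prior(list(alpha = 0, beta = 0, delta = 0, tau = 1)),
                   -Inf)
  expect_identical(log_prior(list(alpha = 0, beta = 0, delta = -1, tau = 0)),
                   -Inf)

  # normal mode: maximized over alpha at 0
  lp <- function(a) log_prior(list(alpha = a, beta = 0, delta = -1, tau = 1))
  expect_true(all(lp(0) > sapply(c(-3, -0.5, 0.5, 3), lp)))
})

test_that("retention follows the burn-in then thin convention", {
  d <- simulate_dataset(cp_scenario(n = 25, p_d = 0), seed = 3)
  ch <- run_chain(d, chain_settings(iterations = 1000, burn_in = 100,
                                    thin = 9, seed = 1))
  expect_equal(nrow(ch$draws), (1000 - 100) %/% 9)
  # default settings retain (1e5 - 1e3) / 50 = 1980 draws
  s <- chain_settings()
  expect_equal((s$iterations - s$burn_in) %/% s$thin, 1980L)
  expect_error(chain_settings(iterations = 100, burn_in = 100), "burn_in")
})

test_that("label full conditional is the two-term Bayes ratio", {
  sh <- default_shape(tau = 0.2)
  sd <- 1 / sqrt(0.2)

  # no observations past c: probability is exactly the prior p_r
  d_pre <- make_cp_data(list(c(0, 2, 4)), list(c(26, 22, 20)))
  for (pr in c(0.2, 0.5, 0.9))
    expect_identical(label_change_prob(d_pre, sh, pr), pr)

  # p_r = 1 forces all labels to 1
  d2 <- make_cp_data(list(c(0, 8), c(0, 8)), list(c(25, 12), c(24, 18)))
  expect_identical(label_change_prob(d2, sh, 1), c(1, 1))
  expect_identical(update_labels(d2, sh, 1), c(1L, 1L))
  expect_identical(label_change_prob(d2, sh, 0), c(0, 0))

  # single post-c observation: hand-computed two-term ratio
  y <- 13.5
  d1 <- make_cp_data(list(8), list(y))
  for (pr in c(0.3, 0.5, 0.8)) {
    l1 <- dnorm(y, cp_mean(sh, 1, 8), sd)
    l0 <- dnorm(y, cp_mean(sh, 0, 8), sd)
    expect_equal(label_change_prob(d1, sh, pr),
                 pr * l1 / (pr * l1 + (1 - pr) * l0), tolerance = 1e-12)
  }
})

test_that("single-parameter MH updates obey their proposal contracts", {
  d <- simulate_dataset(cp_scenario(n = 30, p_d = 0.1), seed = 4)
  state <- list(alpha = 24, beta = -1, delta = -1.5, tau = 0.3,
                labels = d$truth$true_label)
  expect_error(mh_update_scalar("gamma", state, d, 5), "unknown parameter")

  # the multiplicative delta proposal never flips the sign
  set.seed(21)
  st <- state
  for (i in 1:200) {
    st <- mh_update_scalar("delta", st, d, 5)$state
    expect_lt(st$delta, 0)
  }
  # tau stays positive
  st <- state
  for (i in 1:200) {
    st <- mh_update_scalar("tau", st, d, 5)$state
    expect_gt(st$tau, 0)
  }
})

test_that("alpha updates reproduce the conjugate normal conditional", {
  # 2 individuals, 4 observations; beta, delta, tau and labels held fixed,
  # so the alpha conditional is Normal by conjugacy with the N(0, 10^2)
  # prior. Oracle computed in closed form.
  sh <- default_shape(tau = 0.2)
  times <- list(c(0, 6), c(2, 8))
  labels <- c(1, 0)
  outcomes <- list(cp_mean(sh, 1, times[[1]]) + c(1.5, -2),
                   cp_mean(sh, 0, times[[2]]) + c(0.5, 1))
  d <- make_cp_data(times, outcomes, labels = labels)

  offsets <- unlist(mapply(function(tt, lab) cp_mean(sh, lab, tt) - sh$alpha,
                           times, labels, SIMPLIFY = FALSE))
  z <- d$long$outcome - offsets
  v <- 1 / (0.2 * length(z) + 1 / 100)
  m <- v * 0.2 * sum(z)

  # route 1: repeated R-level MH steps
  set.seed(31)
  state <- list(alpha = 20, beta = sh$beta, delta = sh$delta, tau = sh$tau,
                labels = labels)
  draws <- replicate(4000, {
    state <<- mh_update_scalar("alpha", state, d, 5)$state
    state$alpha
  })
  draws <- draws[-(1:500)]
  expect_equal(mean(draws), m, tolerance = 0.15)
  expect_equal(sd(draws), sqrt(v), tolerance = 0.15)

  # route 2: the compiled chain with the other parameters fixed and
  # labels pinned at 1 through p_r = 1
  off1 <- unlist(lapply(times, function(tt) cp_mean(sh, 1, tt) - sh$alpha))
  z1 <- d$long$outcome - off1
  v1 <- 1 / (0.2 * length(z1) + 1 / 100)
  m1 <- v1 * 0.2 * sum(z1)
  ch <- run_chain(d, short_settings(seed = 8, iterations = 6e4, thin = 5),
                  change_point = 5, p_r = 1,
                  fixed = c(beta = sh$beta, delta = sh$delta, tau = sh$tau))
  expect_equal(mean(ch$draws$alpha), m1, tolerance = 0.2)
  expect_equal(sd(ch$draws$alpha), sqrt(v1), tolerance = 0.2)
  expect_true(all(ch$draws$beta == sh$beta))
  expect_true(is.na(ch$acceptance["beta"]))
})

test_that("chain matches brute-force label enumeration + delta grid", {
  # 2 individuals with post-change-point data; alpha, beta, tau fixed at
  # truth so the joint posterior over (delta, labels) is tractable by
  # enumerating the 4 label configurations and integrating delta on a
  # fine grid.
  sh <- default_shape(tau = 0.2)
  times <- list(c(0, 2, 6, 8), c(0, 2, 6, 8))
  outcomes <- list(cp_mean(sh, 1, times[[1]]) + c(0.5, -1, 1, -0.5),
                   cp_mean(sh, 0, times[[2]]) + c(-0.3, 0.8, -1, 0.2))
  d <- make_cp_data(times, outcomes)
  p_r <- 0.5

  # the grid must cover the deep tail: under the all-no-change label
  # configuration the delta posterior reverts to its half-normal(0, 10)
  # prior, which keeps appreciable mass beyond -12
  grid <- seq(-50, -1e-4, length.out = 50000)
  prior_d <- 2 * dnorm(grid / 10) / 10
  loglik_cfg <- function(r) {
    vapply(grid, function(dl) {
      shl <- cp_shape(25, -1, dl, 5, 0.2)
      cp_loglik(d, shl, r)
    }, numeric(1))
  }
  cfgs <- list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  ll <- sapply(cfgs, loglik_cfg)                      # grid x 4
  pr_cfg <- vapply(cfgs, function(r)
    p_r^sum(r) * (1 - p_r)^(2 - sum(r)), numeric(1))
  w <- exp(sweep(ll, 2, log(pr_cfg), "+") - max(ll)) * prior_d
  post_cfg <- colSums(w) / sum(w)
  oracle_p1 <- c(post_cfg[3] + post_cfg[4], post_cfg[2] + post_cfg[4])
  oracle_mean_delta <- sum(rowSums(w) * grid) / sum(w)

  ch <- run_chain(d, short_settings(seed = 12, iterations = 8e4, thin = 5),
                  change_point = 5, p_r = p_r,
                  fixed = c(alpha = 25, beta = -1, tau = 0.2))
  expect_equal(unname(ch$label_prob), oracle_p1, tolerance = 0.05)
  expect_equal(mean(ch$draws$delta), oracle_mean_delta, tolerance = 0.15)
})

test_that("retained draws respect the parameter supports", {
  d <- simulate_dataset(cp_scenario(n = 50, p_d = 0.3,
                                    shape = default_shape(0.1)), seed = 6)
  ch <- run_chain(d, short_settings(seed = 2, iterations = 1e4))
  expect_true(all(ch$draws$delta < 0))
  expect_true(all(ch$draws$tau > 0))
  expect_true(all(ch$label_prob >= 0 & ch$label_prob <= 1))
})

test_that("inference is blinded to the truth columns", {
  d <- simulate_dataset(cp_scenario(n = 40, p_d = 0.3), seed = 8)
  d_perturbed <- d
  d_perturbed$truth$true_label <- 1L - d_perturbed$truth$true_label
  d_perturbed$truth$dropped_out <- 1L
  ch1 <- run_chain(d, short_settings(seed = 5, iterations = 5e3))
  ch2 <- run_chain(d_perturbed, short_settings(seed = 5, iterations = 5e3))
  expect_identical(ch1$draws, ch2$draws)
  expect_identical(ch1$label_prob, ch2$label_prob)
})

test_that("chains move but do not degenerate across sample sizes", {
  # Proposal dispersions shrink with f(n); every parameter must keep a
  # strictly interior acceptance rate (the chain neither freezes nor
  # accepts everything) from the smallest to the largest design size.
  for (n in c(25, 100, 500)) {
    d <- simulate_dataset(cp_scenario(n = n, p_d = 0.1), seed = 100 + n)
    ch <- run_chain(d, short_settings(seed = n, iterations = 1e4))
    expect_true(all(ch$acceptance > 0 & ch$acceptance < 1),
                label = paste("acceptance rates interior at n =", n))
  }
})

test_that("labels stay uninformed when no one is observed past c", {
  d <- simulate_dataset(cp_scenario(n = 60, p_d = 1,
                                    shape = default_shape(0.2)), seed = 13)
  ch <- run_chain(d, short_settings(seed = 3, iterations = 1e4))
  # every individual's posterior change probability is near the prior 0.5
  expect_lt(max(abs(ch$label_prob - 0.5)), 0.1)
})

test_that("chains round-trip through CSV plus JSON sidecar", {
  d <- simulate_dataset(cp_scenario(n = 25, p_d = 0.1), seed = 14)
  ch <- run_chain(d, short_settings(seed = 4, iterations = 2e3))
  prefix <- file.path(withr::local_tempdir(), "chain")
  write_cp_chain(ch, prefix)
  back <- read_cp_chain(prefix)
  expect_equal(back$draws, ch$draws)
  expect_equal(unname(back$label_prob), unname(ch$label_prob))
  expect_equal(back$settings$thin, ch$settings$thin)
  expect_equal(back$acceptance, ch$acceptance)
})
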