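---
title: "Broken-stick change-point models with unlabelled sub-groups: model, sampler, and study-design measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Broken-stick change-point models with unlabelled sub-groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stickcp)
```

## The model

`stickcp` studies a fixed-effect broken-stick trajectory with two latent
classes. Individual $i$ has $m_i$ observations $y_{ij}$ at times $t_{ij}$
(first observation aligned at $t_{i1} = 0$), and an unobserved binary label
$r_i$:

$$
y_{ij} = \begin{cases}
\alpha + \beta t_{ij} + \varepsilon_{ij} & r_i = 0,\ \text{or } r_i = 1,\ t_{ij} \le c\\
(\alpha - \delta c) + (\beta + \delta) t_{ij} + \varepsilon_{ij} & r_i = 1,\ t_{ij} > c
\end{cases}
$$

with $\varepsilon_{ij} \sim N(0, 1/\tau)$ independent within and between
individuals. The change-class intercept $\alpha' = \alpha - \delta c$ makes
the two segments join with no discontinuity at the common change-point
$c$ — the defining feature of the broken-stick family. The
change-magnitude $\delta$ is restricted to the negative reals: the package
targets settings such as cognitive decline where the direction of change is
known a priori, and the sign restriction removes the label-switching
non-identifiability of a symmetric two-class mixture. Class membership is
Bernoulli with known probability $p_r$, and $c$ is treated as known; neither
is estimated.

The default numerical setting is inspired by longitudinal cognition
cohorts scored with the MMSE (0–30 scale, treated as continuous):
$\alpha = 25$, $\beta = -1$ (one point lost per year), $\delta = -2$
(accelerated decline of three points per year past the change-point),
$c = 5$ years, five waves at years $(0, 2, 4, 6, 8)$, and error precisions
$\tau \in \{0.05, 0.1, 0.2\}$, i.e. error standard deviations of about
4.47, 3.16 and 2.24 points. Outcomes are *not* clipped to $[0, 30]$: with
$\sigma^2 = 20$ the generator can and does exceed the scale, and clipping
would break the Gaussian error model that the sampler assumes.

## The observation (drop-out) model

Attrition is modelled as monotone and completely at random (MCAR): every
individual is observed at all scheduled times up to and including a single
drop-out time $t_d$ (default year 4), then with probability $p_d$ is never
observed again. Drop-out is independent of the class label and of all
outcomes, so the missingness factors out of the likelihood as a constant;
its only effect is to thin the information available after the
change-point. Because $t_d = 4 < c = 5$, dropped-out individuals carry *no*
information about their own label — their posterior change probability is
exactly $p_r$ — which is why classification summaries distinguish the
post-change-point subset. Outcome-dependent (MAR/MNAR) drop-out and
per-wave hazards are out of scope.

The design metric that organizes every summary is the **expected
post-change-point sample size** $n(1 - p_d)$: the expected number of
individuals still observed at the final wave. Different $(n, p_d)$ pairs
with the same product are "comparable designs" (e.g. $n = 100, p_d = 0.1$
and $n = 300, p_d = 0.7$ both give 90).

## Posterior computation

Labels are brought into the parameter space by data augmentation, giving
the tractable augmented posterior
$\pi(\alpha, \beta, \delta, \tau, r \mid y) \propto
L(y \mid \alpha, \beta, \delta, \tau, r)\, L(r \mid p_r)\,
\pi(\alpha, \beta, \delta, \tau)$.
Priors are proper but uninformative: $\alpha, \beta \sim N(0, 10^2)$,
$\delta \sim$ half-normal$(0, 10^2)$ on the negative reals,
$\tau \sim$ Gamma$(1, 1)$, $r_i \sim$ Bernoulli$(p_r)$.

One sweep of the sampler (`run_chain()`, compiled) performs:

* Metropolis random-walk updates for $\alpha$, $\beta$ and $\tau$ with
  Gaussian proposals of standard deviation $f(n) \cdot (1.2, 0.85, 0.85)$
  respectively; $\tau' \le 0$ is rejected through the prior's zero density
  rather than reflected (the simplest exactly-correct treatment).
* A multiplicative update for $\delta$: $\delta' = \delta X$ with
  $X \sim$ log-normal$(0, (f(n) \cdot 1.0)^2)$, which preserves the sign.
  This proposal is asymmetric, and the acceptance ratio includes the
  Hastings correction $q(\delta \mid \delta')/q(\delta' \mid \delta) =
  |\delta'|/|\delta|$ so the chain targets the stated posterior exactly
  (see the next section for what happens without it).
* An exact Gibbs draw of every label from its full conditional
  $P(r_i = 1 \mid \cdot) = p_r L_{i1} / (p_r L_{i1} + (1 - p_r) L_{i0})$,
  computed on the log scale. Gibbs rather than a Metropolis step is the
  natural lowest-variance choice once the full conditional is available in
  closed form; observations at $t \le c$ cancel from the ratio, so
  individuals without post-change-point data sit exactly at $p_r$.

The proposal dispersion factor $f(n) = \log 25 / \log n$ shrinks proposals
as the fitted sample size grows, keeping mixing comparable across the
design grid; it is anchored at 1 for $n = 25$, the smallest design size
the default grid considers. Sample sizes below 25 are permitted with a
warning ($f > 1$ there). With these (deliberately simple, non-adaptive)
proposals the acceptance rates are low for $\tau$ in particular (a few
percent, since the $\tau$ proposal scale of $0.85 f(n)$ is far wider than
the $\tau$ posterior); combined with thinning every 50th sweep this still
yields draws accurate enough for every summary below, as the
parameter-recovery and brute-force-oracle tests verify, but users fitting
single datasets in anger may prefer to tighten the $\tau$ base scale.

Chains default to $10^5$ iterations, $10^3$ discarded as burn-in, and
every 50th sweep retained thereafter — $(10^5 - 10^3)/50 = 1980$ retained
draws. Initial values are cheap data-driven guesses recorded in the chain
object: $\alpha_0$ the mean first-wave outcome, $\beta_0$ the pooled
least-squares slope of pre-change-point observations (identical in the two
classes there, so no blinding is broken), $\delta_0 = -0.1$,
$\tau_0 = 1$, labels drawn from the prior. The sampler reads only times
and outcomes — never the simulator's truth columns — and its output is a
pure function of those plus the settings and seed.

## The Hastings correction, and a degenerate detection statistic

Two facts about this model interact in a way anyone using it for
change-point *detection* should understand.

First, the detection statistic $P(\delta < h)$ with a small threshold
(default $h = -0.05$) is nearly degenerate under the exact posterior. The
half-normal$(0, 10^2)$ prior places only about 0.4% of its mass in
$(-0.05, 0)$, so even a posterior carrying *no* information about
$\delta$ satisfies $P(\delta < -0.05) \approx 0.996$. For the posterior
to report a low detection probability, its mass must be actively
compressed into that sliver next to zero — which a correctly targeted
chain essentially never does. Under the exact posterior, detection
probabilities at the default design are close to 1 at every grid cell,
as both `run_chain()` and an independent general-purpose Gibbs sampler
confirm.

Second, multiplicative log-normal proposals are an easy place to omit the
required Hastings factor, and the omission is consequential rather than
cosmetic: without it the chain targets
$\pi(\delta)/|\delta|$, which is *improper* — in $\log|\delta|$ space the
region near zero becomes an infinite flat plateau. The chain then drifts
arbitrarily close to zero whenever the likelihood only weakly resists,
piling mass into the $(-h, 0)$ sliver and producing detection
probabilities that climb smoothly from near 0 to 1 as the information in
the data (error precision, post-change-point sample size) grows.
`run_chain(delta_hastings = FALSE)` reproduces this behaviour on purpose,
so that published detection curves of this shape can be replicated and
probed; it is a diagnostic mode, not an inference mode. The package
default includes the correction.

## Summary measures

For each scenario (a $(\tau, p_d)$ cell) and fitted sample size $k$,
replicate chains are reduced to:

* **MAE**: mean over replicates of $|\hat\omega_l - \omega^*|$, where
  $\hat\omega_l$ is the posterior median of $\omega \in \{\alpha, \beta,
  \delta, \tau\}$ in replicate $l$ and $\omega^*$ the generating value
  (which varies by scenario only for $\tau$).
* **Mean posterior variance** and **mean 95% ALC**, the average length of
  the 95% highest-posterior-density interval — the Bayesian precision
  criteria a designer would set targets for. The HPD interval is the
  empirical shortest window: the narrowest contiguous run of
  $\lceil 0.95 N \rceil$ sorted draws, ties broken toward the smallest
  lower bound. It is deterministic given the draws and involves no
  density estimation; when the posterior is genuinely multimodal a single
  shortest interval under-represents the spread, and the package still
  reports it (the caveat applies to mid-size designs where the
  $\delta$ posterior mixes detection and non-detection modes).
* **Detection probabilities** $P(\delta < h)$ for
  $h \in \{-0.05, -2, -3\}$: the threshold near zero reads existence of a
  change-point, the other two the posterior's position relative to and
  beyond the generating value.
* **Classification AUROC** of the per-individual posterior change
  probabilities against the true labels, computed by the Mann–Whitney
  rank statistic with ties counted half (equal to the trapezoidal area
  under the full threshold sweep). It is reported twice: over all fitted
  individuals, and over the subset with observations past $c$. The first
  is systematically dragged toward 0.5 at high drop-out because
  dropped-out individuals' labels are unlearnable under MCAR (their
  scores sit at $p_r$); the second is the interpretable quantity.
  Replicates where a subset contains a single class (common at small
  $k$) record a missing AUROC and reduce that cell's effective replicate
  count rather than failing the run.

The limiting post-change-point AUROC is set by the error precision alone:
with class separation $(2, 6)$ points at the two post-change-point waves,
the optimal classifier achieves
$\Phi\!\big(\sqrt{40}/(\sigma\sqrt{2})\big)$ — about 0.84 at
$\tau = 0.05$, 0.92 at $\tau = 0.1$, 0.98 at $\tau = 0.2$ — and the
fitted chains approach these values at the largest designs.

## The study runner

`study_config()` declares the full grid (defaults: $3 \times 5$ scenario
cells $\times$ 150 replicate cohorts of 500 individuals $\times$ 9 nested
sample sizes $k$ — 20,250 chains). Each replicate cohort is simulated
once and reused across all $k$ by taking the first $k$ individuals, which
preserves the within-replicate correlation across sample sizes. Every
task's dataset and chain seeds are derived deterministically from the
master seed, so results are identical regardless of worker count or
execution order, any single task can be regenerated in isolation, and
interrupted studies resume from per-replicate checkpoint files.
`smooth_trend()` (LOWESS) is provided for drawing detection and
precision curves against $n(1 - p_d)$.

A worked reduced study:

```{r study, eval = FALSE}
cfg <- study_config(
  tau_grid = c(0.05, 0.2), pd_grid = 0.5, k_grid = c(50, 100),
  n_reps = 10, n_individuals = 100,
  settings = chain_settings(iterations = 2e4, burn_in = 1e3, thin = 10),
  master_seed = 1
)
tab <- run_study(cfg)
tab[, c("tau_true", "p_d", "k", "expected_post_cp_n",
        "mae_delta", "p_below_-0.05", "auroc_post_cp")]
```

## Numerical choices and test scale

* Degenerate inputs: empty datasets, out-of-range $k$, non-positive
  $\tau$, non-negative $\delta$ and invalid schedules are rejected at
  construction; a change-point at or before $t_d$ is allowed with a
  warning (the post-change-point bookkeeping then no longer matches the
  drop-out pattern).
* HPD tie-break: smallest lower bound; AUROC ties: half credit;
  `prob_below` uses a strict inequality.
* The label full conditional returns exactly $p_r$ (not merely
  approximately) when an individual has no post-change-point
  observations, so the no-information case is bit-reproducible.
* The test suite validates the sampler against closed-form conjugate
  conditionals and a brute-force posterior (label enumeration plus
  $\delta$ grid integration) on 2-individual fixtures, and runs reduced
  Monte Carlo studies: 10–20 replicates with $2 \times 10^4$-iteration
  chains for detection and AUROC checks, and one full-length chain at
  $n = 500$ for parameter recovery. These sizes were chosen to keep the
  whole suite in the minutes range on a single core while leaving the
  Monte Carlo error well inside the asserted tolerances; the full
  20,250-chain grid is not run routinely, but nothing in the runner is
  specific to reduced grids.

## What the simulator does and does not emulate

The generator reproduces the structure the model assumes: fixed common
observation times, a single known change-point, exactly two latent
classes, Gaussian error with a common precision, and MCAR single-time
drop-out. Real cohorts violate most of these — irregular visit times,
individual change-points, floor effects in bounded scores,
outcome-dependent attrition, covariate-driven class membership — so
passing tests here demonstrate correctness of the machinery and the
design relationships *under the model*, not robustness of the model to
real data. The random-effects and MAR/MNAR extensions that would address
those violations are deliberately out of scope.
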