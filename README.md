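# stickcp

Simulation and Bayesian inference for **broken-stick change-point models
with unlabelled sub-groups**, aimed at designing longitudinal studies —
typically cohorts of cognitive decline in ageing — where only an unknown
subset of individuals ever experiences an accelerated decline, and where
attrition removes individuals before the change-point.

## The model

Individual *i* with latent class label *r<sub>i</sub>* is observed at times
*t<sub>ij</sub>* (first wave at 0) as

```
y_ij = alpha + beta * t_ij + e_ij                          if r_i = 0, or r_i = 1 and t_ij <= c
y_ij = (alpha - delta*c) + (beta + delta) * t_ij + e_ij    if r_i = 1 and t_ij >  c
```

with `e_ij ~ N(0, 1/tau)` independent. The derived intercept
`alpha - delta*c` joins the two segments with no discontinuity at the
common, known change-point `c`; `delta < 0` is the change-magnitude
(accelerated decline, direction known a priori); `P(r_i = 1) = p_r`.
Drop-out is monotone and completely at random: each individual is observed
through a single drop-out time `t_d`, then with probability `p_d` never
again.

Inference is by a data-augmented Metropolis–Hastings-within-Gibbs sampler
(compiled): random-walk updates for `alpha`, `beta`, `tau`, a
sign-preserving multiplicative log-normal update for `delta` (with the
`|delta'|/|delta|` Hastings correction so the chain targets the exact
posterior), and exact Gibbs draws of every label. Priors:
`alpha, beta ~ N(0, 10^2)`, `delta ~ Half-Normal(0, 10^2)` on the negative
reals, `tau ~ Gamma(1, 1)`, `r_i ~ Bernoulli(p_r)`. Proposal dispersions
scale with the fitted sample size as `f(n) = log(25)/log(n)`.

Study-design summaries per scenario: mean absolute error of posterior
medians, mean posterior variance, mean 95% highest-posterior-density
interval length (ALC), change-detection probability `P(delta < h)`, and
classification AUROC of posterior change probabilities — over all
individuals and over those observed past the change-point — organized by
the expected post-change-point sample size `n * (1 - p_d)`.

## Worked example

Simulate a 500-person cohort under the default cognitive-decline design
(`alpha = 25`, `beta = -1`, `delta = -2`, `c = 5`, waves at years
0, 2, 4, 6, 8, drop-out at year 4 with `p_d = 0.1`, `tau = 0.2`) and fit
it blinded to the true labels:

```r
library(stickcp)
sc <- cp_scenario(n = 500, p_d = 0.1, shape = cp_shape(tau = 0.2))
d  <- simulate_dataset(sc, seed = 42)
ch <- run_chain(d, chain_settings(seed = 7))
print(ch)
#> Posterior chain: 1980 retained draws, 500 individuals
#>   posterior medians: alpha = 25, beta = -1, delta = -1.91, tau = 0.195
#>   acceptance rates: alpha = 0.09, beta = 0.03, delta = 0.06, tau = 0.02

idx <- post_cp_indices(d)
auroc(unname(ch$label_prob)[idx], d$truth$true_label[idx])
#> post-change-point AUROC: 0.975
hpd_interval(ch$draws$delta); prob_below(ch$draws$delta, -0.05)
#> 95% HPD for delta: [-2.04, -1.78]  P(delta < -0.05): 1.000
```

The chain recovers the generating parameters (posterior medians 25, −1,
−1.91, 0.195 against truth 25, −1, −2, 0.2), classifies the individuals
actually observed past the change-point with AUROC 0.975 — near the
precision-set optimum Φ(√40/(σ√2)) ≈ 0.98 for `tau = 0.2` — and places
essentially all posterior mass of `delta` away from zero.

Scenario grids (`study_config()` / `run_study()`) chain these steps over
`tau × p_d × k × replicate` designs with deterministic per-task seeds,
checkpointing and optional parallelism; see the vignette in
`vignettes/broken-stick-design.Rmd` for the full account of the model,
the sampler (including the role of the Hastings correction in the
`delta` update and why the detection statistic is near-degenerate under
the exact posterior), and the summary measures. A thin command-line front
end with `simulate`, `fit`, `study` and `summarize` subcommands is
installed under `inst/cli/stickcp`.

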