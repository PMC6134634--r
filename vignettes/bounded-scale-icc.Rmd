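---
title: "Hierarchical Bayesian ICC for bounded rating scales: model, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Bayesian ICC for bounded rating scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesicc)
```

## The problem

Observer-rated instruments — a trained rater watching a recorded
patient–clinician encounter and scoring, say, the amount of shared
decision making on a 0–100 scale — are routinely evaluated by the
intraclass correlation coefficient,

$$ICC = \frac{\sigma_b^2}{\sigma_b^2 + \sigma_w^2},$$

the fraction of total score variance attributable to real differences
between encounters rather than disagreement between raters. Two standard
assumptions behind this single number are routinely violated by such
data:

1. **Bounded scales induce heteroscedasticity.** Raters agree easily
   about encounters near the floor or ceiling of the scale and disagree
   most in the middle, so the within-encounter variance depends on the
   trait level. A single pooled $\sigma_w^2$ misstates reliability
   everywhere on the scale.
2. **Pooling heterogeneous studies inflates the ICC.** Reliability
   studies often combine encounters from several trials with different
   populations. Between-study spread then masquerades as
   between-encounter signal, and the instrument looks more discriminating
   than it will be in any one population.

`bayesicc` implements a hierarchical Bayesian model that makes both
effects explicit and returns a *family* of ICC measures instead of one
number.

## The model

Index studies $h = 1,\dots,M$, encounters $i = 1,\dots,N_h$ and raters
$j = 1,\dots,R$. Scores are rescaled to $y_{hij} \in (0,1)$. With
$\theta_{hi}$ the true trait level of encounter $i$ in study $h$ and
$X_{hi}$ a binary encounter-level covariate (e.g. decision-aid use),

$$y_{hij} \mid \theta_{hi} \sim N\!\left(\mu_{hij},\, v_{hi}^2\right) I(0,1),
\qquad
\mu_{hij} = \theta_{hi} + \beta_1\!\left(j - \tfrac{R+1}{2}\right) +
\beta_2 (X_{hi} - \bar X),$$

$$v_{hi}^2 = \sigma_h^2\, \theta_{hi} (1 - \theta_{hi}),
\qquad
\theta_{hi} \sim N(\gamma_h, \tau_h^2)\, I(0,1),
\qquad
\gamma_h \sim N(\beta_0, \omega^2).$$

$I(0,1)$ denotes truncation to the open unit interval, with the
truncation normalizer $\Phi((1-\mu)/v) - \Phi(-\mu/v)$ kept in every
density. The *binomial variance function*
$\sigma_h^2 \theta (1-\theta)$ encodes the bounded-scale intuition: the
same $\sigma_h^2$ produces small rater noise near the scale ends and
maximal noise at $\theta = 1/2$. At $R = 2$ the rater coding reduces to
$j - 1.5 = \pm 1/2$; for more raters it stays centered. $\bar X$ is the
mean covariate over *encounters* (the covariate is encounter-level, so
centering over records would weight encounters by their number of
raters).

Priors follow the weakly informative scheme
$\beta_k \sim N(b_0 1\{k=0\}, B^2)$ and
Gamma$(v_l, v_l)$ (shape = rate, prior mean 1) on the three precisions
$\sigma_h^{-2}, \tau_h^{-2}, \omega^{-2}$, with defaults $b_0 = 0.4$,
$B^2 = 10$, $v_l = 10^{-3}$.

Three **variants** correspond to the assumptions one may make:

* `full` — study-specific $\sigma_h^2, \tau_h^2$, binomial variance
  function;
* `homogeneous_binomial` — one shared $\sigma^2, \tau^2$ across studies,
  binomial variance function;
* `homogeneous_constant` — shared variances and a *constant*
  within-encounter variance $v^2 = \sigma^2$ (the classical assumption).

## The ICC family

Two binary choices give four measures, all computed as exact posterior
functionals (the ICC is evaluated on every retained draw, then
summarized — never on point estimates):

* **Pointwise, within-study** (`icc_point`):
  $ICC_h(\theta^*) = \tau_h^2 / (\tau_h^2 + \sigma_h^2
  \theta^*(1-\theta^*))$. Reliability at a chosen trait level; equal to
  1 at the scale ends by continuity.
* **Population-averaged, within-study** (`icc_average`):
  $\tau_h^2 \int_0^1 (\tau_h^2 + \sigma_h^2\theta(1-\theta))^{-1}
  \pi(\theta)\,d\theta$ for a population distribution $\pi$; by default
  each posterior draw's own truncated normal
  $N(\gamma_h, \tau_h^2) I(0,1)$, so the average is over the population
  the study itself describes.
* **Marginal / pooled** (`icc_marginal`): when encounters are sampled
  across studies with equal probability,
  $(\omega^2 + \bar\tau^2) / (\omega^2 + \bar\tau^2 +
  \bar\sigma^2\theta^*(1-\theta^*))$. We define $\bar\tau^2$ and
  $\bar\sigma^2$ as unweighted per-draw means over studies, matching
  the equal-selection assumption; `icc_query(weights =)` substitutes
  unequal selection probabilities. The pooled ICC dominates the
  within-study ICC for any $\omega^2 > 0$ — the inflation the model
  exists to expose, not a virtue of the instrument.
* **Population-averaged, pooled**: the marginal form integrated over the
  pooled population, taken as the truncated normal with mean
  $\bar\gamma$ (equal-weight mean of study means) and variance
  $\omega^2 + \bar\tau^2$.

`icc_curve()` evaluates the pointwise ICC on a grid of trait levels
(default 101 points spanning 0 to 1 inclusive; the endpoints are flagged
and equal 1 by continuity under the binomial variance function), and
`icc_pairwise()` summarizes per-draw differences $ICC_a - ICC_b$
between studies, including $\Pr(\text{difference} > 0)$ with exact ties
counted one half (ties arise only in degenerate tests).

## Estimation

The sampler is Metropolis-within-Gibbs, written in C++ (Rcpp). A
tempting shortcut — normal/gamma conjugate updates for all location and
precision parameters — is *not* available here: the truncation
normalizers (which depend on $\gamma_h$, $\tau_h^2$, $\beta$ through
$\mu$) and the $\theta$-dependent variance function break conjugacy for
every block except two. We therefore use:

* exact conjugate Gibbs steps for $\beta_0$ (normal) and $\omega^{-2}$
  (gamma), whose conditionals are genuinely closed-form;
* univariate slice sampling (stepping-out with shrinkage) for
  everything else: each $\theta_{hi}$ on the logit scale (with Jacobian
  correction, so no boundary proposals), $\gamma_h$, $\beta_1$,
  $\beta_2$, and $\log \sigma_h^2$, $\log \tau_h^2$. Slice sampling is
  tuning-free and robust for bounded or positive scalars; the widths
  (1.0 on logit/log scales, 0.2 for study means, 0.05 for coefficients)
  only affect efficiency, not correctness.

Conditional targets drop terms constant within their own block; the
full joint log posterior (variance-scale parameterization, one exact
density) is exposed separately and tested against an independent plain-R
implementation of likelihood + prior to $10^{-9}$ on random states, and
to $10^{-13}$ at extreme "ridge" states (below). Sampler correctness is
established three ways: simulation-based calibration (rank statistics of
prior-drawn truths uniform across 100 replicate fits, chi-square test at
$\alpha = 0.01$), the analytic identity checks, and agreement of
posterior medians with JAGS fitting the identical model on the same
data.

Initialization is data-driven: $\theta_{hi}$ at the encounter mean
(clamped to $(0.01, 0.99)$), $\gamma_h$ at study means, variances at
method-of-moments values; later chains jitter these starts. Defaults are
3 chains of 10,000 iterations with 5,000 warmup. Convergence is reported
(split-chain rank-normalized R-hat and bulk ESS) and poor mixing is a
warning, never an error.

## Numerical choices

* **Boundary scores.** The likelihood lives on the open interval, so
  observed 0/100 scores have zero density. They are clamped to
  $[\epsilon, 1-\epsilon]$ with default $\epsilon = 0.005$ (half a point
  on a 0–100 scale); the clamp count is logged so the adjustment is
  auditable. This is a modelling choice the original formulation leaves
  unstated; discarding boundary scores would bias the trait
  distribution.
* **Truncation normalizers** are computed in log space everywhere
  (`erfc`-based with an asymptotic far-tail series in C++;
  `pnorm(log.p)` with `log1p` in R). This matters: the posterior has a
  genuine low-mass ridge where a study mean drifts far below 0 with
  large $\tau_h^2$ (the truncated normal then degenerates to a
  near-exponential shape on $(0,1)$, weakly identified against the
  interior mode under the nearly scale-invariant Gamma$(10^{-3},
  10^{-3})$ priors). Probability-scale normalizers underflow to zero on
  that ridge and produce infinite ICC draws; log-space evaluation keeps
  every draw finite. Long chains make round trips into and out of the
  ridge (occupancy around 0.2% at the default design) and match JAGS
  medians to three decimals.
* **Quadrature.** Population averages use 64-point Gauss–Legendre on
  $(0,1)$ with a bisection self-check (the interval is split and
  re-integrated; disagreement beyond $10^{-6}$ is an error). The
  integrand is smooth and bounded, so the rule is effectively exact; a
  $10^7$-sample Monte Carlo oracle agrees within 3 standard errors
  across random parameter settings.
* **Truncated draws** in the generator use rejection sampling with an
  acceptance guard; records whose mean sits many standard deviations
  outside the interval (possible at realistic covariate effects when
  $\theta$ is near a bound and the variance function is tiny) fall back
  to a tail-accurate inverse-CDF draw. Configurations whose overall
  acceptance rate falls below $10^{-3}$ are refused as pathological.
* **Reporting scales.** With 0–100 input, $\sigma_h^2$ rows are already
  on the $(\sigma/100)^2$ scale. Because "between-study spread" is
  ambiguous between a standard deviation and a variance, summaries
  report both $\omega$ and $\omega^2$.

## The synthetic-data generator

`generator_config()` defaults describe the study design this model was
built for: three studies of 201, 72 and 38 encounters (311 in total),
two raters, a Bernoulli(0.5) encounter-level covariate, and variance
components near the full-model posterior medians for that design —
$\gamma \approx (0.30, 0.20, 0.25)$,
$\sigma^2 \approx (0.054, 0.117, 0.056)$,
$\tau^2 \approx (0.043, 0.011, 0.023)$, $\beta_1 = -0.06$,
$\beta_2 = 0.24$. This exercises realistic between-study heterogeneity
and heteroscedasticity without claiming to reproduce any particular
dataset. The generator runs the model forward exactly (same rater
coding, same covariate centering), and writes the latent truth
($\theta$, parameters) separately from the observed table so tests can
never confuse the two.

What the generator does *not* emulate: integer-valued item scores (it
produces continuous scores; real instruments quantize), rater pools
larger than $R$ with missing-at-random dropout, rater drift over time,
and covariate effects that differ by study. Passing tests therefore
demonstrate correct recovery of the model's own data-generating process,
not robustness to those real-data features.

## Validation design and problem sizes

The test suite fits hundreds of models, so replicate studies use
shortened chains (single chain, 900 iterations for full-variant fits,
700 for homogeneous fits, at the 311-encounter design; 100 replicates),
while single-dataset checks use 2 chains of 3,000–8,000 iterations.
These sizes were chosen so that Monte Carlo error is small relative to
each check's tolerance. Two findings from that validation are worth
stating plainly:

* **Interval coverage at a fixed truth is close to, but not exactly,
  nominal.** Over 100 replicates at the default design, 95% credible
  intervals covered the true values at rates 0.91–0.97 for ten of eleven
  parameters, but 0.87 for the within-encounter scale of the smallest
  study ($N_3 = 38$). This is not a sampler defect (simulation-based
  calibration is clean): Bayesian intervals are calibrated on average
  over the prior, and the Gamma$(v, v)$ precision prior's
  $e^{-v/\sigma^2}$ factor tilts small-variance posteriors slightly
  upward at small $N$.
* **The default priors are not innocuous for weakly identified variance
  components.** Changing $v_l$ from $10^{-3}$ to $10^{-2}$ moves a
  well-identified study ICC by well under 0.01, but can move a weakly
  identified one (true $\tau^2 \approx 0.01$, 72 encounters, posterior
  ICC interval spanning several tenths) by about 0.08, because the
  $e^{-v/\tau^2}$ shoulder suppresses $\tau^2$ values below about $v$.
  Users analysing small studies should report ICCs under at least two
  settings of $v_l$; robustness must be checked, not assumed.

## Classical baseline

`estimate_components()` / `icc_classical()` / `reliability_k()`
implement the textbook one-way random-effects ANOVA method-of-moments
estimator (negative between-components truncated at zero; unbalanced
designs use the standard
$k_0 = (\sum k_i - \sum k_i^2/\sum k_i)/(n-1)$ coefficient),
deliberately without rater or covariate adjustment: the baseline exists
to demonstrate the assumptions the hierarchical model relaxes. On large
balanced homoscedastic data the homogeneous-constant Bayesian ICC and
the classical estimate agree closely; on heteroscedastic multi-study
data they diverge, which is the point.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_ratings(generator_config(), seed = 11)
rt <- rescale_ratings(sim$data)

fit <- icc_fit(rt, prior_config(), n_chains = 2, n_iter = 6000,
               n_warmup = 2000, seed = 42)
posterior_summary(fit)
icc_posterior(fit, icc_query("average"))          # per-study ICCs
icc_posterior(fit, icc_query("average", pooled = TRUE))
icc_pairwise(fit, icc_query("average"))
head(icc_curve(fit, grid_size = 101))

empirical_variance_check(rt)                      # variance-function diagnostic
icc_classical(estimate_components(rt))            # classical baseline
```

## Known limitations

* Only the total score is modelled; item-level (ordinal sub-score)
  structure is out of scope.
* One binary encounter-level covariate; no missing-covariate handling.
* The marginal ICC's equal-selection assumption is a modelling choice;
  weights are accepted but not estimated.
* The near-improper precision priors carry the sensitivity documented
  above; alternative priors (e.g. half-normal on standard deviations)
  would change small-sample behaviour and are not implemented, to keep
  the model faithful to its published form.
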