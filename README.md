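# bayesicc

Bayesian hierarchical intraclass correlation (ICC) for observer-rated
instruments scored on a bounded scale.

## The problem

Inter-rater reliability of health measurement scales — two trained raters
scoring recorded patient–clinician encounters on, say, a 0–100 shared
decision making instrument — is conventionally summarized by the
intraclass correlation

```
ICC = sigma_b^2 / (sigma_b^2 + sigma_w^2),
```

the fraction of score variance due to real differences between encounters
rather than rater disagreement. Two of its standard assumptions are
routinely violated: bounded scales make the rater variance depend on the
trait level (raters agree near the floor and ceiling, disagree in the
middle), and pooling encounters from heterogeneous studies counts
between-study spread as discriminative signal, inflating the ICC. Either
violation makes an instrument look more reliable than it is.

## The model

`bayesicc` fits, by MCMC, the hierarchical truncated-normal model

```
y_hij | theta_hi ~ N(mu_hij, v_hi^2) I(0,1)
mu_hij  = theta_hi + beta1 (j - (R+1)/2) + beta2 (X_hi - Xbar)
v_hi^2  = sigma_h^2 theta_hi (1 - theta_hi)        # binomial variance function
theta_hi ~ N(gamma_h, tau_h^2) I(0,1)
gamma_h  ~ N(beta0, omega^2)
```

for studies `h`, encounters `i`, raters `j`, with weakly informative
normal/gamma priors, and evaluates a two-dimensional family of ICC
measures as exact posterior functionals:

* pointwise `ICC_h(theta*) = tau_h^2 / (tau_h^2 + sigma_h^2 theta*(1-theta*))`,
* population-averaged (integrated over a distribution of trait levels),
* within-study vs marginal/pooled (whether the between-study variance
  `omega^2` counts as signal),

plus pairwise study comparisons, ICC-vs-trait-level curves, an empirical
variance-function diagnostic, classical one-way ANOVA baselines, and a
synthetic-data generator that runs the model forward with known
parameters. Three model variants (study-specific heteroscedastic; shared
variances with the binomial variance function; shared constant variance)
quantify exactly how much each ignored assumption inflates the ICC.

## Worked example

Simulate a dataset with the design the model targets (3 studies of
201/72/38 encounters, 2 raters, binary decision-aid covariate,
heteroscedastic variances), fit the full model, and read off the ICC
family:

```r
library(bayesicc)

sim <- simulate_ratings(generator_config(), seed = 11)
rt  <- rescale_ratings(sim$data)         # scores / 100, clamped into (0,1)

fit <- icc_fit(rt, prior_config(), n_chains = 2, n_iter = 6000,
               n_warmup = 2000, seed = 42)
posterior_summary(fit)
```

```
   parameter   median     q2.5   q97.5
1      beta0  0.24838  0.13066  0.3626
2      beta1 -0.07493 -0.09165 -0.0593
3      beta2  0.22711  0.19272  0.2626
4   gamma[1]  0.27079  0.20257  0.3203
5   gamma[2]  0.22540  0.17885  0.2625
6   gamma[3]  0.25491  0.19316  0.3044
7  sigma2[1]  0.04731  0.03814  0.0598
8  sigma2[2]  0.11054  0.07335  0.1970
9  sigma2[3]  0.09643  0.05846  0.1900
10   tau2[1]  0.05695  0.04018  0.0878
11   tau2[2]  0.01029  0.00199  0.0223
12   tau2[3]  0.01273  0.00234  0.0368
13    omega2  0.00294  0.00044  0.0828
14     omega  0.05418  0.02098  0.2878
```

The rater effect (`beta1`, rater 2 scoring about 7.5 points lower on the
native scale), the decision-aid effect (`beta2`), and the study-specific
variance components all recover the generating values (`truth` is stored
separately in `sim$truth`). Per-study population-averaged ICCs and their
pairwise contrasts:

```r
icc_posterior(fit, icc_query("average"))
#>    group  mean median   q2.5 q97.5
#> 1 study1 0.869  0.870 0.8124 0.917
#> 2 study2 0.372  0.378 0.0714 0.607
#> 3 study3 0.435  0.445 0.0787 0.732

icc_pairwise(fit, icc_query("average"))
#>              pair    mean  median   q2.5 q97.5 pr_gt0
#> 1 study1 - study2  0.4964  0.4906  0.259 0.791  1.000
#> 2 study1 - study3  0.4341  0.4247  0.135 0.793  1.000
#> 3 study2 - study3 -0.0623 -0.0615 -0.466 0.338  0.378
```

Study 1 (large, low within-encounter noise) is measured reliably; the
smaller, noisier studies are not — a heterogeneity that any single pooled
ICC would hide: the classical one-way ANOVA estimate for the same data is
a flattering 0.751 (`icc_classical(estimate_components(rt))`). The
empirical variance diagnostic (`empirical_variance_check(rt)`) fits the
binomial shape with coefficient 0.067 against a constant variance of
0.012, plot-ready for a mean-variance figure. `icc_curve(fit)` traces the
ICC across trait levels (highest near the scale ends, lowest at 50), and
the homogeneous variants (`prior_config(variant = ...)`) reproduce the
inflation orderings: pooled > within-study, constant-variance > binomial.

A thin CLI wraps the same functions:
`exec/icc simulate | classical | fit | functionals | curve | pairwise | report`.

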