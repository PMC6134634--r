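test_that("pointwise ICC follows its closed form, symmetry and limits", {
  # case-study-scale inputs: tau2 0.043, sigma2 0.054, theta* 0.5
  expect_equal(icc_point(0.043, 0.054, 0.5), 0.043 / 0.0565,
               tolerance = 1e-12)
  expect_gt(icc_point(0.043, 1e-12, 0.5), 1 - 1e-9)   # no rater noise
  expect_equal(icc_point(0.02, 0.1, 0.2), icc_point(0.02, 0.1, 0.8))
  expect_message(v <- icc_point(0.02, 0.1, 0), "continuity")
  expect_equal(v, 1)
  expect_error(icc_point(-0.1, 0.1, 0.5), "tau2")
  expect_error(icc_point(0.1, 0.1, 1.5), "theta_star")
})

test_that("pointwise ICC is monotone in each variance argument", {
  t2 <- seq(0.01, 0.2, length.out = 20)
  expect_true(all(diff(icc_point(t2, 0.05, 0.4)) > 0))
  s2 <- seq(0.01, 0.5, length.out = 20)
  expect_true(all(diff(icc_point(0.03, s2, 0.4)) < 0))
  th <- seq(0.05, 0.5, length.out = 20)   # u = theta(1-theta) increasing here
  expect_true(all(diff(icc_point(0.03, 0.05, th)) < 0))
})

test_that("marginal ICC reduces to pointwise at omega2 = 0 and dominates otherwise", {
  expect_equal(icc_marginal(0, 0.03, 0.05, 0.4), icc_point(0.03, 0.05, 0.4))
  # magnitudes near the homogeneous-variant posterior medians
  expect_equal(icc_marginal(0.01, 0.015, 0.041, 0.5),
               0.025 / (0.025 + 0.041 * 0.25), tolerance = 1e-12)
  expect_gt(icc_marginal(0.01, 0.015, 0.041, 0.5),
            icc_point(0.015, 0.041, 0.5))
  expect_error(icc_marginal(0, 0, 0, 0.5), "undefined")
})

test_that("population-averaged ICC: degenerate and zero-noise reductions", {
  # near-point-mass population distribution collapses to the pointwise ICC
  a <- icc_average(0.03, 0.08, list(mean = 0.3, sd = 1e-3))
  expect_lt(abs(a - icc_point(0.03, 0.08, 0.3)), 1e-4)
  # sigma2 = 0 makes the integrand exactly 1 for any population density
  expect_equal(icc_average(0.03, 0, list(mean = 0.4, sd = 0.15)), 1,
               tolerance = 1e-10)
  expect_error(icc_average(0.03, 0.08, function(t) rep(2, length(t))),
               "integrate to 1")
})

test_that("quadrature agrees with a Monte Carlo oracle for the averaged ICC", {
  set.seed(60)
  for (rep in 1:3) {
    tau2 <- runif(1, 0.01, 0.08)
    sigma2 <- runif(1, 0.02, 0.2)
    g <- runif(1, 0.2, 0.7)
    sd <- sqrt(runif(1, 0.005, 0.05))
    quad <- icc_average(tau2, sigma2, list(mean = g, sd = sd))
    th <- bayesicc:::rtnorm_invcdf(1e6, rep(g, 1e6), rep(sd, 1e6))
    mc_vals <- tau2 / (tau2 + sigma2 * th * (1 - th))
    mc_se <- sd(mc_vals) / sqrt(length(mc_vals))
    expect_lt(abs(quad - mean(mc_vals)), 3 * mc_se + 1e-6)
  }
})

test_that("averaged ICC respects the mean-value property and the Jensen direction", {
  set.seed(61)
  for (rep in 1:5) {
    tau2 <- runif(1, 0.01, 0.1)
    sigma2 <- runif(1, 0.02, 0.3)
    g <- runif(1, 0.15, 0.85)
    sd <- sqrt(runif(1, 0.005, 0.05))
    a <- icc_average(tau2, sigma2, list(mean = g, sd = sd))
    grid <- seq(1e-4, 1 - 1e-4, length.out = 2001)
    pts <- icc_point(tau2, sigma2, grid)
    expect_gte(a, min(pts) - 1e-10)
    expect_lte(a, max(pts) + 1e-10)
  }
  # symmetric population centered at 0.5: averaging can only raise the ICC
  # above its value at the center (the integrand is convex in the spread)
  a <- icc_average(0.02, 0.1, list(mean = 0.5, sd = 0.1))
  expect_gt(a, icc_point(0.02, 0.1, 0.5))
})

test_that("ICC curves have the binomial-variance shape and grid layout", {
  f <- fake_full_draws(5, M = 3, gamma = c(0.3, 0.2, 0.25),
                       sigma2 = c(0.054, 0.117, 0.056),
                       tau2 = c(0.043, 0.011, 0.023), omega2 = 0.001)
  cv <- icc_curve(f, grid_size = 101L)
  expect_equal(nrow(cv), 3L * 101L)
  expect_true(all(cv$mean > 0 & cv$mean <= 1))
  expect_equal(cv$mean[cv$endpoint], rep(1, 6))   # ICC -> 1 at the bounds
  one <- cv[cv$study == "study1", ]
  # symmetric about theta* = 0.5 and minimized there
  expect_equal(one$mean, rev(one$mean), tolerance = 1e-10)
  expect_equal(which.min(one$mean), 51L)
  # constant draws: curve equals the deterministic pointwise ICC
  expect_equal(one$mean[one$theta_star == 0.5],
               icc_point(0.043, 0.054, 0.5), tolerance = 1e-12)
  expect_equal(one$mean, one$q2.5, tolerance = 1e-12)
})

test_that("posterior functionals collapse to deterministic values on constant draws", {
  f <- fake_full_draws(20, M = 2, gamma = c(0.4, 0.3),
                       sigma2 = c(0.05, 0.08), tau2 = c(0.04, 0.02),
                       omega2 = 0.01)
  pt <- icc_posterior(f, icc_query("point", theta_star = 0.4))
  expect_equal(pt$median, icc_point(c(0.04, 0.02), c(0.05, 0.08), 0.4),
               tolerance = 1e-12)
  expect_equal(pt$median, pt$q2.5)
  av <- icc_posterior(f, icc_query("average"))
  expect_equal(av$median[1],
               icc_average(0.04, 0.05, list(mean = 0.4, sd = sqrt(0.04))),
               tolerance = 1e-6)
  mg <- icc_posterior(f, icc_query("point", theta_star = 0.4, pooled = TRUE))
  expect_equal(mg$median,
               icc_marginal(0.01, 0.03, 0.065, 0.4), tolerance = 1e-12)
})

test_that("pooled ICC dominates the within-study ICC on the same draws", {
  sim <- simulate_ratings(small_gen(), seed = 41)
  rt <- rescale_ratings(sim$data)
  fb <- quick_fit(rt, prior_config(variant = "homogeneous_binomial"),
                  seed = 19)
  w <- icc_posterior(fb, icc_query("average"))
  p <- icc_posterior(fb, icc_query("average", pooled = TRUE))
  expect_gte(p$median, w$median)
  wd <- attr(w, "icc_draws"); pd <- attr(p, "icc_draws")
  pt_w <- icc_posterior(fb, icc_query("point", theta_star = 0.5))
  pt_p <- icc_posterior(fb, icc_query("point", theta_star = 0.5,
                                      pooled = TRUE))
  # pointwise dominance holds draw by draw (same tau2/sigma2, omega2 >= 0)
  expect_true(all(attr(pt_p, "icc_draws") >= attr(pt_w, "icc_draws")))
})

test_that("pairwise comparisons are antisymmetric and detect separated ICCs", {
  f <- fake_full_draws(50, M = 2, gamma = c(0.4, 0.4),
                       sigma2 = c(0.05, 0.05), tau2 = c(0.03, 0.03),
                       omega2 = 0.01)
  pw <- icc_pairwise(f, icc_query("point", theta_star = 0.5))
  expect_equal(pw$median, 0)
  expect_equal(pw$pr_gt0, 0.5)            # exact ties count one half

  set.seed(77)
  g <- fake_full_draws(400, M = 2, gamma = c(0.4, 0.4),
                       sigma2 = c(0.04, 0.04), tau2 = c(0.12, 0.008),
                       omega2 = 0.01, jitter = 0.15)
  pw2 <- icc_pairwise(g, icc_query("point", theta_star = 0.5))
  expect_gt(pw2$pr_gt0, 0.9)              # ICC_1 >> ICC_2 by construction
  # antisymmetry under relabelling, checked on the raw draws
  vals <- attr(icc_posterior(g, icc_query("point", theta_star = 0.5)),
               "icc_draws")
  d12 <- vals[, 1] - vals[, 2]
  expect_equal(mean(d12 > 0) + mean(d12 < 0) + mean(d12 == 0), 1)
  expect_equal(pw2$mean, mean(d12))
  expect_equal(pw2$q2.5, unname(quantile(d12, 0.025)))

  expect_error(icc_pairwise(quick_fit(
    rescale_ratings(simulate_ratings(small_gen(), seed = 2)$data),
    prior_config(variant = "homogeneous_binomial"), seed = 1)),
    "full-variant")
})

test_that("separated generating ICCs yield decisive pairwise probabilities", {
  # true population-average ICCs about 0.86 vs 0.26
  cfg <- generator_config(M = 2, N = c(120, 120), R = 2,
                          gamma = c(0.4, 0.4), tau2 = c(0.12, 0.008),
                          sigma2 = c(0.04, 0.1), beta1 = 0, beta2 = 0)
  sim <- simulate_ratings(cfg, seed = 55)
  f <- suppressWarnings(icc_fit(rescale_ratings(sim$data), prior_config(),
                                n_chains = 1, n_iter = 900, n_warmup = 300,
                                seed = 10))
  pw <- icc_pairwise(f, icc_query("average"))
  expect_gt(pw$pr_gt0, 0.9)
})

test_that("population-average posterior ICC tracks the generator truth", {
  cfg <- generator_config(M = 2, N = c(200, 100), R = 2,
                          gamma = c(0.4, 0.3), tau2 = c(0.04, 0.02),
                          sigma2 = c(0.05, 0.08), beta1 = -0.05, beta2 = 0.2)
  sim <- simulate_ratings(cfg, seed = 70)
  f <- suppressWarnings(icc_fit(rescale_ratings(sim$data), prior_config(),
                                n_chains = 1, n_iter = 1200, n_warmup = 400,
                                seed = 12))
  post <- icc_posterior(f, icc_query("average"))
  truth1 <- icc_average(0.04, 0.05, list(mean = 0.4, sd = sqrt(0.04)))
  expect_lt(abs(post$median[1] - truth1), 0.1)
})

test_that("query validation catches malformed requests", {
  expect_error(icc_query("point", theta_star = 0), "inside")
  expect_error(icc_query("nonsense"), "arg")
})
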