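# single-rater, zero-covariate table so mu_hij = theta_hi exactly
one_rater_table <- function(scores) {
  df <- data.frame(study = "s1",
                   encounter = sprintf("e%02d", seq_along(scores)),
                   rater = 1, score = 100 * scores, covariate = 0)
  rescale_ratings(rating_table(df))
}

params_for <- function(E, theta, sigma2 = 0.05, tau2 = 0.03, M = 1) {
  model_params(theta = theta, gamma = rep(0.4, M), beta0 = 0.4,
               beta1 = 0, beta2 = 0, sigma2 = rep(sigma2, M),
               tau2 = rep(tau2, M), omega2 = 0.05)
}

test_that("log-likelihood at the mode equals the truncated-normal normalizing terms", {
  th <- c(0.5, 0.3)
  rt <- one_rater_table(th)             # y == mu for both records
  p <- params_for(2, th, sigma2 = 0.054)
  got <- icc_log_likelihood(p, rt, variant = "full")
  v <- sqrt(0.054 * th * (1 - th))      # binomial variance function
  oracle <- sum(-log(v * sqrt(2 * pi)) -
                  log(pnorm((1 - th) / v) - pnorm(-th / v)))
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("binomial variance function: theta 0.5, sigma2 0.054 implies v2 = 0.0135", {
  rt <- one_rater_table(0.62)
  p <- params_for(1, 0.5, sigma2 = 0.054)
  got <- icc_log_likelihood(p, rt, variant = "full")
  v2 <- 0.054 * 0.5 * 0.5
  expect_equal(v2, 0.0135)
  oracle <- dnorm(0.62, 0.5, sqrt(v2), log = TRUE) -
    log(pnorm((1 - 0.5) / sqrt(v2)) - pnorm(-0.5 / sqrt(v2)))
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("with truncation disabled the likelihood is the plain normal density", {
  sim <- simulate_ratings(small_gen(), seed = 5)
  rt <- rescale_ratings(sim$data)
  md <- bayesicc:::prepare_model_data(rt)
  set.seed(8)
  p <- model_params(theta = runif(md$E, 0.1, 0.9),
                    gamma = c(0.3, 0.25), beta0 = 0.3, beta1 = -0.05,
                    beta2 = 0.2, sigma2 = c(0.05, 0.08),
                    tau2 = c(0.04, 0.02), omega2 = 0.05)
  got <- icc_log_likelihood(p, rt, variant = "full", truncate = FALSE)
  mu <- p$theta[md$enc] + p$beta1 * md$rater_code + p$beta2 * md$x_centered
  v <- sqrt(p$sigma2[md$study] * p$theta[md$enc] * (1 - p$theta[md$enc]))
  expect_equal(got, sum(dnorm(md$y, mu, v, log = TRUE)), tolerance = 1e-12)
})

test_that("log-prior matches a term-by-term closed-form oracle and handles support", {
  rt <- one_rater_table(c(0.3, 0.6, 0.5))
  cfg <- prior_config()                 # b0 = 0.4, B2 = 10, v_l = 1e-3
  th <- c(0.3, 0.6, 0.5)
  p <- model_params(theta = th, gamma = 0.4, beta0 = 0.4, beta1 = 0,
                    beta2 = 0, sigma2 = 0.05, tau2 = 0.03, omega2 = 0.02)
  got <- icc_log_prior(p, cfg, rt)
  tn <- function(x, m, s) {
    dnorm(x, m, s, log = TRUE) - log(pnorm((1 - m) / s) - pnorm(-m / s))
  }
  gam_var <- function(t, v) dgamma(1 / t, v, rate = v, log = TRUE) - 2 * log(t)
  oracle <- sum(tn(th, 0.4, sqrt(0.03))) +
    dnorm(0.4, 0.4, sqrt(0.02), log = TRUE) +
    dnorm(0.4, 0.4, sqrt(10), log = TRUE) +
    2 * dnorm(0, 0, sqrt(10), log = TRUE) +
    gam_var(0.05, 1e-3) + gam_var(0.03, 1e-3) + gam_var(0.02, 1e-3)
  expect_equal(got, oracle, tolerance = 1e-12)

  bad <- p
  bad$theta[1] <- 1.5                   # outside (0,1): rejection signal
  expect_identical(icc_log_prior(bad, cfg, rt), -Inf)
  bad2 <- p
  bad2$tau2 <- -0.01
  expect_identical(icc_log_prior(bad2, cfg, rt), -Inf)
})

test_that("doubling B2 lowers the coefficient prior by half log 2 per coefficient", {
  rt <- one_rater_table(c(0.3, 0.6))
  p <- model_params(theta = c(0.3, 0.6), gamma = 0.4, beta0 = 0.4,
                    beta1 = 0, beta2 = 0, sigma2 = 0.05, tau2 = 0.03,
                    omega2 = 0.02)
  lp10 <- icc_log_prior(p, prior_config(B2 = 10), rt)
  lp20 <- icc_log_prior(p, prior_config(B2 = 20), rt)
  expect_equal(lp10 - lp20, 3 * 0.5 * log(2), tolerance = 1e-12)
})

test_that("log posterior = log likelihood + log prior, and matches the compiled kernel", {
  sim <- simulate_ratings(small_gen(), seed = 9)
  rt <- rescale_ratings(sim$data)
  md <- bayesicc:::prepare_model_data(rt)
  set.seed(31)
  for (variant in c("full", "homogeneous_binomial", "homogeneous_constant")) {
    Ms <- if (variant == "full") md$M else 1L
    cfg <- prior_config(variant = variant)
    for (rep in 1:3) {
      p <- model_params(theta = runif(md$E, 0.05, 0.95),
                        gamma = runif(md$M, 0.1, 0.6),
                        beta0 = rnorm(1, 0.4, 0.2), beta1 = rnorm(1, 0, 0.1),
                        beta2 = rnorm(1, 0, 0.1),
                        sigma2 = runif(Ms, 0.01, 0.3),
                        tau2 = runif(Ms, 0.005, 0.2),
                        omega2 = runif(1, 0.005, 0.2))
      lp <- icc_log_posterior(p, cfg, rt)
      expect_equal(lp, icc_log_likelihood(p, rt, variant) +
                     icc_log_prior(p, cfg, rt), tolerance = 1e-12)
      sdat <- bayesicc:::sampler_data(md, variant)
      cpp <- bayesicc:::.cpp_log_posterior(
        sdat, cfg[c("b0", "B2", "v1", "v2", "v3")],
        p$theta, p$gamma, p$beta0, p$beta1, p$beta2,
        p$sigma2, p$tau2, p$omega2)
      expect_equal(lp, cpp, tolerance = 1e-9)
    }
  }
})

test_that("model_params enforces positivity and the open interval", {
  expect_error(model_params(theta = 0.5, gamma = 0.4, beta0 = 0, beta1 = 0,
                            beta2 = 0, sigma2 = -1, tau2 = 1, omega2 = 1),
               "strictly positive")
  expect_error(model_params(theta = 1, gamma = 0.4, beta0 = 0, beta1 = 0,
                            beta2 = 0, sigma2 = 1, tau2 = 1, omega2 = 1),
               "inside")
})
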