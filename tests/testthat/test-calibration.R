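# Sampler validation: simulation-based calibration (rank uniformity when
# parameters are drawn from the prior), and an independent cross-check of
# posterior medians against JAGS on the same data and model.

test_that("rank statistics are uniform under prior draws (simulation-based calibration)", {
  set.seed(4242)
  n_rep <- 100
  M <- 2L
  N <- c(12, 12)
  pars <- c("beta1", "beta2", "gamma[1]", "sigma2[1]", "tau2[1]", "omega2")
  ranks <- matrix(NA_real_, n_rep, length(pars),
                  dimnames = list(NULL, pars))
  # a proper, moderately informative prior so prior draws generate data
  # on a realistic scale; SBC is valid for any prior shared by generator
  # and fit
  pc <- prior_config(b0 = 0.4, B2 = 0.05, v1 = 2, v2 = 2, v3 = 2)
  for (i in seq_len(n_rep)) {
    repeat {
      beta0 <- rnorm(1, pc$b0, sqrt(pc$B2))
      beta1 <- rnorm(1, 0, sqrt(pc$B2))
      beta2 <- rnorm(1, 0, sqrt(pc$B2))
      omega2 <- 1 / rgamma(1, pc$v3, rate = pc$v3)
      gamma <- rnorm(M, beta0, sqrt(omega2))
      sigma2 <- 1 / rgamma(M, pc$v1, rate = pc$v1)
      tau2 <- 1 / rgamma(M, pc$v2, rate = pc$v2)
      sim <- try(simulate_ratings(
        generator_config(M = M, N = N, gamma = gamma, tau2 = tau2,
                         sigma2 = sigma2, beta1 = beta1, beta2 = beta2),
        seed = sample.int(1e6, 1)), silent = TRUE)
      if (!inherits(sim, "try-error")) break   # redraw pathological tails
    }
    rt <- suppressMessages(rescale_ratings(sim$data, epsilon = 1e-6))
    f <- icc_fit(rt, pc, n_chains = 1, n_iter = 1300, n_warmup = 300,
                 thin = 10, seed = sample.int(1e6, 1))
    m <- as.matrix(f)
    truth <- c(beta1, beta2, gamma[1], sigma2[1], tau2[1], omega2)
    for (j in seq_along(pars)) ranks[i, j] <- sum(m[, pars[j]] < truth[j])
  }
  L <- 100   # retained draws per fit
  for (j in seq_along(pars)) {
    tab <- table(cut(ranks[, j], breaks = seq(-0.5, L + 0.5,
                                              length.out = 11)))
    chi <- suppressWarnings(chisq.test(tab, p = rep(0.1, 10)))
    expect_gt(chi$p.value, 0.01)
  }
})

test_that("posterior medians agree with an independent JAGS fit of the same model", {
  skip_if_not_installed("rjags")
  cfg <- generator_config(M = 2, N = c(40, 40), R = 2,
                          gamma = c(0.35, 0.25), tau2 = c(0.04, 0.02),
                          sigma2 = c(0.05, 0.08), beta1 = -0.05, beta2 = 0.2)
  sim <- simulate_ratings(cfg, seed = 23)
  rt <- rescale_ratings(sim$data)
  md <- bayesicc:::prepare_model_data(rt)
  pc <- prior_config()

  f <- suppressWarnings(icc_fit(rt, pc, n_chains = 2, n_iter = 4000,
                                n_warmup = 1000, seed = 31))
  s <- posterior_summary(f)
  rownames(s) <- s$parameter

  model_str <- "
  model {
    for (r in 1:n) {
      prec[r] <- 1 / (sig2[st[r]] * theta[enc[r]] * (1 - theta[enc[r]]))
      y[r] ~ dnorm(theta[enc[r]] + b1 * rc[r] + b2 * xc[r], prec[r]) T(0, 1)
    }
    for (e in 1:E) {
      theta[e] ~ dnorm(gamma[es[e]], 1 / tau2[es[e]]) T(0, 1)
    }
    for (s in 1:M) {
      gamma[s] ~ dnorm(b0, 1 / om2)
      isig2[s] ~ dgamma(v1, v1); sig2[s] <- 1 / isig2[s]
      itau2[s] ~ dgamma(v2, v2); tau2[s] <- 1 / itau2[s]
    }
    b0 ~ dnorm(pb0, 1 / B2)
    b1 ~ dnorm(0, 1 / B2)
    b2 ~ dnorm(0, 1 / B2)
    iom2 ~ dgamma(v3, v3); om2 <- 1 / iom2
  }"
  jd <- list(y = md$y, st = md$study, enc = md$enc, rc = md$rater_code,
             xc = md$x_centered, es = md$enc_study, n = length(md$y),
             E = md$E, M = md$M, pb0 = pc$b0, B2 = pc$B2,
             v1 = pc$v1, v2 = pc$v2, v3 = pc$v3)
  jinit <- list(theta = pmin(pmax(tapply(md$y, md$enc, mean), 0.05), 0.95),
                .RNG.name = "base::Mersenne-Twister", .RNG.seed = 7)
  jm <- rjags::jags.model(textConnection(model_str), data = jd,
                          inits = jinit, n.chains = 1, quiet = TRUE)
  update(jm, 2000, progress.bar = "none")
  js <- rjags::coda.samples(jm, c("b1", "b2", "gamma", "sig2", "tau2"),
                            n.iter = 6000, progress.bar = "none")
  jmed <- apply(as.matrix(js), 2, median)

  expect_lt(abs(s["beta1", "median"] - jmed[["b1"]]), 0.01)
  expect_lt(abs(s["beta2", "median"] - jmed[["b2"]]), 0.02)
  for (h in 1:2) {
    expect_lt(abs(s[sprintf("gamma[%d]", h), "median"] -
                    jmed[[sprintf("gamma[%d]", h)]]), 0.03)
    expect_lt(abs(s[sprintf("sigma2[%d]", h), "median"] -
                    jmed[[sprintf("sig2[%d]", h)]]),
              0.15 * s[sprintf("sigma2[%d]", h), "median"])
    expect_lt(abs(s[sprintf("tau2[%d]", h), "median"] -
                    jmed[[sprintf("tau2[%d]", h)]]),
              0.2 * s[sprintf("tau2[%d]", h), "median"])
  }
})
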