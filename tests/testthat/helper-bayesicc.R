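# Shared fixtures, built in code.

# small long-format data frame: 1 study, 2 encounters, 2 raters
tiny_df <- function() {
  data.frame(study = "s1",
             encounter = c("e1", "e1", "e2", "e2"),
             rater = c(1, 2, 1, 2),
             score = c(20, 40, 60, 80),
             covariate = c(0, 0, 1, 1))
}

# rating table with chosen per-encounter rater scores (single study,
# constant covariate), on the (0,1) scale times 100
pairs_table <- function(pairs, covariate = 0) {
  n <- length(pairs)
  df <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(study = "s1", encounter = sprintf("e%02d", i),
               rater = seq_along(pairs[[i]]),
               score = 100 * pairs[[i]], covariate = covariate)
  }))
  rating_table(df, scale_max = 100)
}

# a small heterogeneous two-study generator for quick fits
small_gen <- function(N = c(25, 20)) {
  generator_config(M = 2, N = N, R = 2,
                   gamma = c(0.35, 0.25), tau2 = c(0.04, 0.02),
                   sigma2 = c(0.05, 0.08), beta1 = -0.05, beta2 = 0.2)
}

quick_fit <- function(rt, config = prior_config(), seed = 1, ...) {
  suppressWarnings(icc_fit(rt, config, n_chains = 1, n_iter = 600,
                           n_warmup = 200, seed = seed, ...))
}

# hand-made icc_draws object from explicit per-chain matrices
fake_draws <- function(chains, variant = "full", M = 1L,
                       study_labels = paste0("study", seq_len(M))) {
  structure(list(draws = chains, pars = colnames(chains[[1L]]),
                 n_chains = length(chains), n_warmup = 0L,
                 n_kept = nrow(chains[[1L]]), thin = 1L, seed = 0L,
                 variant = variant, prior = prior_config(variant = variant),
                 data_info = list(M = M, N_h = rep(10L, M), R = 2L,
                                  E = 10L * M, study_labels = study_labels,
                                  scale_max = 100),
                 diagnostics = NULL),
            class = "icc_draws")
}

# full-variant fake draws with named parameter columns
fake_full_draws <- function(n, M, gamma, sigma2, tau2, omega2,
                            jitter = 0) {
  nm <- c("beta0", "beta1", "beta2", paste0("gamma[", seq_len(M), "]"),
          paste0("sigma2[", seq_len(M), "]"),
          paste0("tau2[", seq_len(M), "]"), "omega2")
  m <- matrix(0, n, length(nm), dimnames = list(NULL, nm))
  for (h in seq_len(M)) {
    m[, paste0("gamma[", h, "]")] <- gamma[h]
    m[, paste0("sigma2[", h, "]")] <- sigma2[h] * exp(stats::rnorm(n, 0, jitter))
    m[, paste0("tau2[", h, "]")] <- tau2[h] * exp(stats::rnorm(n, 0, jitter))
  }
  m[, "omega2"] <- omega2
  fake_draws(list(m), variant = "full", M = M)
}
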