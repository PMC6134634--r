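# Pack prepared model data into the index arrays the compiled sampler uses.
sampler_data <- function(md, variant) {
  variant_code <- match(variant, c("full", "homogeneous_binomial",
                                   "homogeneous_constant")) - 1L
  enc0 <- md$enc - 1L
  enc_start <- integer(md$E)
  enc_len <- integer(md$E)
  for (e in seq_len(md$E)) {
    idx <- which(md$enc == e)
    enc_start[e] <- idx[1L] - 1L
    enc_len[e] <- length(idx)
  }
  srec_start <- integer(md$M)
  srec_len <- integer(md$M)
  senc_start <- integer(md$M)
  senc_len <- integer(md$M)
  for (s in seq_len(md$M)) {
    ridx <- which(md$study == s)
    srec_start[s] <- ridx[1L] - 1L
    srec_len[s] <- length(ridx)
    eidx <- which(md$enc_study == s)
    senc_start[s] <- eidx[1L] - 1L
    senc_len[s] <- length(eidx)
  }
  list(y = md$y, rater_code = md$rater_code, x_centered = md$x_centered,
       enc0 = enc0, enc_study0 = md$enc_study - 1L,
       enc_start = enc_start, enc_len = enc_len,
       srec_start = srec_start, srec_len = srec_len,
       senc_start = senc_start, senc_len = senc_len,
       M = md$M, E = md$E, variant = variant_code)
}

# Data-driven initial values; `jitter_sd` spreads chain starts.
initial_state <- function(md, variant, jitter_sd = 0) {
  Ms <- if (variant == "full") md$M else 1L
  enc_mean <- vapply(seq_len(md$E), function(e) mean(md$y[md$enc == e]),
                     numeric(1))
  theta <- pmin(pmax(enc_mean, 0.01), 0.99)
  gamma <- vapply(seq_len(md$M), function(s) {
    mean(enc_mean[md$enc_study == s])
  }, numeric(1))
  # method-of-moments variance starts
  enc_var <- vapply(seq_len(md$E), function(e) {
    yy <- md$y[md$enc == e]
    if (length(yy) > 1L) stats::var(yy) else NA_real_
  }, numeric(1))
  tau2 <- vapply(seq_len(md$M), function(s) {
    max(stats::var(enc_mean[md$enc_study == s]), 1e-4)
  }, numeric(1))
  sigma2 <- vapply(seq_len(md$M), function(s) {
    v <- enc_var[md$enc_study == s]
    u <- theta[md$enc_study == s] * (1 - theta[md$enc_study == s])
    mv <- mean(v, na.rm = TRUE)
    if (!is.finite(mv) || mv <= 0) mv <- 1e-3
    if (variant == "homogeneous_constant") mv else max(mv / mean(u), 1e-4)
  }, numeric(1))
  if (Ms == 1L) {
    tau2 <- mean(tau2)
    sigma2 <- mean(sigma2)
  }
  jit <- function(x, s) x + stats::rnorm(length(x), 0, s)
  if (jitter_sd > 0) {
    theta <- pmin(pmax(jit(theta, jitter_sd), 0.01), 0.99)
    gamma <- jit(gamma, jitter_sd)
    sigma2 <- sigma2 * exp(stats::rnorm(Ms, 0, jitter_sd))
    tau2 <- tau2 * exp(stats::rnorm(Ms, 0, jitter_sd))
  }
  vg <- if (md$M > 1L) stats::var(gamma) else 0
  list(theta = theta, gamma = gamma,
       beta0 = mean(md$y), beta1 = 0, beta2 = 0,
       sigma2 = sigma2, tau2 = tau2,
       omega2 = max(vg, 1e-3))
}

par_names <- function(md, variant, keep_theta) {
  Ms <- if (variant == "full") md$M else 1L
  sfx <- if (Ms == 1L) "" else paste0("[", seq_len(Ms), "]")
  nm <- c("beta0", "beta1", "beta2",
          paste0("gamma[", seq_len(md$M), "]"),
          paste0("sigma2", sfx), paste0("tau2", sfx), "omega2")
  if (keep_theta) {
    lab <- paste0("theta[", md$enc_study, ",",
                  stats::ave(md$enc_study, md$enc_study, FUN = seq_along), "]")
    nm <- c(nm, lab)
  }
  nm
}

#' Fit the hierarchical Bayesian ICC model
#'
#' Draws from the joint posterior of the truncated-normal hierarchical
#' model by Metropolis-within-Gibbs: exact conjugate updates for the
#' hyper-mean `beta0` and the between-study precision, univariate slice
#' sampling (on the logit scale for the latent `theta`, on the log scale
#' for variances) for every block whose conditional is non-conjugate.
#' Chains start from data-driven initial values, jittered per chain.
#'
#' @param data a [rating_table()]; rescaled automatically if needed.
#' @param config a [prior_config()] (hyperparameters and model variant).
#' @param n_chains number of chains (default 3).
#' @param n_iter total iterations per chain, including warmup
#'   (default 10000).
#' @param n_warmup warmup iterations discarded per chain (default
#'   `n_iter / 2`).
#' @param thin keep every `thin`-th post-warmup draw (default 1).
#' @param seed integer seed; required for reproducibility.
#' @param keep_theta store the latent per-encounter trait draws
#'   (default `FALSE`; they are not needed for the ICC functionals).
#' @return an object of class `icc_draws`: list with `draws` (one matrix
#'   per chain, columns named parameters), counts, `variant`, `prior`,
#'   `data_info` and a `diagnostics` data frame (split-chain R-hat, bulk
#'   ESS). A warning is issued if any reported R-hat exceeds 1.05.
#' @export
icc_fit <- function(data, config = prior_config(), n_chains = 3,
                    n_iter = 10000, n_warmup = floor(n_iter / 2), thin = 1,
                    seed, keep_theta = FALSE) {
  stopifnot(inherits(config, "prior_config"))
  if (missing(seed)) stop("`seed` must be supplied explicitly", call. = FALSE)
  if (n_warmup >= n_iter) stop("`n_warmup` must be < `n_iter`", call. = FALSE)
  if (!is_rescaled(data)) data <- rescale_ratings(data)
  md <- prepare_model_data(data)
  if (any(md$N_h < 2L)) {
    stop("each study needs at least 2 encounters", call. = FALSE)
  }
  variant <- config$variant
  sd_list <- sampler_data(md, variant)
  prior <- config[c("b0", "B2", "v1", "v2", "v3")]
  nm <- par_names(md, variant, keep_theta)

  set.seed(seed)
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    init <- initial_state(md, variant,
                          jitter_sd = if (ch == 1L) 0 else 0.05)
    m <- .run_chain(sd_list, prior, init, as.integer(n_iter),
                    as.integer(n_warmup), as.integer(thin), keep_theta)
    colnames(m) <- nm
    chains[[ch]] <- m
  }

  fit <- structure(list(
    draws = chains,
    pars = nm,
    n_chains = n_chains,
    n_warmup = n_warmup,
    n_kept = nrow(chains[[1L]]),
    thin = thin,
    seed = seed,
    variant = variant,
    prior = config,
    data_info = list(M = md$M, N_h = md$N_h, R = md$R, E = md$E,
                     study_labels = md$study_labels,
                     scale_max = attr(data, "scale_max"))
  ), class = "icc_draws")
  fit$diagnostics <- convergence(fit)
  warn_if_unconverged(fit$diagnostics)
  fit
}

# warn (never error) when reported parameters mix poorly
warn_if_unconverged <- function(diag, threshold = 1.05) {
  main <- !grepl("^theta\\[", diag$parameter)
  bad <- which(is.finite(diag$rhat[main]) & diag$rhat[main] > threshold)
  if (length(bad)) {
    warning("R-hat > ", threshold, " for: ",
            paste(diag$parameter[main][bad], collapse = ", "),
            "; consider more iterations", call. = FALSE)
  }
  invisible(diag)
}

#' @export
print.icc_draws <- function(x, ...) {
  cat(sprintf("Posterior draws (%s variant): %d chain(s) x %d kept (warmup %d, thin %d)\n",
              x$variant, x$n_chains, x$n_kept, x$n_warmup, x$thin))
  cat(sprintf("Data: M = %d studies, N = (%s), R = %d raters\n",
              x$data_info$M, paste(x$data_info$N_h, collapse = ", "),
              x$data_info$R))
  print(posterior_summary(x))
  invisible(x)
}

#' Pooled draws matrix
#'
#' @param x an `icc_draws` object.
#' @param ... unused.
#' @return matrix with all chains stacked, one column per parameter.
#' @export
as.matrix.icc_draws <- function(x, ...) {
  do.call(rbind, x$draws)
}

#' Posterior summary table
#'
#' Per-parameter posterior median and symmetric 95% credible interval
#' (2.5th and 97.5th percentiles) across all chains. When the data were
#' recorded on a 0-100 scale, the within-encounter scale rows are already
#' on the rescaled, i.e. `(sigma/100)^2`, scale. Because it is ambiguous
#' whether between-study spread should be read as a standard deviation or
#' a variance, both `omega2` and `omega` rows are reported.
#'
#' @param draws an `icc_draws` object.
#' @param prob total credible mass (default 0.95).
#' @return data frame with columns `parameter`, `median`, `q2.5`, `q97.5`
#'   (quantile columns named from `prob`).
#' @export
posterior_summary <- function(draws, prob = 0.95) {
  stopifnot(inherits(draws, "icc_draws"))
  m <- as.matrix(draws)
  if (nrow(m) == 0L) stop("no retained draws", call. = FALSE)
  if ("omega2" %in% colnames(m)) {
    m <- cbind(m, omega = sqrt(m[, "omega2"]))
  }
  a <- (1 - prob) / 2
  qs <- t(apply(m, 2L, stats::quantile, probs = c(0.5, a, 1 - a),
                names = FALSE))
  out <- data.frame(parameter = colnames(m),
                    median = qs[, 1L], q1 = qs[, 2L], q2 = qs[, 3L],
                    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[3:4] <- paste0("q", format(100 * c(a, 1 - a), trim = TRUE,
                                        drop0trailing = TRUE))
  out
}
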