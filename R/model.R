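#' Prior configuration for the hierarchical ICC model
#'
#' Hyperparameters of the weakly informative priors:
#' \deqn{\gamma_h \sim N(\beta_0, \omega^2), \quad
#'       \beta_k \sim N(b_0 1\{k=0\}, B^2), \quad
#'       \sigma_h^{-2}, \tau_h^{-2}, \omega^{-2} \sim
#'       \mathrm{Gamma}(v_l, v_l).}
#' The gamma priors are shape/rate with shape = rate = `v_l`, so each
#' precision has prior mean 1 and, for small `v_l`, very large variance.
#' Defaults are `b0 = 0.4`, `B2 = 10`, `v1 = v2 = v3 = 1e-3`.
#'
#' @param b0 prior mean of the intercept `beta0` (grand mean of the latent
#'   trait, on the (0,1) scale).
#' @param B2 prior variance of the regression coefficients.
#' @param v1,v2,v3 gamma shape/rate for the precisions of, respectively,
#'   the within-encounter scale `sigma_h^2`, the between-encounter variance
#'   `tau_h^2`, and the between-study variance `omega^2`.
#' @param variant model variant: `"full"` (study-specific `sigma_h^2`,
#'   `tau_h^2`, binomial variance function), `"homogeneous_binomial"`
#'   (shared `sigma^2`, `tau^2`, binomial variance function), or
#'   `"homogeneous_constant"` (shared variances, constant within-encounter
#'   variance — no dependence on the trait level).
#' @return object of class `prior_config`.
#' @export
prior_config <- function(b0 = 0.4, B2 = 10, v1 = 1e-3, v2 = 1e-3, v3 = 1e-3,
                         variant = c("full", "homogeneous_binomial",
                                     "homogeneous_constant")) {
  variant <- match.arg(variant)
  if (!is.numeric(B2) || B2 <= 0) stop("B2 must be > 0", call. = FALSE)
  if (any(c(v1, v2, v3) <= 0)) stop("v1, v2, v3 must be > 0", call. = FALSE)
  structure(list(b0 = b0, B2 = B2, v1 = v1, v2 = v2, v3 = v3,
                 variant = variant),
            class = "prior_config")
}

#' @export
print.prior_config <- function(x, ...) {
  cat(sprintf("Prior config (variant = %s): b0 = %g, B2 = %g, v = (%g, %g, %g)\n",
              x$variant, x$b0, x$B2, x$v1, x$v2, x$v3))
  invisible(x)
}

#' Parameter state of the hierarchical model
#'
#' One complete parameter state: latent trait levels `theta` (one per
#' encounter, in model order — the encounter order of the prepared table),
#' study means `gamma`, coefficients `beta0` (intercept), `beta1` (rater
#' effect), `beta2` (covariate effect), within-encounter scales `sigma2`
#' (length M, or 1 for homogeneous variants), between-encounter variances
#' `tau2` (same length rule), and the between-study variance `omega2`.
#'
#' @param theta,gamma,beta0,beta1,beta2,sigma2,tau2,omega2 see description.
#' @return object of class `model_params`.
#' @export
model_params <- function(theta, gamma, beta0, beta1, beta2,
                         sigma2, tau2, omega2) {
  p <- structure(list(theta = as.numeric(theta), gamma = as.numeric(gamma),
                      beta0 = beta0, beta1 = beta1, beta2 = beta2,
                      sigma2 = as.numeric(sigma2), tau2 = as.numeric(tau2),
                      omega2 = omega2),
                 class = "model_params")
  if (any(p$sigma2 <= 0) || any(p$tau2 <= 0) || p$omega2 <= 0) {
    stop("variance/scale parameters must be strictly positive", call. = FALSE)
  }
  if (any(p$theta <= 0 | p$theta >= 1)) {
    stop("theta values must lie strictly inside (0, 1)", call. = FALSE)
  }
  p
}

# log(Phi(b) - Phi(a)) computed stably for a < b (vectorized).
log_phi_diff <- function(a, b) {
  flip <- (a + b) > 0                 # reflect so the mass sits in the
  aa <- ifelse(flip, -b, a)           # well-conditioned lower tail
  bb <- ifelse(flip, -a, b)
  la <- stats::pnorm(aa, log.p = TRUE)
  lb <- stats::pnorm(bb, log.p = TRUE)
  lb + log1p(-exp(la - lb))
}

# log density of Normal(mean, sd^2) truncated to (lower, upper), vectorized.
log_dtnorm <- function(x, mean, sd, lower = 0, upper = 1) {
  out <- stats::dnorm(x, mean, sd, log = TRUE) -
    log_phi_diff((lower - mean) / sd, (upper - mean) / sd)
  out[x <= lower | x >= upper] <- -Inf
  out
}

#' Model log-likelihood
#'
#' Sum over records of the log truncated-normal density on (0, 1) with mean
#' \deqn{\mu_{hij} = \theta_{hi} + \beta_1 (j - (R+1)/2) +
#'       \beta_2 (X_{hi} - \bar X)}
#' and variance \eqn{v_{hi}^2 = \sigma_h^2 \theta_{hi} (1 - \theta_{hi})}
#' (binomial variance function; for `homogeneous_constant` the variance is
#' the constant \eqn{\sigma^2}). The truncation normalizer
#' \eqn{\Phi((1-\mu)/v) - \Phi(-\mu/v)} is included. At `R = 2` raters the
#' rater coding reduces to \eqn{j - 1.5}, i.e. \eqn{\pm 1/2}.
#'
#' This is the plain-R reference implementation; the sampler uses a
#' compiled equivalent which is tested against it.
#'
#' @param params a [model_params()] state.
#' @param data a rescaled [rating_table()].
#' @param variant model variant (see [prior_config()]).
#' @param truncate if `FALSE`, drop the truncation normalizer (an
#'   ordinary-normal debugging mode).
#' @return the log-likelihood (a single finite number, or an error naming
#'   the first offending record if non-finite).
#' @export
icc_log_likelihood <- function(params, data, variant = "full",
                               truncate = TRUE) {
  md <- prepare_model_data(data)
  ll <- record_loglik(params, md, variant, truncate)
  if (!is.finite(sum(ll))) {
    bad <- which(!is.finite(ll))[1L]
    stop("non-finite log-likelihood at record ", bad, call. = FALSE)
  }
  sum(ll)
}

# per-record log-likelihood contributions
record_loglik <- function(params, md, variant, truncate = TRUE) {
  theta_r <- params$theta[md$enc]
  mu <- theta_r + params$beta1 * md$rater_code +
    params$beta2 * md$x_centered
  if (variant == "homogeneous_constant") {
    v2 <- rep(params$sigma2[1L], length(mu))
  } else {
    s2 <- if (length(params$sigma2) == 1L) {
      rep(params$sigma2, md$M)
    } else params$sigma2
    v2 <- s2[md$study] * theta_r * (1 - theta_r)
  }
  v <- sqrt(v2)
  if (truncate) {
    log_dtnorm(md$y, mu, v)
  } else {
    stats::dnorm(md$y, mu, v, log = TRUE)
  }
}

#' Model log-prior
#'
#' Sum of the log prior densities: truncated-normal
#' \eqn{N(\gamma_h, \tau_h^2) I(0,1)} for each latent `theta`, normal
#' \eqn{N(\beta_0, \omega^2)} for the study means, normal priors for the
#' coefficients, and Gamma(`v_l`, `v_l`) for the precisions. The density is
#' expressed with respect to the stored parameterization (variances), so
#' each precision term carries the change-of-variables factor
#' \eqn{t^{-2}}; `icc_log_likelihood + icc_log_prior` is then an honest
#' unnormalized log posterior density over the `model_params` state.
#'
#' Any parameter outside its support yields `-Inf` (a rejection signal),
#' never an error.
#'
#' @inheritParams icc_log_likelihood
#' @param config a [prior_config()].
#' @return a single number, possibly `-Inf`.
#' @export
icc_log_prior <- function(params, config, data) {
  md <- prepare_model_data(data)
  th <- params$theta
  if (any(!is.finite(th)) || any(th <= 0 | th >= 1)) return(-Inf)
  if (any(params$sigma2 <= 0) || any(params$tau2 <= 0) ||
      params$omega2 <= 0) return(-Inf)
  tau2 <- if (length(params$tau2) == 1L) rep(params$tau2, md$M) else params$tau2
  lp <- sum(log_dtnorm(th, params$gamma[md$enc_study],
                       sqrt(tau2[md$enc_study])))
  lp <- lp + sum(stats::dnorm(params$gamma, params$beta0,
                              sqrt(params$omega2), log = TRUE))
  lp <- lp + stats::dnorm(params$beta0, config$b0, sqrt(config$B2), log = TRUE) +
    stats::dnorm(params$beta1, 0, sqrt(config$B2), log = TRUE) +
    stats::dnorm(params$beta2, 0, sqrt(config$B2), log = TRUE)
  lgam_var <- function(t, v) {     # Gamma(v, v) on 1/t, density in t
    stats::dgamma(1 / t, shape = v, rate = v, log = TRUE) - 2 * log(t)
  }
  lp <- lp + sum(lgam_var(params$sigma2, config$v1)) +
    sum(lgam_var(params$tau2, config$v2)) +
    lgam_var(params$omega2, config$v3)
  if (is.nan(lp)) -Inf else lp
}

#' @rdname icc_log_prior
#' @export
icc_log_posterior <- function(params, config, data) {
  lp <- icc_log_prior(params, config, data)
  if (!is.finite(lp)) return(-Inf)
  lp + icc_log_likelihood(params, data, variant = config$variant)
}
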