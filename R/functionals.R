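# --- ICC functionals -------------------------------------------------------
# The model yields a two-dimensional family of ICC measures:
#   * point vs population-averaged in the trait level theta*;
#   * within-study vs marginal/pooled (between-study variance omega^2
#     counted as between-encounter signal or not).

#' Pointwise ICC at a trait level
#'
#' \deqn{ICC_h(\theta^*) = \tau_h^2 / (\tau_h^2 + \sigma_h^2
#' \theta^*(1-\theta^*)).} At exactly `theta_star` 0 or 1 the
#' within-encounter variance vanishes and the ICC is 1 by continuity
#' (a message notes this).
#'
#' @param tau2 between-encounter variance (> 0); vectorized.
#' @param sigma2 within-encounter scale (> 0); vectorized.
#' @param theta_star trait level in `[0, 1]`.
#' @return ICC value(s) in (0, 1].
#' @export
icc_point <- function(tau2, sigma2, theta_star) {
  if (any(tau2 <= 0) || any(sigma2 < 0)) {
    stop("tau2 must be > 0 and sigma2 >= 0", call. = FALSE)
  }
  if (any(theta_star < 0 | theta_star > 1)) {
    stop("theta_star must lie in [0, 1]", call. = FALSE)
  }
  if (any(theta_star == 0 | theta_star == 1)) {
    message("theta_star at the scale boundary: ICC = 1 by continuity")
  }
  tau2 / (tau2 + sigma2 * theta_star * (1 - theta_star))
}

#' Marginal (pooled-across-studies) ICC
#'
#' When encounters are pooled across studies with equal selection
#' probability, the between-study variance joins the signal:
#' \deqn{ICC_{Marg}(\theta^*) = (\omega^2 + \bar\tau^2) /
#' (\omega^2 + \bar\tau^2 + \bar\sigma^2 \theta^*(1-\theta^*)).}
#' `tau2_bar` and `sigma2_bar` are (weighted) means of the per-study
#' variances. For any `omega2 > 0` this exceeds the within-study
#' [icc_point()] at the same `theta_star`; at `omega2 = 0` the two agree.
#'
#' @param omega2 between-study variance (>= 0).
#' @inheritParams icc_point
#' @param tau2_bar,sigma2_bar averaged variance components.
#' @export
icc_marginal <- function(omega2, tau2_bar, sigma2_bar, theta_star) {
  if (any(omega2 < 0)) stop("omega2 must be >= 0", call. = FALSE)
  num <- omega2 + tau2_bar
  den <- num + sigma2_bar * theta_star * (1 - theta_star)
  if (any(den == 0)) stop("all variance components zero; ICC undefined",
                          call. = FALSE)
  num / den
}

# truncated-normal density on (0,1); log-space normalizer so means far
# outside the interval (posterior ridge states) stay finite
dtnorm01 <- function(x, mean, sd) {
  lz <- log_phi_diff((0 - mean) / sd, (1 - mean) / sd)
  out <- exp(stats::dnorm(x, mean, sd, log = TRUE) - lz)
  out[x <= 0 | x >= 1] <- 0
  out
}

# 64-point Gauss-Legendre nodes/weights on (0,1), cached
gl_nodes <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 64L, a = 0, b = 1) {
    key <- paste(n, a, b)
    if (is.null(cache[[key]])) {
      cache[[key]] <- pracma::gaussLegendre(n, a, b)
    }
    cache[[key]]
  }
})

#' Population-averaged ICC
#'
#' \deqn{\overline{ICC} = \tau^2 \int_0^1 (\tau^2 + \sigma^2
#' \theta^*(1-\theta^*))^{-1} \pi(\theta^*)\, d\theta^*} for a population
#' distribution \eqn{\pi} of trait levels, evaluated by 64-point
#' Gauss-Legendre quadrature with an adaptive bisection check (the
#' interval is split in two and re-integrated; disagreement beyond `tol`
#' raises an error).
#'
#' @inheritParams icc_point
#' @param pi_spec either `list(mean =, sd =)` (or `list(gamma =, tau2 =)`)
#'   describing a truncated normal on (0, 1), or a density function on
#'   (0, 1). A function must integrate to 1 within `tol`.
#' @param tol quadrature tolerance (default 1e-6).
#' @export
icc_average <- function(tau2, sigma2, pi_spec, tol = 1e-6) {
  if (tau2 <= 0 || sigma2 < 0) {
    stop("tau2 must be > 0 and sigma2 >= 0", call. = FALSE)
  }
  lo <- 0
  hi <- 1
  dens <- if (is.function(pi_spec)) {
    pi_spec
  } else if (is.list(pi_spec)) {
    mu <- if (!is.null(pi_spec$mean)) pi_spec$mean else pi_spec$gamma
    sd <- if (!is.null(pi_spec$sd)) pi_spec$sd else sqrt(pi_spec$tau2)
    if (is.null(mu) || is.null(sd)) {
      stop("pi_spec list needs mean/sd (or gamma/tau2)", call. = FALSE)
    }
    # a known truncated normal lets the rule sit on its effective
    # support, so even near-point-mass distributions are resolved
    lo <- max(0, mu - 12 * sd)
    hi <- min(1, mu + 12 * sd)
    if (lo >= hi) { lo <- 0; hi <- 1 }
    function(t) dtnorm01(t, mu, sd)
  } else {
    stop("pi_spec must be a list or a density function", call. = FALSE)
  }
  quad <- function(f, a, b) {
    g <- gl_nodes(64L, a, b)
    sum(g$w * f(g$x))
  }
  mid <- (lo + hi) / 2
  mass <- quad(dens, lo, hi)
  mass2 <- quad(dens, lo, mid) + quad(dens, mid, hi)
  if (abs(mass2 - mass) > tol) {
    stop("quadrature non-convergence for pi density", call. = FALSE)
  }
  if (abs(mass - 1) > max(tol, 1e-4)) {
    stop("pi density does not integrate to 1 on (0,1)", call. = FALSE)
  }
  integrand <- function(t) dens(t) / (tau2 + sigma2 * t * (1 - t))
  v1 <- quad(integrand, lo, hi)
  v2 <- quad(integrand, lo, mid) + quad(integrand, mid, hi)
  if (abs(v2 - v1) > tol * max(1, abs(v1))) {
    stop("quadrature non-convergence for ICC integrand", call. = FALSE)
  }
  tau2 * v2 / mass
}

#' ICC query specification
#'
#' Describes which member of the ICC family to evaluate on posterior
#' draws: `mode = "point"` fixes a trait level `theta_star`; `mode =
#' "average"` integrates over a population distribution of trait levels
#' (by default each draw's own truncated-normal
#' \eqn{N(\gamma_h, \tau_h^2) I(0,1)}). `pooled = TRUE` adds the
#' between-study variance to the numerator (marginal ICC across studies),
#' with optional study `weights` for unequal selection probabilities.
#'
#' @param mode `"average"` (default) or `"point"`.
#' @param theta_star trait level for point mode (default 0.5).
#' @param pi_spec optional explicit population distribution (see
#'   [icc_average()]); if `NULL` in average mode, each draw's
#'   `(gamma, tau2)` defines it.
#' @param pooled logical; marginal/pooled ICC.
#' @param weights optional per-study weights (default equal).
#' @export
icc_query <- function(mode = c("average", "point"), theta_star = 0.5,
                      pi_spec = NULL, pooled = FALSE, weights = NULL) {
  mode <- match.arg(mode)
  if (mode == "point" &&
      (!is.numeric(theta_star) || theta_star <= 0 || theta_star >= 1)) {
    stop("point mode needs theta_star strictly inside (0, 1)", call. = FALSE)
  }
  structure(list(mode = mode, theta_star = theta_star, pi_spec = pi_spec,
                 pooled = pooled, weights = weights),
            class = "icc_query")
}

# Per-draw ICC values for a query. Returns a matrix draws x columns where
# columns are studies (full variant, within-study query) or a single
# pooled/homogeneous column.
icc_draw_values <- function(draws, query) {
  stopifnot(inherits(draws, "icc_draws"), inherits(query, "icc_query"))
  m <- as.matrix(draws)
  M <- draws$data_info$M
  full <- draws$variant == "full"
  gcols <- paste0("gamma[", seq_len(M), "]")
  tau2 <- if (full) m[, paste0("tau2[", seq_len(M), "]"), drop = FALSE] else
    m[, "tau2", drop = FALSE]
  sig2 <- if (full) m[, paste0("sigma2[", seq_len(M), "]"), drop = FALSE] else
    m[, "sigma2", drop = FALSE]
  constant_var <- draws$variant == "homogeneous_constant"
  w <- query$weights
  if (is.null(w)) w <- rep(1 / M, M) else w <- w / sum(w)

  u_of <- function(t) if (constant_var) rep(1, length(t)) else t * (1 - t)

  avg_over_pi <- function(num, sig2v, g, tv, om2 = NULL) {
    # num, sig2v: draw vectors; pi = tnorm(g, tv) per draw unless pi_spec
    gl <- gl_nodes(64L)
    U <- u_of(gl$x)                              # length 64
    if (!is.null(query$pi_spec)) {
      dv <- if (is.function(query$pi_spec)) query$pi_spec(gl$x) else {
        mu <- if (!is.null(query$pi_spec$mean)) query$pi_spec$mean else
          query$pi_spec$gamma
        sdv <- if (!is.null(query$pi_spec$sd)) query$pi_spec$sd else
          sqrt(query$pi_spec$tau2)
        dtnorm01(gl$x, mu, sdv)
      }
      dens <- matrix(dv, nrow = length(num), ncol = length(gl$x),
                     byrow = TRUE)
      dens <- dens / sum(gl$w * dv)
    } else {
      sdv <- sqrt(tv)
      lz <- log_phi_diff(-g / sdv, (1 - g) / sdv)  # log normalizer per draw
      zmat <- outer(g, gl$x, function(a, b) b - a) / sdv
      dens <- exp(stats::dnorm(zmat, log = TRUE) - log(sdv) - lz)
    }
    denom <- num + outer(sig2v, U)                # draws x 64
    rowSums(sweep(dens / denom, 2L, gl$w, `*`)) * num
  }

  if (query$pooled) {
    om2 <- m[, "omega2"]
    tau2_bar <- as.vector(tau2 %*% (if (full) w else 1))
    sig2_bar <- as.vector(sig2 %*% (if (full) w else 1))
    num <- om2 + tau2_bar
    if (query$mode == "point") {
      u <- u_of(query$theta_star)
      vals <- num / (num + sig2_bar * u)
    } else {
      gbar <- as.vector(m[, gcols, drop = FALSE] %*% w)
      vals <- avg_over_pi(num, sig2_bar, gbar, om2 + tau2_bar)
    }
    out <- matrix(vals, ncol = 1L)
    colnames(out) <- "pooled"
    return(out)
  }

  if (full) {
    out <- matrix(NA_real_, nrow(m), M)
    colnames(out) <- draws$data_info$study_labels
    for (h in seq_len(M)) {
      if (query$mode == "point") {
        u <- u_of(query$theta_star)
        out[, h] <- tau2[, h] / (tau2[, h] + sig2[, h] * u)
      } else {
        out[, h] <- avg_over_pi(tau2[, h], sig2[, h],
                                m[, gcols[h]], tau2[, h])
      }
    }
    out
  } else {
    if (query$mode == "point") {
      u <- u_of(query$theta_star)
      vals <- tau2[, 1L] / (tau2[, 1L] + sig2[, 1L] * u)
    } else {
      gbar <- as.vector(m[, gcols, drop = FALSE] %*% w)
      vals <- avg_over_pi(tau2[, 1L], sig2[, 1L], gbar, tau2[, 1L])
    }
    out <- matrix(vals, ncol = 1L)
    colnames(out) <- "within"
    out
  }
}

summarize_icc_draws <- function(vals) {
  qs <- t(apply(vals, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975),
                names = FALSE))
  data.frame(group = colnames(vals),
             mean = colMeans(vals),
             median = qs[, 2L], q2.5 = qs[, 1L], q97.5 = qs[, 3L],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Posterior ICC summaries
#'
#' Evaluates the requested ICC functional on every retained draw (using
#' that draw's own variance components, and in average mode its own
#' \eqn{(\gamma_h, \tau_h^2)} population distribution unless an explicit
#' one is supplied), then summarizes by posterior mean, median and 95%
#' interval. This is the exact posterior functional: the nonlinear ICC is
#' applied before averaging, never to parameter point estimates.
#'
#' @param draws an `icc_draws` object.
#' @param query an [icc_query()].
#' @return data frame (class `icc_summary`) with one row per study (full
#'   variant, within-study queries) or a single row; the per-draw
#'   functional values are attached as attribute `icc_draws`.
#' @export
icc_posterior <- function(draws, query = icc_query()) {
  vals <- icc_draw_values(draws, query)
  out <- summarize_icc_draws(vals)
  attr(out, "icc_draws") <- vals
  attr(out, "query") <- query
  class(out) <- c("icc_summary", "data.frame")
  out
}

#' ICC as a function of the trait level
#'
#' Evaluates the pointwise ICC on a grid of `grid_size` evenly spaced
#' trait levels spanning 0 to 1 inclusive (default 101) on every posterior
#' draw, and returns the posterior mean and 95% band per study and grid
#' point. The grid endpoints have ICC 1 by continuity (the
#' within-encounter variance vanishes there); they are flagged in the
#' `endpoint` column.
#'
#' @param draws an `icc_draws` object.
#' @param grid_size number of grid points (default 101).
#' @return tidy data frame: `study`, `theta_star`, `mean`, `q2.5`,
#'   `q97.5`, `endpoint`.
#' @export
icc_curve <- function(draws, grid_size = 101L) {
  stopifnot(inherits(draws, "icc_draws"), grid_size >= 2L)
  m <- as.matrix(draws)
  M <- draws$data_info$M
  full <- draws$variant == "full"
  grid <- seq(0, 1, length.out = grid_size)
  u <- grid * (1 - grid)
  if (draws$variant == "homogeneous_constant") u <- rep(1, grid_size)
  studies <- if (full) draws$data_info$study_labels else "all"
  res <- vector("list", length(studies))
  for (h in seq_along(studies)) {
    tau2 <- if (full) m[, paste0("tau2[", h, "]")] else m[, "tau2"]
    sig2 <- if (full) m[, paste0("sigma2[", h, "]")] else m[, "sigma2"]
    icc <- tau2 / (tau2 + outer(sig2, u))         # draws x grid
    qs <- apply(icc, 2L, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE)
    res[[h]] <- data.frame(study = studies[h], theta_star = grid,
                           mean = colMeans(icc),
                           q2.5 = qs[1L, ], q97.5 = qs[2L, ],
                           endpoint = grid %in% c(0, 1),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pairwise study differences in ICC
#'
#' For each pair of studies (a, b), the per-draw difference
#' `ICC_a - ICC_b` under the given query, summarized by posterior mean,
#' median, 95% interval and the posterior probability that the difference
#' exceeds 0 (strict inequality; exact ties count 1/2).
#'
#' @param draws full-variant `icc_draws` (per-study parameters required).
#' @param query an [icc_query()] (within-study; `pooled` must be FALSE).
#' @return data frame with one row per ordered pair (a < b).
#' @export
icc_pairwise <- function(draws, query = icc_query()) {
  stopifnot(inherits(draws, "icc_draws"))
  if (draws$variant != "full") {
    stop("pairwise comparisons need full-variant draws", call. = FALSE)
  }
  if (isTRUE(query$pooled)) {
    stop("pairwise comparisons are within-study; use pooled = FALSE",
         call. = FALSE)
  }
  M <- draws$data_info$M
  if (M < 2L) stop("need at least 2 studies", call. = FALSE)
  vals <- icc_draw_values(draws, query)
  labs <- colnames(vals)
  pairs <- utils::combn(M, 2L)
  res <- apply(pairs, 2L, function(p) {
    d <- vals[, p[1L]] - vals[, p[2L]]
    q <- stats::quantile(d, c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(pair = paste(labs[p[1L]], "-", labs[p[2L]]),
               mean = mean(d), median = q[2L], q2.5 = q[1L], q97.5 = q[3L],
               pr_gt0 = mean((d > 0) + 0.5 * (d == 0)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
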