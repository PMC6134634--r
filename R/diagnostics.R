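# Convergence diagnostics: split-chain rank-normalized R-hat and bulk
# effective sample size (the current-practice definitions). Implemented on
# a draws matrix with one column per chain.

split_chains <- function(x) {
  n <- nrow(x)
  h <- floor(n / 2)
  cbind(x[seq_len(h), , drop = FALSE],
        x[(n - h + 1):n, , drop = FALSE])
}

rank_normalize <- function(x) {
  z <- stats::qnorm((rank(as.vector(x), ties.method = "average") - 3 / 8) /
                      (length(x) + 1 / 4))
  matrix(z, nrow = nrow(x), ncol = ncol(x))
}

# classic potential scale reduction on an iterations x chains matrix
rhat_basic <- function(x) {
  n <- nrow(x)
  W <- mean(apply(x, 2L, stats::var))
  B <- n * stats::var(colMeans(x))
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

#' @rdname convergence
#' @param x matrix of draws, iterations in rows and chains in columns.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 4L) return(NA_real_)
  if (all(abs(x - x[1L]) < .Machine$double.eps * 100)) return(1)
  rhat_basic(rank_normalize(split_chains(x)))
}

#' @rdname convergence
#' @export
ess_bulk <- function(x) {
  x <- as.matrix(x)
  n_total <- length(x)
  if (nrow(x) < 4L) return(NA_real_)
  if (all(abs(x - x[1L]) < .Machine$double.eps * 100)) return(NA_real_)
  z <- rank_normalize(split_chains(x))
  n <- nrow(z); m <- ncol(z)
  acov <- apply(z, 2L, function(v) {
    a <- stats::acf(v, lag.max = n - 1L, plot = FALSE,
                    demean = TRUE, type = "covariance")$acf[, 1L, 1L]
    a * (n - 1) / n
  })
  mean_acov <- rowMeans(acov)
  W <- mean(apply(z, 2L, stats::var))
  B <- n * stats::var(colMeans(z))
  var_plus <- (n - 1) / n * W + B / n
  rho <- 1 - (W - mean_acov) / var_plus       # rho[1] corresponds to lag 0
  # Geyer initial monotone positive sequence on paired sums
  max_pairs <- floor((length(rho) - 1) / 2)
  psum <- numeric(0)
  for (k in seq_len(max_pairs)) {
    p <- rho[2 * k] + rho[2 * k + 1]          # lags 2k-1, 2k
    if (p < 0) break
    psum <- c(psum, p)
  }
  if (length(psum) > 1L) psum <- cummin(psum)
  tau <- -1 + 2 * (1 + sum(psum))             # rho_0 = 1
  max(n_total / max(tau, 1 / log10(n_total + 1)), 1e-8)
}

#' Convergence diagnostics for posterior draws
#'
#' Split-chain rank-normalized R-hat and bulk effective sample size per
#' scalar parameter. With a single chain, R-hat is marked unavailable
#' (`NA`) while ESS is still computed. Chains with (numerically) zero
#' variance are flagged and reported with R-hat 1.
#'
#' @param draws an `icc_draws` object from [icc_fit()].
#' @return data frame with columns `parameter`, `rhat`, `ess`, `note`.
#' @export
convergence <- function(draws) {
  stopifnot(inherits(draws, "icc_draws"))
  pars <- draws$pars
  out <- data.frame(parameter = pars, rhat = NA_real_, ess = NA_real_,
                    note = "", stringsAsFactors = FALSE)
  for (i in seq_along(pars)) {
    x <- vapply(draws$draws, function(m) m[, i], numeric(draws$n_kept))
    x <- matrix(x, nrow = draws$n_kept)
    zero_var <- all(abs(x - x[1L]) < .Machine$double.eps * 100)
    if (zero_var) {
      out$rhat[i] <- 1
      out$note[i] <- "zero variance"
      next
    }
    out$rhat[i] <- if (draws$n_chains >= 2L) split_rhat(x) else NA_real_
    if (draws$n_chains < 2L) out$note[i] <- "single chain: R-hat unavailable"
    out$ess[i] <- ess_bulk(x)
  }
  out
}
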