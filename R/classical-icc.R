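#' Classical one-way ANOVA variance components
#'
#' Method-of-moments variance components from a one-way random-effects
#' ANOVA with encounters as the grouping factor, the textbook estimator
#' behind the classical ICC \eqn{\sigma_b^2 / (\sigma_b^2 + \sigma_w^2)}.
#' The within component is the within-encounter mean square; the between
#' component is \eqn{\max(0, (MS_b - MS_w) / k_0)} where
#' \eqn{k_0 = (\sum k_i - \sum k_i^2 / \sum k_i) / (n - 1)} is the standard
#' unbalanced-design coefficient (equal to the common number of raters when
#' the design is balanced). Mean squares are taken from [stats::anova()] on
#' a linear model with an encounter factor.
#'
#' This baseline deliberately makes the classical assumptions the
#' hierarchical model relaxes: one homogeneous population of encounters and
#' a constant within-encounter variance, with no rater or covariate
#' adjustment.
#'
#' @param table a [rating_table()] (rescaled or not; scores are analysed on
#'   the (0,1) scale).
#' @return object of class `variance_components`: list with `sigma_b2`,
#'   `sigma_w2`, `n_encounters`, `k0`, `k` (mean raters per encounter).
#' @export
estimate_components <- function(table) {
  stopifnot(inherits(table, "rating_table"))
  y <- if (is_rescaled(table)) table$y else table$score / scale_max(table)
  enc <- factor(paste(table$study, table$encounter, sep = "\r"))
  k_i <- as.integer(table(enc))
  n <- nlevels(enc)
  if (n < 2L) stop("need at least 2 encounters", call. = FALSE)
  if (all(k_i < 2L)) {
    stop("all encounters have a single rating; within-encounter variance is unidentifiable",
         call. = FALSE)
  }
  N <- sum(k_i)
  # the F-test warning on a saturated fit is irrelevant: only the mean
  # squares are used
  a <- suppressWarnings(stats::anova(stats::lm(y ~ enc)))
  ms_between <- a$`Mean Sq`[1L]
  ms_within <- a$`Mean Sq`[2L]
  # zap numerical dust so exactly-degenerate inputs give exact zeros
  if (ms_between < 1e-14) ms_between <- 0
  if (ms_within < 1e-14) ms_within <- 0
  k0 <- (N - sum(k_i^2) / N) / (n - 1)
  structure(list(
    sigma_b2 = max(0, (ms_between - ms_within) / k0),
    sigma_w2 = ms_within,
    n_encounters = n,
    k0 = k0,
    k = N / n
  ), class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("Variance components (one-way ANOVA, %d encounters):\n",
              x$n_encounters))
  cat(sprintf("  between-encounter sigma_b^2 = %.6g\n", x$sigma_b2))
  cat(sprintf("  within-encounter  sigma_w^2 = %.6g  (k0 = %.4g)\n",
              x$sigma_w2, x$k0))
  invisible(x)
}

#' Classical intraclass correlation and k-rater reliability
#'
#' `icc_classical()` returns \eqn{\sigma_b^2 / (\sigma_b^2 + \sigma_w^2)},
#' the single-rating consistency ICC. `reliability_k()` returns
#' \eqn{\sigma_b^2 / (\sigma_b^2 + \sigma_w^2 / k)}, the reliability of the
#' mean of `k` raters, which reduces to the ICC at `k = 1` and tends to 1
#' as `k` grows.
#'
#' @param components a `variance_components` object from
#'   [estimate_components()].
#' @return a single number in `[0, 1]`.
#' @export
icc_classical <- function(components) {
  stopifnot(inherits(components, "variance_components"))
  tot <- components$sigma_b2 + components$sigma_w2
  if (tot <= 0) {
    stop("both variance components are zero; ICC undefined", call. = FALSE)
  }
  components$sigma_b2 / tot
}

#' @rdname icc_classical
#' @param k number of raters averaged (integer >= 1).
#' @export
reliability_k <- function(components, k) {
  stopifnot(inherits(components, "variance_components"))
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    stop("`k` must be a number >= 1", call. = FALSE)
  }
  tot <- components$sigma_b2 + components$sigma_w2 / k
  if (tot <= 0) {
    stop("both variance components are zero; reliability undefined",
         call. = FALSE)
  }
  components$sigma_b2 / tot
}
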