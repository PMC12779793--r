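#' Posterior distribution of true mastery from trial counts
#'
#' Fits the conjugate beta-binomial model for a single student and skill
#' component: given `n` independent assessment trials of which `x` were
#' correct, and a Beta prior on the latent true mastery level \eqn{p}
#' (the probability the student answers an arbitrary item from the skill
#' component space correctly), the posterior is
#' Beta(`x + prior_alpha`, `n - x + prior_beta`).
#'
#' Conditioning is on the exact observed count `x`, matching the reference
#' criterion tables, which index rows by the number correct.
#'
#' @param n positive integer number of trials.
#' @param x integer number of correct responses, `0 <= x <= n`.
#' @param prior a [mastery_prior()] object or anything it accepts;
#'   default is the Jeffreys Beta(0.5, 0.5) prior.
#' @return an object of class `mastery_posterior`: a list with shape
#'   parameters `alpha`, `beta` and the provenance fields `n`, `x`, `prior`.
#' @examples
#' post <- mastery_posterior(n = 10, x = 8)
#' post$alpha                       # 8.5
#' mastery_prob(post, 0.90)         # Pr(p >= 0.90 | data) = 0.143...
#' mean(post)                       # 8.5 / 11
#' quantile(post, 0.05)             # 95% credible lower bound
#' @seealso [mastery_prob()], [lower_credible_bound()], [mastery_summary()],
#'   [criterion_table()]
#' @export
mastery_posterior <- function(n, x, prior = mastery_prior()) {
  check_counts(n, x)
  prior <- mastery_prior(prior)
  structure(
    list(alpha = x + prior$alpha, beta = n - x + prior$beta,
         n = as.integer(n), x = as.integer(x), prior = prior),
    class = "mastery_posterior"
  )
}

check_counts <- function(n, x) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n)) {
    stop("`n` must be a single integer >= 1 (got ", deparse(n), ")",
         call. = FALSE)
  }
  if (length(x) != 1L || !is.finite(x) || x != round(x)) {
    stop("`x` must be a single integer (got ", deparse(x), ")",
         call. = FALSE)
  }
  if (x < 0) stop("`x` must satisfy x >= 0 (got x = ", x, ")", call. = FALSE)
  if (x > n) stop("`x` must satisfy x <= n (got x = ", x, ", n = ", n, ")",
                  call. = FALSE)
  invisible(TRUE)
}

#' Probability that true mastery meets a desired threshold
#'
#' The upper-tail posterior probability \eqn{b = Pr(p \ge p^* | x, n)}:
#' the confidence, conferred by the observed assessment, that the student's
#' latent mastery is at least the desired level `p_star`. At `p_star = 1`
#' the continuous posterior assigns no mass to the point, so `b = 0`.
#'
#' @param post a [mastery_posterior()] object.
#' @param p_star desired true-mastery threshold in `[0, 1]`; vectorised.
#' @return probability (or vector of probabilities) in `[0, 1]`.
#' @examples
#' mastery_prob(mastery_posterior(10, 8), 0.90)  # ~0.143
#' mastery_prob(mastery_posterior(5, 5), 0.90)   # ~0.71
#' @export
mastery_prob <- function(post, p_star) {
  stopifnot(inherits(post, "mastery_posterior"))
  if (length(p_star) < 1L || any(!is.finite(p_star)) ||
      any(p_star < 0) || any(p_star > 1)) {
    stop("`p_star` must lie in [0, 1]", call. = FALSE)
  }
  b <- stats::pbeta(p_star, post$alpha, post$beta, lower.tail = FALSE)
  # continuous posterior: Pr(p >= 1) = 0, Pr(p >= 0) = 1
  b[p_star >= 1] <- 0
  b[p_star <= 0] <- 1
  b
}

#' Credible lower bound on true mastery
#'
#' The posterior `a`-quantile `q`, so that with probability `1 - a` the
#' student's true mastery exceeds `q` ("there is a 95% chance that the true
#' mastery is at least q" for the default `a = 0.05`).
#'
#' @param post a [mastery_posterior()] object.
#' @param a tail level in `(0, 1)`; default `0.05`.
#' @return mastery value in `[0, 1]`.
#' @examples
#' lower_credible_bound(mastery_posterior(10, 8), 0.05)  # ~0.5475
#' @export
lower_credible_bound <- function(post, a = 0.05) {
  stopifnot(inherits(post, "mastery_posterior"))
  if (length(a) != 1L || !is.finite(a) || a <= 0 || a >= 1) {
    stop("tail level `a` must lie strictly inside (0, 1)", call. = FALSE)
  }
  stats::qbeta(a, post$alpha, post$beta)
}

#' @export
mean.mastery_posterior <- function(x, ...) {
  x$alpha / (x$alpha + x$beta)
}

#' @export
quantile.mastery_posterior <- function(x, probs = c(0.05, 0.5, 0.95), ...) {
  stats::qbeta(probs, x$alpha, x$beta)
}

#' Posterior density on an even grid
#'
#' Evaluates the posterior density of true mastery on an evenly spaced grid
#' over `[0, 1]`, for plotting and for overlay comparisons of criteria.
#' When a shape parameter is below 1 the density is unbounded at the
#' corresponding endpoint; evaluation is clipped to `[eps, 1 - eps]` with
#' `eps = 1e-9` so the grid stays finite.
#'
#' @param x a [mastery_posterior()] object.
#' @param npoints number of grid points, at least 2; default 1025.
#' @param ... unused.
#' @return a data frame with columns `mastery` and `density`.
#' @export
density.mastery_posterior <- function(x, npoints = 1025L, ...) {
  if (length(npoints) != 1L || !is.finite(npoints) || npoints < 2) {
    stop("`npoints` must be a single integer >= 2", call. = FALSE)
  }
  eps <- 1e-9
  grid <- seq(0, 1, length.out = npoints)
  at <- pmin(pmax(grid, eps), 1 - eps)
  data.frame(mastery = grid, density = stats::dbeta(at, x$alpha, x$beta))
}

#' @export
plot.mastery_posterior <- function(x, npoints = 1025L, ...) {
  d <- density.mastery_posterior(x, npoints)
  plot(d$mastery, d$density, type = "l",
       xlab = "true mastery level p", ylab = "posterior density",
       main = sprintf("Posterior of true mastery (%d of %d correct)",
                      x$x, x$n), ...)
  invisible(d)
}

#' Expected proportion correct in future trials
#'
#' The posterior-predictive expected proportion of correct responses over
#' `m` future trials. For the beta-binomial model this equals the posterior
#' mean, independent of `m`; `m` is echoed for reporting. It quantifies the
#' gap between an observed criterion proportion and the performance to
#' expect at maintenance, before any genuine skill loss.
#'
#' @param object a [mastery_posterior()] object.
#' @param m number of future trials, `>= 1`; default 1.
#' @param ... unused.
#' @return a list with elements `proportion` (the expected proportion) and
#'   `m`.
#' @examples
#' predict(mastery_posterior(10, 9), m = 10)$proportion  # ~0.864 -> "86%"
#' @export
predict.mastery_posterior <- function(object, m = 1L, ...) {
  if (length(m) != 1L || !is.finite(m) || m < 1 || m != round(m)) {
    stop("`m` must be a single integer >= 1", call. = FALSE)
  }
  list(proportion = mean(object), m = as.integer(m))
}

#' @export
print.mastery_posterior <- function(x, ...) {
  cat(sprintf("True-mastery posterior: Beta(%g, %g)\n", x$alpha, x$beta))
  cat(sprintf("  from %d correct of %d trials, Beta(%g, %g) prior [%s]\n",
              x$x, x$n, x$prior$alpha, x$prior$beta, x$prior$name))
  cat(sprintf("  posterior mean %.4f\n", mean(x)))
  invisible(x)
}

#' Summarise confidence in mastery for observed counts
#'
#' Bundles the three quantities of a criterion report for one set of
#' observed counts: the probability `b` that true mastery is at least
#' `p_star`, the `(1 - a)` credible lower bound, and the posterior mean.
#'
#' @inheritParams mastery_posterior
#' @param p_star desired true-mastery threshold in `[0, 1]`; default 0.90.
#' @param a tail level in `(0, 1)`; default 0.05.
#' @return an object of class `mastery_summary`: a list with elements `b`,
#'   `lower_bound`, `mean`, `p_star`, `a`, `n`, `x`.
#' @examples
#' mastery_summary(10, 8, p_star = 0.90, a = 0.05)
#' @export
mastery_summary <- function(n, x, p_star = 0.9, a = 0.05,
                            prior = mastery_prior()) {
  post <- mastery_posterior(n, x, prior)
  structure(
    list(b = mastery_prob(post, p_star),
         lower_bound = lower_credible_bound(post, a),
         mean = mean(post),
         p_star = p_star, a = a, n = post$n, x = post$x),
    class = "mastery_summary"
  )
}

#' @export
print.mastery_summary <- function(x, ...) {
  cat(sprintf("%d of %d correct:\n", x$x, x$n))
  cat(sprintf("  Pr(true mastery >= %s%%) = %s\n",
              fmt_pct(x$p_star), fmt_prob(x$b)))
  cat(sprintf("  %s%% credible lower bound = %s%%\n",
              fmt_pct(1 - x$a), fmt_pct(x$lower_bound)))
  cat(sprintf("  posterior mean = %s%%\n", fmt_pct(x$mean)))
  invisible(x)
}

#' @export
summary.mastery_posterior <- function(object, p_star = 0.9, a = 0.05, ...) {
  mastery_summary(object$n, object$x, p_star = p_star, a = a,
                  prior = object$prior)
}

#' Criterion table for a fixed number of trials
#'
#' For each attainable correct count `x = 0, ..., n` computes the criterion
#' proportion `tau = x / n`, the probability `b` that true mastery is at
#' least `p_star`, the `(1 - a)` credible lower bound and the posterior
#' mean — one row per candidate performance criterion, as in the reference
#' tables for `p_star = 0.90` and `p_star = 0.70`.
#'
#' @inheritParams mastery_summary
#' @return a data frame of class `criterion_table` with columns `x`, `tau`,
#'   `b`, `lower_bound`, `mean`, and attributes `n`, `p_star`, `a`, `prior`.
#' @examples
#' criterion_table(10, p_star = 0.90)
#' @export
criterion_table <- function(n, p_star = 0.9, a = 0.05,
                            prior = mastery_prior()) {
  prior <- mastery_prior(prior)
  check_counts(n, 0)
  xs <- 0:n
  rows <- lapply(xs, function(x) {
    s <- mastery_summary(n, x, p_star = p_star, a = a, prior = prior)
    data.frame(x = x, tau = x / n, b = s$b,
               lower_bound = s$lower_bound, mean = s$mean)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("criterion_table", "data.frame"),
            n = as.integer(n), p_star = p_star, a = a, prior = prior)
}

#' @export
print.criterion_table <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Criterion table: n = %d trials, p* = %s%%, tail level a = %g\n",
    attr(x, "n"), fmt_pct(attr(x, "p_star")), attr(x, "a")))
  print.data.frame(x, digits = digits, row.names = FALSE, ...)
  invisible(x)
}
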