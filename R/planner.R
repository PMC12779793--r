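#' Smallest number of trials achieving a target confidence
#'
#' Scans upward over the number of trials `n`, requiring the student to get
#' `x = ceiling(tau * n)` correct (the criterion is a floor: a fractional
#' trial cannot be partially correct), and returns the smallest `n` at
#' which the probability that true mastery is at least `p_star` reaches
#' `b_target`. A linear scan is used because the confidence at
#' `ceiling(tau * n)` is not monotone in `n` for `tau < 1` (the ceiling
#' creates a sawtooth).
#'
#' @param p_star desired true-mastery threshold, strictly in `(0, 1)`.
#' @param b_target target confidence, strictly in `(0, 1)`.
#' @param tau performance criterion proportion in `(0, 1]`; default 1
#'   (a 100% criterion).
#' @param prior a [mastery_prior()]; default Jeffreys.
#' @param max_n search bound; the scan stops here and reports no solution.
#' @return an object of class `miebl_plan`: a list with `solved` (logical),
#'   `n`, `x`, `achieved_b`, and the query echoed. If no `n <= max_n`
#'   works, `solved` is `FALSE` and `n`, `x`, `achieved_b` are `NA`.
#' @examples
#' min_trials_for_confidence(p_star = 0.90, b_target = 0.70)  # n = 5
#' @export
min_trials_for_confidence <- function(p_star, b_target, tau = 1,
                                      prior = mastery_prior(),
                                      max_n = 10000L) {
  check_open_unit(p_star, "p_star")
  check_open_unit(b_target, "b_target")
  if (length(tau) != 1L || !is.finite(tau) || tau <= 0 || tau > 1) {
    stop("`tau` must lie in (0, 1]", call. = FALSE)
  }
  prior <- mastery_prior(prior)
  for (n in seq_len(max_n)) {
    x <- ceiling(tau * n)
    b <- mastery_prob(mastery_posterior(n, x, prior), p_star)
    if (b >= b_target) {
      return(new_plan(TRUE, n, x, b, p_star, b_target, tau, max_n))
    }
  }
  new_plan(FALSE, NA_integer_, NA_integer_, NA_real_,
           p_star, b_target, tau, max_n)
}

#' Smallest correct count achieving a target confidence
#'
#' For a fixed number of trials `n`, finds the smallest correct count `x`
#' whose posterior confidence that true mastery is at least `p_star`
#' reaches `b_target`. Confidence is strictly increasing in `x`, so the
#' first hit in an upward scan is the answer.
#'
#' @inheritParams min_trials_for_confidence
#' @param n fixed number of trials, `>= 1`.
#' @return an object of class `miebl_plan` (see
#'   [min_trials_for_confidence()]); `solved = FALSE` with `NA` fields when
#'   even `x = n` falls short.
#' @examples
#' min_correct_for_confidence(n = 10, p_star = 0.70, b_target = 0.90)  # x = 9
#' @export
min_correct_for_confidence <- function(n, p_star, b_target,
                                       prior = mastery_prior()) {
  check_counts(n, 0)
  check_open_unit(p_star, "p_star")
  if (length(b_target) != 1L || !is.finite(b_target) ||
      b_target <= 0 || b_target > 1) {
    stop("`b_target` must lie in (0, 1]", call. = FALSE)
  }
  prior <- mastery_prior(prior)
  for (x in 0:n) {
    b <- mastery_prob(mastery_posterior(n, x, prior), p_star)
    if (b >= b_target) {
      return(new_plan(TRUE, n, x, b, p_star, b_target, x / n, n,
                      mode = "min_x"))
    }
  }
  new_plan(FALSE, n, NA_integer_, NA_real_, p_star, b_target, NA_real_, n,
           mode = "min_x")
}

check_open_unit <- function(v, name) {
  if (length(v) != 1L || !is.finite(v) || v <= 0 || v >= 1) {
    stop("`", name, "` must lie strictly inside (0, 1)", call. = FALSE)
  }
  invisible(TRUE)
}

new_plan <- function(solved, n, x, b, p_star, b_target, tau, bound,
                     mode = "min_n") {
  structure(
    list(solved = solved, n = if (is.na(n)) n else as.integer(n),
         x = if (is.na(x)) x else as.integer(x), achieved_b = b,
         query = list(mode = mode, p_star = p_star, b_target = b_target,
                      tau = tau, bound = as.integer(bound))),
    class = "miebl_plan"
  )
}

#' @export
print.miebl_plan <- function(x, ...) {
  q <- x$query
  if (!x$solved) {
    cat(sprintf(
      "No design within the search bound reaches Pr(p >= %s) >= %g\n",
      fmt_prob(q$p_star), q$b_target))
    return(invisible(x))
  }
  if (q$mode == "min_n") {
    cat(sprintf(
      "Smallest design: n = %d trials, criterion %s%% (x = %d correct)\n",
      x$n, fmt_pct(q$tau), x$x))
  } else {
    cat(sprintf("Smallest criterion at n = %d: x = %d correct (%s%%)\n",
                x$n, x$x, fmt_pct(x$x / x$n)))
  }
  cat(sprintf("  achieved Pr(true mastery >= %s%%) = %s\n",
              fmt_pct(q$p_star), fmt_prob(x$achieved_b)))
  invisible(x)
}
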