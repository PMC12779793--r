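#' Monte Carlo operating characteristics of a performance criterion
#'
#' Simulates the population interpretation of the posterior statements:
#' students' true mastery levels `p` are drawn from a Beta population
#' distribution (by default the same Jeffreys prior used for inference, so
#' the simulation is the exact frequentist mirror of the Bayesian model),
#' each student is assessed with `n` binomial trials, and students meeting
#' the criterion (`X == x_criterion` correct, or `X >= x_criterion` under
#' `conditioning = "at_least"`) are retained. Among the retained students
#' the function reports the fraction whose true mastery falls short of
#' `p_star` — the misclassification rate of the criterion — and their mean
#' true mastery.
#'
#' As the number of replicates grows, under exact conditioning the
#' misclassified fraction converges to `1 - mastery_prob(...)` and the mean
#' retained mastery to the posterior mean.
#'
#' @param n number of assessment trials per simulated student.
#' @param x_criterion required correct count.
#' @param p_star desired true-mastery threshold in `[0, 1]`.
#' @param prior a [mastery_prior()]: the population distribution of true
#'   mastery; default Jeffreys.
#' @param reps number of simulated students, `>= 1`; default 200000.
#' @param seed integer seed; the simulation is bit-reproducible given the
#'   seed and leaves the caller's random state untouched.
#' @param conditioning `"exact"` (retain `X == x_criterion`, the default,
#'   matching the model) or `"at_least"` (retain `X >= x_criterion`).
#' @param keep_draws if `TRUE`, attach a per-replicate data frame
#'   (`p`, `X`, `met`) for audit.
#' @return an object of class `criterion_simulation`: a list with
#'   `n_meeting`, `misclassified_frac`, `mean_true_p`, `mc_se` (binomial
#'   standard error of the misclassified fraction), and `config`. With zero
#'   retained replicates the fractions are `NA` and `degenerate = TRUE`.
#' @examples
#' sim <- simulate_criterion(5, 5, p_star = 0.90, reps = 20000, seed = 1)
#' sim$misclassified_frac   # near 1 - 0.7075
#' @export
simulate_criterion <- function(n, x_criterion, p_star,
                               prior = mastery_prior(), reps = 200000L,
                               seed = NULL,
                               conditioning = c("exact", "at_least"),
                               keep_draws = FALSE) {
  check_counts(n, x_criterion)
  if (length(p_star) != 1L || !is.finite(p_star) || p_star < 0 || p_star > 1) {
    stop("`p_star` must lie in [0, 1]", call. = FALSE)
  }
  if (length(reps) != 1L || !is.finite(reps) || reps < 1) {
    stop("`reps` must be a positive integer", call. = FALSE)
  }
  conditioning <- match.arg(conditioning)
  prior <- mastery_prior(prior)

  draws <- with_local_seed(seed, {
    p <- stats::rbeta(reps, prior$alpha, prior$beta)
    X <- stats::rbinom(reps, size = n, prob = p)
    list(p = p, X = X)
  })
  met <- if (conditioning == "exact") draws$X == x_criterion
         else draws$X >= x_criterion
  n_meeting <- sum(met)
  config <- list(n = as.integer(n), x_criterion = as.integer(x_criterion),
                 p_star = p_star, prior = prior, reps = as.integer(reps),
                 seed = seed, conditioning = conditioning)
  if (n_meeting == 0L) {
    out <- list(n_meeting = 0L, misclassified_frac = NA_real_,
                mean_true_p = NA_real_, mc_se = NA_real_,
                degenerate = TRUE, config = config)
  } else {
    p_met <- draws$p[met]
    f <- mean(p_met < p_star)
    out <- list(n_meeting = n_meeting, misclassified_frac = f,
                mean_true_p = mean(p_met),
                mc_se = sqrt(f * (1 - f) / n_meeting),
                degenerate = FALSE, config = config)
  }
  if (keep_draws) {
    out$draws <- data.frame(replicate = seq_len(reps), p = draws$p,
                            X = draws$X, met_criterion = met)
  }
  structure(out, class = "criterion_simulation")
}

# Run code under a private RNG stream: set the seed if given, and restore
# the caller's .Random.seed afterwards either way.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  if (!is.null(seed)) set.seed(seed)
  force(expr)
}

#' @export
print.criterion_simulation <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Criterion simulation: %d reps, criterion %d of %d (%s), p* = %s%%\n",
    cfg$reps, cfg$x_criterion, cfg$n, cfg$conditioning, fmt_pct(cfg$p_star)))
  if (isTRUE(x$degenerate)) {
    cat("  no replicate met the criterion; fractions undefined\n")
    return(invisible(x))
  }
  cat(sprintf("  %d replicates met the criterion\n", x$n_meeting))
  cat(sprintf("  misclassified fraction (true p < p*): %.4f (SE %.4f)\n",
              x$misclassified_frac, x$mc_se))
  cat(sprintf("  mean true mastery among meeters: %.4f\n", x$mean_true_p))
  invisible(x)
}

#' Expected maintenance proportion after meeting a criterion
#'
#' The expected proportion of correct responses over `m` future trials for
#' a student observed at `x` of `n` correct: the posterior-predictive mean
#' proportion, which for this model equals the posterior mean and does not
#' depend on `m`. The gap between the observed criterion proportion `x/n`
#' and this value is the selection bias that inflates apparent skill loss
#' at maintenance.
#'
#' @inheritParams mastery_posterior
#' @param m number of future (maintenance) trials, `>= 1`.
#' @return a list with `proportion` and `m`.
#' @examples
#' expected_maintenance_proportion(10, 9, m = 10)$proportion  # ~0.8636
#' @export
expected_maintenance_proportion <- function(n, x, prior = mastery_prior(),
                                            m = 1L) {
  predict(mastery_posterior(n, x, prior), m = m)
}
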