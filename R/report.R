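#' Five-statement report for one performance criterion
#'
#' Builds the practitioner-facing report for a performance criterion `mc`
#' (an integer percent, e.g. `mc = 80` for "8 out of 10 items") from a
#' [criterion_table()]. The report restates, at display rounding, the
#' probability that true mastery is at least the table's `p_star`, the
#' credible lower bound at the table's tail level, and the posterior mean —
#' all taken from the table row whose correct count `x` equals
#' `mc / 100 * n`. A criterion that does not correspond to a whole number
#' of trials (e.g. 85% of 10 trials) is rejected, with the attainable
#' criteria listed.
#'
#' @param table a [criterion_table()].
#' @param mc performance criterion: an integer percent in `[0, 100]`, or a
#'   fraction in `[0, 1]` (values `<= 1` are read as fractions).
#' @return an object of class `criterion_report`: a list with fields `n`,
#'   `mc`, `x`, `p_star`, `a`, `b`, `lower_bound`, `mean`, `statements`
#'   (the five display strings) and `density` (a posterior density grid).
#' @examples
#' tab <- criterion_table(10, p_star = 0.90, a = 0.05)
#' rep <- criterion_report(tab, mc = 80)
#' cat(rep$statements, sep = "\n")
#' @export
criterion_report <- function(table, mc) {
  stopifnot(inherits(table, "criterion_table"))
  if (length(mc) != 1L || !is.finite(mc) || mc < 0 || mc > 100) {
    stop("`mc` must be a single value in [0, 100]", call. = FALSE)
  }
  if (mc <= 1) mc <- 100 * mc  # fractions are accepted; > 1 means percent
  n <- attr(table, "n")
  x_exact <- mc / 100 * n
  if (abs(x_exact - round(x_exact)) > 1e-9) {
    attainable <- paste0(round(100 * (0:n) / n, 2), "%", collapse = ", ")
    stop(sprintf(
      "a %g%% criterion is not attainable with n = %d trials (%g items); attainable criteria: %s",
      mc, n, x_exact, attainable), call. = FALSE)
  }
  x <- as.integer(round(x_exact))
  row <- table[table$x == x, ]
  p_star <- attr(table, "p_star")
  a <- attr(table, "a")
  post <- mastery_posterior(n, x, attr(table, "prior"))
  statements <- c(
    sprintf("Performance criterion of %s%% (%d out of %d items)",
            fmt_pct(mc / 100), x, n),
    "If the student meets this criterion, then:",
    sprintf("The probability that the true mastery is at least %s%% is %s.",
            fmt_pct(p_star), fmt_prob(row$b)),
    sprintf("There is a %s%% chance that the true mastery is at least %s%%.",
            fmt_pct(1 - a), fmt_pct(row$lower_bound)),
    sprintf("The average mastery of comparable students reaching this criterion is %s%%.",
            fmt_pct(row$mean))
  )
  structure(
    list(n = n, mc = mc, x = x, p_star = p_star, a = a,
         b = row$b, lower_bound = row$lower_bound, mean = row$mean,
         statements = statements,
         density = density.mastery_posterior(post, 1025L)),
    class = "criterion_report"
  )
}

#' Render a criterion report as text
#'
#' @param x a [criterion_report()].
#' @param ... unused.
#' @return the five statements joined by newlines, invisibly from `print`.
#' @export
format.criterion_report <- function(x, ...) {
  paste(x$statements, collapse = "\n")
}

#' @export
print.criterion_report <- function(x, ...) {
  cat(format(x), "\n", sep = "")
  invisible(x)
}

#' JSON rendering of a criterion report
#'
#' Carries the unrounded quantities for programmatic use; rounding is
#' applied only in the text statements.
#'
#' @param report a [criterion_report()].
#' @return a JSON string.
#' @export
report_json <- function(report) {
  stopifnot(inherits(report, "criterion_report"))
  jsonlite::toJSON(
    list(n = report$n, mc = report$mc, x = report$x,
         p_star = report$p_star, a = report$a, b = report$b,
         lower_bound = report$lower_bound, mean = report$mean,
         statements = report$statements),
    auto_unbox = TRUE, digits = NA)
}

#' Compare posterior mastery distributions across criteria
#'
#' Overlays the posterior densities of 2 to 5 criterion reports sharing the
#' same number of trials, for plots comparing e.g. 100%, 90% and 80%
#' criteria on 10 trials.
#'
#' @param ... between 2 and 5 [criterion_report()] objects (or a single
#'   list of them).
#' @return an object of class `criterion_comparison`: a list with the
#'   input `reports` and `overlay`, a long-format data frame with columns
#'   `label`, `mastery`, `density`.
#' @examples
#' tab <- criterion_table(10, p_star = 0.90)
#' cmp <- compare_criteria(criterion_report(tab, 100),
#'                         criterion_report(tab, 90),
#'                         criterion_report(tab, 80))
#' head(cmp$overlay)
#' @export
compare_criteria <- function(...) {
  reports <- list(...)
  if (length(reports) == 1L && !inherits(reports[[1L]], "criterion_report")) {
    reports <- reports[[1L]]
  }
  if (!all(vapply(reports, inherits, logical(1), "criterion_report"))) {
    stop("all arguments must be criterion_report objects", call. = FALSE)
  }
  k <- length(reports)
  if (k < 2L || k > 5L) {
    stop("between 2 and 5 reports are required (got ", k, ")", call. = FALSE)
  }
  ns <- vapply(reports, function(r) r$n, numeric(1))
  if (length(unique(ns)) != 1L) {
    stop("all reports must share the same number of trials n ",
         "(got n = ", paste(ns, collapse = ", "), ")", call. = FALSE)
  }
  overlay <- do.call(rbind, lapply(reports, function(r) {
    data.frame(label = sprintf("%s%% (%d/%d)", fmt_pct(r$mc / 100), r$x, r$n),
               mastery = r$density$mastery, density = r$density$density)
  }))
  structure(list(reports = reports, overlay = overlay),
            class = "criterion_comparison")
}

#' @export
print.criterion_comparison <- function(x, ...) {
  cat(sprintf("Comparison of %d performance criteria at n = %d trials:\n",
              length(x$reports), x$reports[[1L]]$n))
  for (r in x$reports) cat("  ", r$statements[[1L]], "\n", sep = "")
  invisible(x)
}

#' @export
plot.criterion_comparison <- function(x, ...) {
  labs <- unique(x$overlay$label)
  cols <- seq_along(labs)
  ymax <- max(x$overlay$density)
  plot(NULL, xlim = c(0, 1), ylim = c(0, ymax),
       xlab = "true mastery level p", ylab = "posterior density",
       main = "Posterior mastery by performance criterion", ...)
  for (i in seq_along(labs)) {
    d <- x$overlay[x$overlay$label == labs[[i]], ]
    graphics::lines(d$mastery, d$density, col = cols[[i]])
  }
  graphics::legend("topleft", legend = labs, col = cols, lty = 1, bty = "n")
  invisible(x)
}
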