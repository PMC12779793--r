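#' Prior specification for the latent mastery level
#'
#' The latent true mastery level \eqn{p} of a student over a skill component
#' space is given a Beta prior. The default is the Jeffreys prior
#' Beta(1/2, 1/2), under which the posterior summaries reproduce the
#' reference criterion tables and tutorial reports; the uniform Beta(1, 1)
#' prior and arbitrary Beta shapes are also supported.
#'
#' @param prior either a name (`"jeffreys"` or `"uniform"`) or a numeric
#'   vector of two strictly positive shape parameters `c(alpha, beta)`.
#' @return an object of class `mastery_prior`: a list with elements
#'   `alpha`, `beta` and `name`.
#' @examples
#' mastery_prior()                 # Jeffreys Beta(0.5, 0.5)
#' mastery_prior("uniform")        # Beta(1, 1)
#' mastery_prior(c(2, 2))          # custom
#' @export
mastery_prior <- function(prior = "jeffreys") {
  if (inherits(prior, "mastery_prior")) return(prior)
  if (is.character(prior)) {
    prior <- match.arg(prior, c("jeffreys", "uniform"))
    shapes <- switch(prior, jeffreys = c(0.5, 0.5), uniform = c(1, 1))
    name <- prior
  } else if (is.numeric(prior) && length(prior) == 2L) {
    shapes <- as.numeric(prior)
    name <- "custom"
  } else {
    stop("`prior` must be \"jeffreys\", \"uniform\", or a numeric vector ",
         "of two positive shape parameters", call. = FALSE)
  }
  if (!all(is.finite(shapes)) || any(shapes <= 0)) {
    stop("prior shape parameters must be strictly positive and finite",
         call. = FALSE)
  }
  structure(list(alpha = shapes[[1L]], beta = shapes[[2L]], name = name),
            class = "mastery_prior")
}

#' @export
print.mastery_prior <- function(x, ...) {
  cat(sprintf("Beta(%g, %g) prior on true mastery [%s]\n",
              x$alpha, x$beta, x$name))
  invisible(x)
}
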