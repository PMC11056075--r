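#' Heterogeneity prior for the between-study standard deviation
#'
#' The between-study heterogeneity SD tau of the normal-normal hierarchical
#' model gets a half-normal or half-Cauchy prior, i.e. the positive half of
#' the corresponding symmetric density, rescaled to integrate to one on
#' `[0, Inf)`.  The default scale of 0.5 is weakly informative for binary
#' log effects: it puts 58% (half-normal) or 43% (half-Cauchy) of the prior
#' mass below tau = 0.4, the upper end of small-to-moderate heterogeneity.
#'
#' @param family `"half-normal"` or `"half-cauchy"`.
#' @param scale positive scale parameter.
#' @return An object of class `het_prior`.
#' @examples
#' p <- het_prior("half-cauchy", 0.5)
#' phet(p, 0.4)  # prior P(tau < 0.4)
#' @export
het_prior <- function(family = c("half-normal", "half-cauchy"), scale = 0.5) {
  family <- match.arg(family)
  if (!is.finite(scale) || scale <= 0) stop("'scale' must be > 0")
  structure(list(family = family, scale = scale), class = "het_prior")
}

#' @export
print.het_prior <- function(x, ...) {
  cat(sprintf("%s heterogeneity prior, scale %g\n", x$family, x$scale))
  invisible(x)
}

#' Heterogeneity prior density, distribution and quantile functions
#'
#' @param prior a [het_prior()].
#' @param tau non-negative evaluation point(s); negative values are an error.
#' @param p probabilities in `[0, 1]`.
#' @return `dhet` the density, `phet` the CDF, `qhet` the quantile function.
#' @export
dhet <- function(prior, tau) {
  stopifnot(inherits(prior, "het_prior"))
  if (any(tau < 0)) stop("'tau' must be non-negative")
  switch(prior$family,
         "half-normal" = 2 * stats::dnorm(tau, 0, prior$scale),
         "half-cauchy" = 2 * stats::dcauchy(tau, 0, prior$scale))
}

#' @rdname dhet
#' @export
phet <- function(prior, tau) {
  stopifnot(inherits(prior, "het_prior"))
  if (any(tau < 0)) stop("'tau' must be non-negative")
  switch(prior$family,
         "half-normal" = 2 * stats::pnorm(tau, 0, prior$scale) - 1,
         "half-cauchy" = (2 / pi) * atan(tau / prior$scale))
}

#' @rdname dhet
#' @export
qhet <- function(prior, p) {
  stopifnot(inherits(prior, "het_prior"), all(p >= 0 & p <= 1))
  switch(prior$family,
         "half-normal" = stats::qnorm((1 + p) / 2, 0, prior$scale),
         "half-cauchy" = prior$scale * tan(pi * p / 2))
}

#' Normal prior for the pooled log effect
#'
#' Prior on the pooled effect mu, on the natural-log (log-OR / log-RR)
#' scale.  The default N(0, 2) is vague on the ratio scale: it places 95%
#' prior mass on ratios between roughly 1/50 and 50.
#'
#' @param mean prior mean (log scale).
#' @param sd positive prior standard deviation.
#' @return An object of class `effect_prior`.
#' @export
effect_prior <- function(mean = 0, sd = 2) {
  if (!is.finite(mean)) stop("'mean' must be finite")
  if (!is.finite(sd) || sd <= 0) stop("'sd' must be > 0")
  structure(list(mean = mean, sd = sd), class = "effect_prior")
}

#' @export
print.effect_prior <- function(x, ...) {
  cat(sprintf("normal effect prior, mean %g, sd %g (log scale)\n", x$mean, x$sd))
  invisible(x)
}
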