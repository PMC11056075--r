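#' Frequentist pooled estimation of a meta-analysis
#'
#' Fits one of three frequentist pooled models to study-level log effects:
#'
#' * `"DSL"` — DerSimonian-Laird random effects: the moment estimator of the
#'   heterogeneity variance tau^2 with inverse-variance random-effects
#'   weights and a normal-quantile 95% CI.
#' * `"HKSJ"` — the Hartung-Knapp-Sidik-Jonkman variance correction applied
#'   to the DSL estimator: the same pooled estimate, but the CI uses the
#'   weighted dispersion of the studies around it and a t quantile with
#'   k - 1 degrees of freedom.
#' * `"IVhet"` — the inverse-variance heterogeneity model of Doi and
#'   colleagues: fixed-effect (inverse-variance) weights for the point
#'   estimate, with the variance inflated by the DSL tau^2, so the CI widens
#'   under heterogeneity without re-weighting the studies.
#'
#' @param data a [meta_dataset()], or a data.frame with columns `y` and `se`.
#' @param estimator one of `"DSL"`, `"HKSJ"`, `"IVhet"`.
#' @param level confidence level (default 0.95).
#' @return An object of class `freq_fit` with components `estimator`,
#'   `mu_hat`, `se_mu`, `ci_low`, `ci_high`, `tau2`, `Q`, `I2`, `df`, `k`,
#'   `excludes_null` (whether the ratio-scale CI excludes 1) and `unstable`
#'   (`TRUE` for HKSJ with a single degree of freedom, whose t interval is
#'   valid but enormous).
#' @examples
#' d <- meta_dataset(data.frame(study_id = letters[1:3],
#'                              design = c("RCT", "NRS", "NRS"),
#'                              y = c(0, 0.8, 1.6), se = 0.2), "OR")
#' freq_fit(d, "DSL")
#' @seealso [dsl_fit()], [hksj_fit()], [ivhet_fit()] for direct wrappers.
#' @export
freq_fit <- function(data, estimator = c("DSL", "HKSJ", "IVhet"),
                     level = 0.95) {
  estimator <- match.arg(estimator)
  ys <- get_effects(data)
  y <- ys$y; se <- ys$se; k <- length(y)
  if (k < 1) stop("empty dataset")
  alpha <- 1 - level

  w <- 1 / se^2
  mu_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - mu_fe)^2)
  tau2 <- if (k == 1) 0 else
    max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  I2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) else 0

  wstar <- 1 / (se^2 + tau2)
  mu_re <- sum(wstar * y) / sum(wstar)
  unstable <- FALSE

  if (estimator == "DSL") {
    mu <- mu_re
    se_mu <- 1 / sqrt(sum(wstar))
    df <- Inf
    half <- stats::qnorm(1 - alpha / 2) * se_mu
  } else if (estimator == "HKSJ") {
    if (k < 2)
      stop("HKSJ requires at least 2 studies")
    mu <- mu_re
    v <- sum(wstar * (y - mu)^2) / ((k - 1) * sum(wstar))
    se_mu <- sqrt(v)
    df <- k - 1
    half <- stats::qt(1 - alpha / 2, df = df) * se_mu
    unstable <- df == 1
  } else { # IVhet
    what <- w / sum(w)
    mu <- sum(what * y)
    se_mu <- sqrt(sum(what^2 * (se^2 + tau2)))
    df <- Inf
    half <- stats::qnorm(1 - alpha / 2) * se_mu
  }
  ci <- c(mu - half, mu + half)
  structure(list(estimator = estimator, mu_hat = mu, se_mu = se_mu,
                 ci_low = ci[1], ci_high = ci[2], tau2 = tau2, Q = Q, I2 = I2,
                 df = df, k = k, level = level,
                 excludes_null = ci[1] > 0 || ci[2] < 0,
                 unstable = unstable,
                 metric = if (inherits(data, "meta_dataset")) data$metric else NA_character_,
                 label = if (inherits(data, "meta_dataset")) data$label else ""),
            class = "freq_fit")
}

#' @rdname freq_fit
#' @param ... passed on to [freq_fit()].
#' @export
dsl_fit <- function(data, ...) freq_fit(data, "DSL", ...)

#' @rdname freq_fit
#' @export
hksj_fit <- function(data, ...) freq_fit(data, "HKSJ", ...)

#' @rdname freq_fit
#' @export
ivhet_fit <- function(data, ...) freq_fit(data, "IVhet", ...)

get_effects <- function(data) {
  if (inherits(data, "meta_dataset")) data$studies
  else if (is.data.frame(data) && all(c("y", "se") %in% names(data))) data
  else stop("'data' must be a meta_dataset or a data.frame with y and se")
}

#' @export
print.freq_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s pooled estimate (k = %d)\n", x$estimator, x$k))
  cat(sprintf("  mu = %.*f  [%.*f, %.*f]  (log scale, %g%% CI)\n",
              digits, x$mu_hat, digits, x$ci_low, digits, x$ci_high,
              100 * x$level))
  if (!is.na(x$metric))
    cat(sprintf("  %s = %.*f  [%.*f, %.*f]\n", x$metric,
                digits, exp(x$mu_hat), digits, exp(x$ci_low),
                digits, exp(x$ci_high)))
  cat(sprintf("  tau^2 = %.*f, Q = %.*f, I^2 = %.1f%%, df = %s\n",
              digits, x$tau2, digits, x$Q, 100 * x$I2, format(x$df)))
  cat(sprintf("  CI excludes null: %s%s\n", x$excludes_null,
              if (x$unstable) "  (df = 1: interval unstable)" else ""))
  invisible(x)
}

#' @export
coef.freq_fit <- function(object, ...) c(mu = object$mu_hat)

#' @export
confint.freq_fit <- function(object, parm = "mu", level = NULL, ...) {
  if (!is.null(level) && level != object$level)
    stop("refit with the desired 'level'; stored level is ", object$level)
  matrix(c(object$ci_low, object$ci_high), nrow = 1,
         dimnames = list("mu", c("low", "high")))
}

#' @export
summary.freq_fit <- function(object, ...) object

#' Flatten a frequentist fit to a one-row data frame
#'
#' Includes the exponentiated estimate and CI in the dataset's metric, for
#' CSV/JSON serialization.
#'
#' @param x a `freq_fit`.
#' @param ... unused.
#' @export
as.data.frame.freq_fit <- function(x, ...) {
  data.frame(label = x$label, estimator = x$estimator, k = x$k,
             mu_hat = x$mu_hat, se_mu = x$se_mu,
             ci_low = x$ci_low, ci_high = x$ci_high,
             tau2 = x$tau2, Q = x$Q, I2 = x$I2, df = x$df,
             excludes_null = x$excludes_null,
             metric = x$metric, exp_est = exp(x$mu_hat),
             exp_low = exp(x$ci_low), exp_high = exp(x$ci_high),
             stringsAsFactors = FALSE)
}
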