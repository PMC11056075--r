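#' Bayesian normal-normal hierarchical meta-analysis
#'
#' Fits the normal-normal hierarchical model (NNHM)
#' \deqn{y_i \mid \theta_i \sim N(\theta_i, \sigma_i^2), \quad
#'       \theta_i \sim N(\mu, \tau^2)}
#' with a normal prior on the pooled effect mu and a half-normal or
#' half-Cauchy prior on the heterogeneity SD tau, by deterministic numerical
#' integration — no MCMC.  Conditional on tau the model is conjugate, so the
#' only numerical integral is one-dimensional over tau; it is computed by
#' adaptive quadrature after the substitution `u = tau / (tau + s)` (s the
#' prior scale), which maps `[0, Inf)` to `[0, 1)`.  All likelihood
#' computations are carried in log space.
#'
#' The fit stores the log marginal likelihood `log p(y | M)` (the
#' normalizing constant used by Bayes factors), the discretized posterior of
#' tau on a grid, and the marginal posterior of mu, which is an exact finite
#' mixture of normals (one conjugate component per tau grid point).  The
#' credible interval is the shortest interval with `level` posterior mass;
#' for the unimodal posteriors that arise here it equals the highest
#' posterior density interval.
#'
#' @param data a [meta_dataset()] or data.frame with columns `y` and `se`.
#'   A single study is allowed: the prior then dominates.
#' @param het_prior a [het_prior()]; default half-normal with scale 0.5.
#' @param effect_prior an [effect_prior()]; default N(0, 2) on the log scale.
#' @param level credible level, default 0.95.
#' @param control a [nnhm_control()] list.
#' @return An object of class `nnhm`: a list with `log_marglik`, `tau_grid`
#'   (data.frame of tau support points and posterior weights), `mixture`
#'   (the mu posterior), `mu_median`, `mu_mean`, `cri_low`, `cri_high`,
#'   `tau_median`, `excludes_null`, and `diagnostics` (quadrature relative
#'   error and a convergence flag; non-convergent quadrature is reported
#'   here rather than silently accepted).
#' @examples
#' d <- meta_dataset(data.frame(study_id = c("a", "b", "c"),
#'                              design = c("RCT", "NRS", "NRS"),
#'                              y = c(-0.4, -0.2, -0.7), se = c(0.2, 0.25, 0.3)),
#'                   metric = "OR", label = "toy")
#' fit <- nnhm(d, het_prior("half-cauchy", 0.5))
#' fit
#' @export
nnhm <- function(data, het_prior = bfmeta::het_prior(),
                 effect_prior = bfmeta::effect_prior(),
                 level = 0.95, control = nnhm_control()) {
  stopifnot(inherits(het_prior, "het_prior"),
            inherits(effect_prior, "effect_prior"))
  ys <- get_effects(data)
  y <- ys$y; se <- ys$se; k <- length(y)
  if (k < 1) stop("empty dataset")
  if (any(se <= 0)) stop("all standard errors must be > 0")

  ml <- nnhm_marglik(y, se, het_prior, effect_prior, control)

  fit <- list(log_marglik = ml$log_ml, k = k, level = level,
              het_prior = het_prior, effect_prior = effect_prior,
              diagnostics = ml$diagnostics,
              metric = if (inherits(data, "meta_dataset")) data$metric else NA_character_,
              label = if (inherits(data, "meta_dataset")) data$label else "")

  if (control$summaries) {
    g <- nnhm_posterior_grid(y, se, het_prior, effect_prior, control)
    fit$tau_grid <- g$tau_grid
    fit$tau_median <- g$tau_median
    fit$mixture <- g$mixture
    fit$mu_mean <- mix_mean(g$mixture)
    fit$mu_median <- qmix(g$mixture, 0.5)
    cri <- shortest_interval(g$mixture, level = level)
    fit$cri_low <- cri[1]; fit$cri_high <- cri[2]
    fit$multimodal <- isTRUE(attr(cri, "multimodal"))
    fit$excludes_null <- cri[1] > 0 || cri[2] < 0
  }
  structure(fit, class = "nnhm")
}

#' Control parameters for the NNHM quadrature
#'
#' @param grid_size number of tau support points retained for the posterior
#'   (default 401; at least 201).
#' @param rel_tol relative tolerance passed to the adaptive quadrature.
#' @param summaries if `FALSE`, only the log marginal likelihood is computed
#'   (used internally by the Bayes-factor machinery, which needs nothing
#'   else and is called many times in simulations).
#' @return A list of class `nnhm_control`.
#' @export
nnhm_control <- function(grid_size = 401, rel_tol = 1e-10, summaries = TRUE) {
  stopifnot(grid_size >= 201)
  structure(list(grid_size = as.integer(grid_size), rel_tol = rel_tol,
                 summaries = isTRUE(summaries)), class = "nnhm_control")
}

## log p(y | tau): after integrating mu analytically, y | tau is
## multivariate normal with mean m0 * 1 and covariance
## diag(se^2 + tau^2) + s0^2 * J.  The rank-one structure gives the
## determinant and quadratic form without any matrix inversion.
nnhm_loglik_tau <- function(y, se, effect_prior) {
  m0 <- effect_prior$mean; s02 <- effect_prior$sd^2
  k <- length(y); r <- y - m0
  function(tau) {
    vapply(tau, function(t) {
      d <- se^2 + t^2
      S1 <- sum(1 / d)
      logdet <- sum(log(d)) + log1p(s02 * S1)
      quad <- sum(r^2 / d) - s02 * sum(r / d)^2 / (1 + s02 * S1)
      -0.5 * (k * log(2 * pi) + logdet + quad)
    }, numeric(1))
  }
}

## log integrand on the u scale, u = tau / (tau + s)
nnhm_log_integrand <- function(y, se, het_prior, effect_prior) {
  loglik <- nnhm_loglik_tau(y, se, effect_prior)
  s <- het_prior$scale
  function(u) {
    tau <- s * u / (1 - u)
    out <- rep(-Inf, length(u))
    ok <- u < 1
    out[ok] <- loglik(tau[ok]) + log(dhet(het_prior, tau[ok])) +
      log(s) - 2 * log1p(-u[ok])
    out
  }
}

nnhm_marglik <- function(y, se, het_prior, effect_prior, control = nnhm_control()) {
  logf <- nnhm_log_integrand(y, se, het_prior, effect_prior)
  probe <- logf(seq(0, 1 - 1e-9, length.out = 201))
  C <- max(probe)
  int <- stats::integrate(function(u) exp(logf(u) - C), 0, 1,
                          rel.tol = control$rel_tol, abs.tol = 0,
                          stop.on.error = FALSE)
  converged <- int$message == "OK" && int$value > 0 &&
    int$abs.error <= 1e-6 * int$value
  if (!converged)
    warning("NNHM quadrature did not converge to tolerance (", int$message,
            "); marginal likelihood flagged", call. = FALSE)
  list(log_ml = C + log(int$value),
       diagnostics = list(converged = converged,
                          rel_error = int$abs.error / max(int$value, .Machine$double.xmin),
                          message = int$message))
}

nnhm_posterior_grid <- function(y, se, het_prior, effect_prior,
                                control = nnhm_control()) {
  n <- control$grid_size
  s <- het_prior$scale
  u <- (seq_len(n) - 0.5) / n          # cell midpoints on (0, 1)
  tau <- s * u / (1 - u)
  logf <- nnhm_log_integrand(y, se, het_prior, effect_prior)
  lw <- logf(u)
  w <- exp(lw - max(lw))
  w <- w / sum(w)

  ## conjugate conditional posterior of mu at each tau
  m0 <- effect_prior$mean; s02 <- effect_prior$sd^2
  cond <- vapply(tau, function(t) {
    wi <- 1 / (se^2 + t^2)
    P <- sum(wi) + 1 / s02
    c((sum(wi * y) + m0 / s02) / P, 1 / sqrt(P))
  }, numeric(2))

  cdf <- cumsum(w)
  tau_median <- stats::approx(cdf, tau, xout = 0.5, ties = "ordered")$y
  if (is.na(tau_median)) tau_median <- tau[which.max(cdf >= 0.5)]

  list(tau_grid = data.frame(tau = tau, weight = w),
       tau_median = tau_median,
       mixture = mix_norm(w, cond[1, ], cond[2, ]))
}

#' Conditional posterior of the pooled effect given tau
#'
#' For fixed heterogeneity tau the NNHM is conjugate: the posterior of mu is
#' exactly normal with precision equal to the sum of the random-effects
#' precisions `1 / (se_i^2 + tau^2)` plus the prior precision.
#'
#' @inheritParams nnhm
#' @param tau fixed non-negative heterogeneity SD.
#' @return A list with the posterior `mean` and `sd` of mu given tau.
#' @export
conditional_mu_posterior <- function(data, effect_prior = bfmeta::effect_prior(),
                                     tau = 0) {
  stopifnot(tau >= 0, inherits(effect_prior, "effect_prior"))
  ys <- get_effects(data)
  wi <- 1 / (ys$se^2 + tau^2)
  P <- sum(wi) + 1 / effect_prior$sd^2
  list(mean = (sum(wi * ys$y) + effect_prior$mean / effect_prior$sd^2) / P,
       sd = 1 / sqrt(P))
}

#' Log-likelihood of the data given tau, with mu integrated out
#'
#' `log p(y | tau)` under the NNHM with the normal effect prior: a
#' multivariate normal density with compound-symmetric covariance, computed
#' stably through its diagonal-plus-rank-one structure.
#'
#' @inheritParams conditional_mu_posterior
#' @param tau non-negative heterogeneity SD (vectorized).
#' @return Numeric vector of log densities.
#' @export
likelihood_given_tau <- function(data, effect_prior = bfmeta::effect_prior(),
                                 tau = 0) {
  stopifnot(all(tau >= 0), inherits(effect_prior, "effect_prior"))
  ys <- get_effects(data)
  nnhm_loglik_tau(ys$y, ys$se, effect_prior)(tau)
}

#' Posterior density, CDF and quantiles of the pooled effect
#'
#' Evaluate the marginal posterior of mu from a fitted [nnhm()] (or the
#' model-averaged posterior from [model_average()]).
#'
#' @param fit an `nnhm` or `bma` object.
#' @param x evaluation points on the log-effect scale.
#' @param p probabilities.
#' @export
mu_density <- function(fit, x) dmix(posterior_mixture(fit), x)

#' @rdname mu_density
#' @export
mu_cdf <- function(fit, x) pmix(posterior_mixture(fit), x)

#' @rdname mu_density
#' @export
mu_quantile <- function(fit, p) qmix(posterior_mixture(fit), p)

posterior_mixture <- function(fit) {
  if (is.null(fit$mixture))
    stop("fit carries no posterior summaries (refit with summaries = TRUE)")
  fit$mixture
}

#' @export
print.nnhm <- function(x, digits = 4, ...) {
  cat(sprintf("NNHM fit (k = %d), %s heterogeneity prior (scale %g)\n",
              x$k, x$het_prior$family, x$het_prior$scale))
  cat(sprintf("  log marginal likelihood: %.*f\n", digits, x$log_marglik))
  if (!is.null(x$mixture)) {
    cat(sprintf("  mu (posterior median) = %.*f, shortest %g%% CrI [%.*f, %.*f]\n",
                digits, x$mu_median, 100 * x$level,
                digits, x$cri_low, digits, x$cri_high))
    if (!is.na(x$metric))
      cat(sprintf("  %s = %.*f  [%.*f, %.*f]\n", x$metric,
                  digits, exp(x$mu_median), digits, exp(x$cri_low),
                  digits, exp(x$cri_high)))
    cat(sprintf("  tau (posterior median) = %.*f\n", digits, x$tau_median))
    cat(sprintf("  CrI excludes null: %s\n", x$excludes_null))
  }
  if (!x$diagnostics$converged)
    cat("  WARNING: quadrature flagged as non-convergent\n")
  invisible(x)
}

#' @export
coef.nnhm <- function(object, ...)
  c(mu = object$mu_median, tau = object$tau_median)

#' @export
summary.nnhm <- function(object, ...) object

#' Flatten an NNHM fit for serialization
#'
#' @param x an `nnhm` fit.
#' @param ... unused.
#' @export
as.data.frame.nnhm <- function(x, ...) {
  data.frame(label = x$label, k = x$k,
             het_family = x$het_prior$family, het_scale = x$het_prior$scale,
             log_marglik = x$log_marglik,
             mu_median = x$mu_median %||% NA_real_,
             mu_mean = x$mu_mean %||% NA_real_,
             cri_low = x$cri_low %||% NA_real_,
             cri_high = x$cri_high %||% NA_real_,
             tau_median = x$tau_median %||% NA_real_,
             excludes_null = x$excludes_null %||% NA,
             converged = x$diagnostics$converged,
             metric = x$metric,
             exp_est = exp(x$mu_median %||% NA_real_),
             exp_low = exp(x$cri_low %||% NA_real_),
             exp_high = exp(x$cri_high %||% NA_real_),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
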