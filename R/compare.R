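#' Bayes-factor comparison of pooled versus design-separate models
#'
#' Compares two accounts of a meta-analysis that mixes randomized trials
#' (RCT) and non-randomized studies (NRS):
#'
#' * *pooled* — one NNHM over all studies, common `(mu, tau)`;
#' * *separate* — independent NNHMs for the RCT and the NRS subgroups, with
#'   identical priors; its marginal likelihood is the product of the two
#'   subgroup marginal likelihoods.
#'
#' The Bayes factor of pooled versus separate is the ratio of the marginal
#' likelihoods; the decision rule accepts the pooled model for BF > 3, the
#' separate model for BF < 1/3, and is indeterminate in between (boundary
#' values inclusive).  Posterior model probabilities follow from the
#' posterior odds with the stated prior model probability.
#'
#' @param data a [meta_dataset()] containing at least one RCT and one NRS.
#' @param het_prior a [het_prior()] shared by all three fits.
#' @param effect_prior an [effect_prior()] shared by all three fits.
#' @param prior_prob prior probability of the pooled model (default 0.5).
#' @param control a [nnhm_control()]; posterior summaries are not needed for
#'   the comparison and are switched off internally.
#' @return An object of class `design_comparison` with components
#'   `log_ml_joint`, `log_ml_rct`, `log_ml_nrs`, `bf_pooled`, `bf_separate`
#'   (the exact reciprocal), `pp_pooled` and `decision` (one of `"POOLED"`,
#'   `"SEPARATE"`, `"INDETERMINATE"`).
#' @examples
#' cfg <- synth_config(n_meta = 1, seed = 42)
#' compare_models(generate_meta(cfg, 1), het_prior("half-cauchy"))
#' @export
compare_models <- function(data, het_prior = bfmeta::het_prior(),
                           effect_prior = bfmeta::effect_prior(),
                           prior_prob = 0.5, control = nnhm_control()) {
  stopifnot(inherits(data, "meta_dataset"))
  counts <- design_counts(data)
  if (counts["k_rct"] < 1 || counts["k_nrs"] < 1)
    stop("model comparison requires at least one RCT and one NRS study")
  ctl <- control; ctl$summaries <- FALSE
  lml <- function(d) nnhm(d, het_prior, effect_prior, control = ctl)$log_marglik
  log_ml_joint <- lml(data)
  log_ml_rct <- lml(subset_design(data, "RCT"))
  log_ml_nrs <- lml(subset_design(data, "NRS"))
  new_comparison(log_ml_joint, log_ml_rct, log_ml_nrs, prior_prob,
                 label = data$label, counts = counts)
}

new_comparison <- function(log_ml_joint, log_ml_rct, log_ml_nrs, prior_prob,
                           label = "", counts = NULL) {
  log_bf <- log_ml_joint - (log_ml_rct + log_ml_nrs)
  bf <- exp(log_bf)
  structure(list(log_ml_joint = log_ml_joint, log_ml_rct = log_ml_rct,
                 log_ml_nrs = log_ml_nrs,
                 bf_pooled = bf, bf_separate = exp(-log_bf),
                 pp_pooled = posterior_model_probability(bf, prior_prob),
                 prior_prob = prior_prob,
                 decision = bf_decision(bf),
                 label = label, counts = counts),
            class = "design_comparison")
}

#' Decision rule on a Bayes factor
#'
#' `"POOLED"` for BF > 3, `"SEPARATE"` for BF < 1/3, `"INDETERMINATE"`
#' otherwise (both boundaries resolve to indeterminate).
#'
#' @param bf positive Bayes factor(s) of the pooled vs separate model.
#' @return Character vector of decisions; `NA` propagates.
#' @export
bf_decision <- function(bf) {
  out <- rep(NA_character_, length(bf))
  out[!is.na(bf) & bf > 3] <- "POOLED"
  out[!is.na(bf) & bf < 1 / 3] <- "SEPARATE"
  out[!is.na(bf) & bf >= 1 / 3 & bf <= 3] <- "INDETERMINATE"
  out
}

#' Posterior model probability from a Bayes factor
#'
#' Posterior odds are the Bayes factor times the prior odds; the posterior
#' probability is `odds / (odds + 1)`.  With prior probability 0.5 this
#' reduces to `bf / (bf + 1)`.
#'
#' @param bf positive Bayes factor(s).
#' @param prior_prob prior probability of the first model, in (0, 1).
#' @return Posterior probability in (0, 1).
#' @examples
#' posterior_model_probability(8.176)   # 0.891
#' posterior_model_probability(10.957)  # 0.916
#' @export
posterior_model_probability <- function(bf, prior_prob = 0.5) {
  if (any(!is.na(bf) & bf <= 0)) stop("'bf' must be positive")
  stopifnot(prior_prob > 0, prior_prob < 1)
  odds <- bf * prior_prob / (1 - prior_prob)
  odds / (odds + 1)
}

#' @export
print.design_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("Pooled vs separate model comparison%s\n",
              if (nzchar(x$label)) paste0(" — ", x$label) else ""))
  if (!is.null(x$counts))
    cat(sprintf("  studies: %d (%d RCT, %d NRS)\n",
                x$counts["k"], x$counts["k_rct"], x$counts["k_nrs"]))
  cat(sprintf("  BF (pooled) = %.*f, BF (separate) = %.*f\n",
              digits, x$bf_pooled, digits, x$bf_separate))
  cat(sprintf("  posterior probability of pooling = %.*f (prior %.2f)\n",
              digits, x$pp_pooled, x$prior_prob))
  cat(sprintf("  decision: %s\n", x$decision))
  invisible(x)
}

#' Model-averaged posterior of the reported effect
#'
#' The reported posterior is a weighted mixture of the conditional
#' posteriors under the two data models, weighted by their posterior model
#' probabilities: sharing of NRS information is strong when the designs
#' agree (the pooled model dominates) and fades when they conflict.  Under
#' the separate model there is no single pooled effect; by default the
#' RCT-subgroup posterior stands in for it, on the view that the randomized
#' estimate is the inferential target and NRS are co-data whose influence
#' should vanish under conflict.  `separate_target` makes the alternative
#' choices available.
#'
#' @inheritParams compare_models
#' @param level credible level for the shortest interval.
#' @param separate_target which posterior represents the separate model:
#'   `"rct"` (default), `"nrs"`, or `"mixture"` (equal-weight mixture of
#'   both subgroup posteriors).
#' @return An object of class `bma`: weights, the mixture posterior of the
#'   reported effect, its shortest credible interval, the posterior median
#'   `point`, and the underlying `comparison`.
#' @export
model_average <- function(data, het_prior = bfmeta::het_prior(),
                          effect_prior = bfmeta::effect_prior(),
                          prior_prob = 0.5, level = 0.95,
                          separate_target = c("rct", "nrs", "mixture"),
                          control = nnhm_control()) {
  separate_target <- match.arg(separate_target)
  fits <- fit_design_models(data, het_prior, effect_prior, level, control)
  build_bma(fits, prior_prob, level, separate_target)
}

## fit joint + both subgroup models once; shared by model_average and
## run_both_priors so nothing is fitted twice
fit_design_models <- function(data, het_prior, effect_prior, level, control) {
  counts <- design_counts(data)
  if (counts["k_rct"] < 1 || counts["k_nrs"] < 1)
    stop("model averaging requires at least one RCT and one NRS study")
  list(joint = nnhm(data, het_prior, effect_prior, level, control),
       rct = nnhm(subset_design(data, "RCT"), het_prior, effect_prior, level, control),
       nrs = nnhm(subset_design(data, "NRS"), het_prior, effect_prior, level, control),
       label = data$label, counts = counts)
}

build_bma <- function(fits, prior_prob, level, separate_target) {
  cmp <- new_comparison(fits$joint$log_marglik, fits$rct$log_marglik,
                        fits$nrs$log_marglik, prior_prob,
                        label = fits$label, counts = fits$counts)
  sep_mix <- switch(separate_target,
                    rct = fits$rct$mixture,
                    nrs = fits$nrs$mixture,
                    mixture = mix_combine(fits$rct$mixture, fits$nrs$mixture, 0.5))
  mixture <- mix_combine(fits$joint$mixture, sep_mix, cmp$pp_pooled)
  cri <- shortest_interval(mixture, level = level)
  converged <- fits$joint$diagnostics$converged &&
    fits$rct$diagnostics$converged && fits$nrs$diagnostics$converged
  structure(list(weights = c(pooled = cmp$pp_pooled,
                             separate = 1 - cmp$pp_pooled),
                 mixture = mixture, point = qmix(mixture, 0.5),
                 cri_low = cri[1], cri_high = cri[2], level = level,
                 excludes_null = cri[1] > 0 || cri[2] < 0,
                 separate_target = separate_target,
                 comparison = cmp, converged = converged,
                 label = fits$label),
            class = "bma")
}

#' @export
print.bma <- function(x, digits = 4, ...) {
  cat(sprintf("Model-averaged posterior%s\n",
              if (nzchar(x$label)) paste0(" — ", x$label) else ""))
  cat(sprintf("  weights: pooled %.3f, separate %.3f (separate target: %s)\n",
              x$weights["pooled"], x$weights["separate"], x$separate_target))
  cat(sprintf("  effect (median) = %.*f, shortest %g%% CrI [%.*f, %.*f]\n",
              digits, x$point, 100 * x$level, digits, x$cri_low,
              digits, x$cri_high))
  cat(sprintf("  CrI excludes null: %s\n", x$excludes_null))
  if (!x$converged) cat("  WARNING: a component fit was flagged non-convergent\n")
  invisible(x)
}

#' @export
coef.bma <- function(object, ...) c(mu = object$point)

#' Full Bayesian analysis under both heterogeneity prior families
#'
#' Runs the NNHM fit, pooled-vs-separate comparison and model average twice,
#' identically except for the heterogeneity prior family (half-normal and
#' half-Cauchy, same scale).  Failures are captured per prior, since
#' computability can differ between the two families.
#'
#' @inheritParams model_average
#' @param scale shared scale of the two heterogeneity priors (default 0.5).
#' @return A list of class `both_priors` with elements `half_normal` and
#'   `half_cauchy`, each either a list `(fit, comparison, bma)` or a
#'   captured error condition.
#' @export
run_both_priors <- function(data, scale = 0.5,
                            effect_prior = bfmeta::effect_prior(),
                            prior_prob = 0.5, level = 0.95,
                            separate_target = c("rct", "nrs", "mixture"),
                            control = nnhm_control()) {
  separate_target <- match.arg(separate_target)
  one <- function(family) {
    tryCatch({
      fits <- fit_design_models(data, het_prior(family, scale), effect_prior,
                                level, control)
      list(fit = fits$joint,
           comparison = new_comparison(fits$joint$log_marglik,
                                       fits$rct$log_marglik,
                                       fits$nrs$log_marglik, prior_prob,
                                       label = fits$label, counts = fits$counts),
           bma = build_bma(fits, prior_prob, level, separate_target))
    }, error = function(e) e)
  }
  structure(list(half_normal = one("half-normal"),
                 half_cauchy = one("half-cauchy"),
                 label = data$label),
            class = "both_priors")
}

#' @export
print.both_priors <- function(x, ...) {
  for (nm in c("half_normal", "half_cauchy")) {
    cat("==", gsub("_", "-", nm), "prior ==\n")
    if (inherits(x[[nm]], "condition"))
      cat("  failed:", conditionMessage(x[[nm]]), "\n")
    else print(x[[nm]]$comparison)
  }
  invisible(x)
}
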