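#' Classify agreement between a frequentist CI and a Bayesian CrI
#'
#' "Statistical significance" is operationalized as the interval excluding
#' the null ratio (OR/RR = 1, i.e. 0 on the log scale); no p-values enter
#' on the Bayesian side.
#'
#' @param freq_excludes_null,bayes_excludes_null logicals (vectorized).
#' @return Character vector with levels `"BOTH_EXCLUDE"`, `"FREQ_ONLY"`,
#'   `"BAYES_ONLY"`, `"NEITHER"`.
#' @export
agreement_category <- function(freq_excludes_null, bayes_excludes_null) {
  stopifnot(length(freq_excludes_null) == length(bayes_excludes_null))
  ifelse(is.na(freq_excludes_null) | is.na(bayes_excludes_null), NA_character_,
    ifelse(freq_excludes_null & bayes_excludes_null, "BOTH_EXCLUDE",
      ifelse(freq_excludes_null, "FREQ_ONLY",
        ifelse(bayes_excludes_null, "BAYES_ONLY", "NEITHER"))))
}

agreement_levels <- c("BOTH_EXCLUDE", "FREQ_ONLY", "BAYES_ONLY", "NEITHER")

#' Run the full analysis pipeline over a cohort of meta-analyses
#'
#' For every dataset: the three frequentist fits (DSL, HKSJ, IVhet), the
#' Bayesian NNHM under both heterogeneity prior families, the
#' pooled-vs-separate Bayes-factor comparison, the model-averaged posterior,
#' and the CI-vs-CrI agreement classification (DSL CI against the
#' model-averaged CrI, per prior family).  Per-dataset failures are caught,
#' reported in the summary, and excluded from denominators.
#'
#' @param datasets a list of [meta_dataset()] objects (e.g. from
#'   [generate_cohort()] or a directory of CSVs read with
#'   [read_meta_csv()]).
#' @param scale heterogeneity prior scale used for both families.
#' @param effect_prior an [effect_prior()].
#' @param prior_prob prior probability of the pooled model.
#' @param level interval level.
#' @param separate_target passed to [model_average()].
#' @param control a [nnhm_control()].
#' @return An object of class `cohort_report`: `per_dataset` (one row per
#'   successfully fitted dataset), `summary` (agreement-category and
#'   BF-decision counts per prior family, and the median/IQR of the DSL
#'   tau across the cohort), `n_failed`, and `failures` (messages).
#' @export
run_cohort <- function(datasets, scale = 0.5,
                       effect_prior = bfmeta::effect_prior(),
                       prior_prob = 0.5, level = 0.95,
                       separate_target = c("rct", "nrs", "mixture"),
                       control = nnhm_control()) {
  stopifnot(length(datasets) >= 1)
  separate_target <- match.arg(separate_target)
  rows <- list(); failures <- character(0)
  for (d in datasets) {
    row <- tryCatch(
      analyse_one(d, scale, effect_prior, prior_prob, level,
                  separate_target, control),
      error = function(e) e)
    if (inherits(row, "condition")) {
      failures <- c(failures,
                    sprintf("%s: %s", d$label, conditionMessage(row)))
    } else rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) stop("no dataset could be fitted")
  per <- do.call(rbind, rows)
  rownames(per) <- NULL

  count_cat <- function(x) {
    tab <- table(factor(x, levels = agreement_levels))
    as.integer(tab)
  }
  summ <- list(
    n_fitted = nrow(per), n_failed = length(failures),
    agreement_hn = stats::setNames(count_cat(per$agreement_hn), agreement_levels),
    agreement_hc = stats::setNames(count_cat(per$agreement_hc), agreement_levels),
    decisions_hn = table(factor(per$decision_hn,
                                levels = c("POOLED", "SEPARATE", "INDETERMINATE"))),
    decisions_hc = table(factor(per$decision_hc,
                                levels = c("POOLED", "SEPARATE", "INDETERMINATE"))),
    tau_dsl_median = stats::median(per$tau_dsl),
    tau_dsl_iqr = stats::quantile(per$tau_dsl, c(0.25, 0.75), names = FALSE))
  structure(list(per_dataset = per, summary = summ,
                 n_failed = length(failures), failures = failures),
            class = "cohort_report")
}

analyse_one <- function(d, scale, effect_prior, prior_prob, level,
                        separate_target, control) {
  counts <- design_counts(d)
  if (counts[["k_rct"]] < 1 || counts[["k_nrs"]] < 1)
    stop("pipeline requires at least one RCT and one NRS study")
  dsl <- dsl_fit(d, level = level)
  hksj <- tryCatch(hksj_fit(d, level = level), error = function(e) NULL)
  ivh <- ivhet_fit(d, level = level)
  both <- run_both_priors(d, scale = scale, effect_prior = effect_prior,
                          prior_prob = prior_prob, level = level,
                          separate_target = separate_target, control = control)
  one_prior <- function(res) {
    if (inherits(res, "condition"))
      return(data.frame(mu = NA_real_, cri_low = NA_real_, cri_high = NA_real_,
                        excl = NA, bf = NA_real_, pp = NA_real_,
                        decision = NA_character_, stringsAsFactors = FALSE))
    data.frame(mu = res$bma$point, cri_low = res$bma$cri_low,
               cri_high = res$bma$cri_high, excl = res$bma$excludes_null,
               bf = res$comparison$bf_pooled, pp = res$comparison$pp_pooled,
               decision = res$comparison$decision, stringsAsFactors = FALSE)
  }
  hn <- one_prior(both$half_normal); hc <- one_prior(both$half_cauchy)
  data.frame(label = d$label, metric = d$metric,
             k = counts[["k"]], k_rct = counts[["k_rct"]], k_nrs = counts[["k_nrs"]],
             mu_dsl = dsl$mu_hat, ci_low_dsl = dsl$ci_low,
             ci_high_dsl = dsl$ci_high, tau_dsl = sqrt(dsl$tau2),
             excl_dsl = dsl$excludes_null,
             excl_hksj = if (is.null(hksj)) NA else hksj$excludes_null,
             excl_ivhet = ivh$excludes_null,
             mu_hn = hn$mu, cri_low_hn = hn$cri_low, cri_high_hn = hn$cri_high,
             excl_hn = hn$excl, bf_hn = hn$bf, pp_hn = hn$pp,
             decision_hn = hn$decision,
             mu_hc = hc$mu, cri_low_hc = hc$cri_low, cri_high_hc = hc$cri_high,
             excl_hc = hc$excl, bf_hc = hc$bf, pp_hc = hc$pp,
             decision_hc = hc$decision,
             agreement_hn = agreement_category(dsl$excludes_null, hn$excl),
             agreement_hc = agreement_category(dsl$excludes_null, hc$excl),
             stringsAsFactors = FALSE)
}

#' @export
print.cohort_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Cohort report: %d fitted, %d failed\n", s$n_fitted, s$n_failed))
  cat("  DSL tau: median", round(s$tau_dsl_median, 3),
      " IQR", round(s$tau_dsl_iqr[1], 3), "-", round(s$tau_dsl_iqr[2], 3), "\n")
  cat("  agreement (half-normal): ",
      paste(agreement_levels, s$agreement_hn, sep = "=", collapse = " "), "\n")
  cat("  agreement (half-Cauchy): ",
      paste(agreement_levels, s$agreement_hc, sep = "=", collapse = " "), "\n")
  cat("  BF decisions (half-normal):",
      paste(names(s$decisions_hn), as.integer(s$decisions_hn),
            sep = "=", collapse = " "), "\n")
  cat("  BF decisions (half-Cauchy):",
      paste(names(s$decisions_hc), as.integer(s$decisions_hc),
            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Packaged transcription of the published model-preference table
#'
#' Fifty meta-analyses with, per heterogeneity prior family, the printed
#' pooled and separate Bayes factors and posterior model probabilities,
#' together with study counts (total, RCT, NRS) and the author metric.  One
#' row (Barakakis) has no computable Bayesian results and carries `NA`s.
#'
#' @return A data.frame of class `model_preference_fixture` with 50 rows.
#' @export
model_preference_fixture <- function() {
  path <- system.file("extdata", "model_preference.csv",
                      package = "bfmeta", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("model_preference_fixture", "data.frame")
  df
}

#' Summarize the packaged model-preference fixture
#'
#' Validates the fixture (50 rows; `k_total = k_rct + k_nrs` everywhere),
#' applies the Bayes-factor decision rule to each printed pooled BF,
#' computes cohort descriptors, and audits the printed values for internal
#' consistency: the posterior model probability must equal `bf / (bf + 1)`
#' and the separate BF must be the reciprocal of the pooled BF, both within
#' the propagation of 3-decimal rounding.
#'
#' @param fixture a [model_preference_fixture()] (default: the packaged one).
#' @return A list of class `fixture_summary`:
#'   `decisions` (counts of POOLED / SEPARATE / INDETERMINATE /
#'   incomputable per prior family), `descriptors` (median/quartiles/range
#'   of study counts, median RCT proportion), `pp_inconsistent` (data.frame
#'   of printed probability entries that fail the identity, expected to be
#'   empty or near-empty), and `reciprocity_ok` (logical).
#' @export
summarize_fixture <- function(fixture = model_preference_fixture()) {
  stopifnot(is.data.frame(fixture))
  need <- c("author", "k_total", "k_rct", "k_nrs", "metric",
            "bf_pooled_hn", "bf_separate_hn", "pp_hn",
            "bf_pooled_hc", "bf_separate_hc", "pp_hc")
  if (!all(need %in% names(fixture)))
    stop("fixture is missing columns: ",
         paste(setdiff(need, names(fixture)), collapse = ", "))
  if (any(fixture$k_total != fixture$k_rct + fixture$k_nrs))
    stop("fixture integrity failure: k_total != k_rct + k_nrs in row ",
         which(fixture$k_total != fixture$k_rct + fixture$k_nrs)[1])

  dec <- function(bf) {
    d <- bf_decision(bf)
    c(POOLED = sum(d == "POOLED", na.rm = TRUE),
      SEPARATE = sum(d == "SEPARATE", na.rm = TRUE),
      INDETERMINATE = sum(d == "INDETERMINATE", na.rm = TRUE),
      incomputable = sum(is.na(bf)))
  }

  ## identity pp = bf/(bf+1), allowing half-ulp rounding on both the printed
  ## 3-decimal bf (propagated through the derivative 1/(1+bf)^2) and pp
  pp_tol <- function(bf) 0.0005 + 0.00055 / (1 + bf)^2
  audit <- function(bf, pp, prior) {
    ok <- is.na(bf) | abs(pp - bf / (bf + 1)) <= pp_tol(bf)
    data.frame(author = fixture$author[!ok],
               prior = rep(prior, sum(!ok)),
               bf = bf[!ok], pp_printed = pp[!ok],
               pp_implied = bf[!ok] / (bf[!ok] + 1),
               stringsAsFactors = FALSE)
  }
  pp_bad <- rbind(audit(fixture$bf_pooled_hn, fixture$pp_hn, "half-normal"),
                  audit(fixture$bf_pooled_hc, fixture$pp_hc, "half-cauchy"))

  recip_ok <- function(bp, bs)
    all(is.na(bp) | abs(bp * bs - 1) <= 0.00055 * (bp + bs))

  p_rct <- fixture$k_rct / fixture$k_total
  structure(list(
    decisions = list(half_normal = dec(fixture$bf_pooled_hn),
                     half_cauchy = dec(fixture$bf_pooled_hc)),
    descriptors = list(
      n = nrow(fixture),
      k_median = stats::median(fixture$k_total),
      k_range = range(fixture$k_total),
      k_quartiles = stats::quantile(fixture$k_total, c(0.25, 0.75), names = FALSE),
      rct_prop_median = stats::median(p_rct),
      rct_prop_range = range(p_rct)),
    pp_inconsistent = pp_bad,
    reciprocity_ok = recip_ok(fixture$bf_pooled_hn, fixture$bf_separate_hn) &&
      recip_ok(fixture$bf_pooled_hc, fixture$bf_separate_hc)),
    class = "fixture_summary")
}

#' @export
print.fixture_summary <- function(x, ...) {
  cat("Model-preference fixture summary (n =", x$descriptors$n, ")\n")
  cat("  decisions, half-normal: ",
      paste(names(x$decisions$half_normal), x$decisions$half_normal,
            sep = "=", collapse = " "), "\n")
  cat("  decisions, half-Cauchy: ",
      paste(names(x$decisions$half_cauchy), x$decisions$half_cauchy,
            sep = "=", collapse = " "), "\n")
  d <- x$descriptors
  cat(sprintf("  study counts: median %g (range %d-%d, quartiles %g/%g)\n",
              d$k_median, d$k_range[1], d$k_range[2],
              d$k_quartiles[1], d$k_quartiles[2]))
  cat(sprintf("  RCT proportion: median %.2f (range %.2f-%.2f)\n",
              d$rct_prop_median, d$rct_prop_range[1], d$rct_prop_range[2]))
  cat(sprintf("  BF reciprocity within rounding: %s\n", x$reciprocity_ok))
  if (nrow(x$pp_inconsistent)) {
    cat("  printed posterior probabilities inconsistent with bf/(bf+1):\n")
    print(x$pp_inconsistent, row.names = FALSE)
  } else cat("  all printed posterior probabilities consistent with bf/(bf+1)\n")
  invisible(x)
}
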