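#' Configuration for synthetic RCT+NRS meta-analytic cohorts
#'
#' Defines the generating process for seeded synthetic cohorts with the
#' structure of published critical-care meta-analyses that combine
#' randomized trials and non-randomized studies: per-meta study counts with
#' median about 9 (range clamped to 2-60), RCT proportion about one third,
#' binary outcomes, and between-study heterogeneity SD 0.25 on the log
#' scale.  Study-level true effects are
#' `theta_i ~ N(mu_true + delta_nrs * [design == NRS], tau_true^2)`;
#' `delta_nrs` is an additive NRS bias on the log scale, zero by default.
#'
#' In `"BINOMIAL"` mode each study draws a control event probability and
#' per-arm sizes uniformly from the stated ranges, maps `theta_i` onto the
#' treatment probability through the metric's link (logit for OR, log for
#' RR), draws binomial events, and computes `(y, se)` from the 2x2 table.
#' In `"NORMAL"` mode `y_i ~ N(theta_i, sigma_i^2)` with `sigma_i` uniform
#' on `sigma_range`, bypassing the binomial layer.
#'
#' @param n_meta number of meta-analyses in a cohort.
#' @param k_rct,k_nrs fixed per-meta study counts, or `NULL` (default) to
#'   sample: total `k` is a rounded lognormal with median 9 (sdlog 0.65)
#'   clamped to `k_range`, and the RCT count is binomial with probability
#'   `rct_prob`, clamped so every dataset keeps at least one study of each
#'   design.
#' @param k_range admissible range of total study counts.
#' @param rct_prob expected RCT proportion (default 1/3).
#' @param mu_true true pooled log effect (default `log(0.7)`, a moderate
#'   protective effect typical of the cohort's interventions).
#' @param tau_true true heterogeneity SD (default 0.25).
#' @param delta_nrs additive NRS bias on the log scale (default 0).
#' @param arm_size_range range of subjects per arm (default 25-400).
#' @param p_ctrl_range range of control event probabilities (default
#'   0.05-0.40, mortality-like outcomes).
#' @param sigma_range range of study standard errors in `"NORMAL"` mode.
#' @param metric `"OR"` or `"RR"`.
#' @param mode `"BINOMIAL"` or `"NORMAL"`.
#' @param correction continuity correction used when converting tables.
#' @param seed master seed; each dataset derives a child seed from it and
#'   its index, so cohorts are reproducible and individually regenerable.
#' @return A list of class `synth_config`.
#' @examples
#' cfg <- synth_config(n_meta = 3, seed = 7)
#' generate_meta(cfg, 2)
#' @export
synth_config <- function(n_meta = 50, k_rct = NULL, k_nrs = NULL,
                         k_range = c(2, 60), rct_prob = 1 / 3,
                         mu_true = log(0.7), tau_true = 0.25, delta_nrs = 0,
                         arm_size_range = c(25, 400),
                         p_ctrl_range = c(0.05, 0.40),
                         sigma_range = c(0.10, 0.60),
                         metric = c("OR", "RR"),
                         mode = c("BINOMIAL", "NORMAL"),
                         correction = 0.5, seed = 1) {
  metric <- match.arg(metric); mode <- match.arg(mode)
  stopifnot(n_meta >= 1, tau_true >= 0, is.finite(mu_true),
            arm_size_range[1] >= 2, diff(arm_size_range) >= 0,
            p_ctrl_range[1] > 0, p_ctrl_range[2] < 1,
            rct_prob > 0, rct_prob < 1, seed == round(seed))
  if (!is.null(k_rct)) stopifnot(k_rct >= 1)
  if (!is.null(k_nrs)) stopifnot(k_nrs >= 1)
  structure(list(n_meta = as.integer(n_meta), k_rct = k_rct, k_nrs = k_nrs,
                 k_range = k_range, rct_prob = rct_prob, mu_true = mu_true,
                 tau_true = tau_true, delta_nrs = delta_nrs,
                 arm_size_range = arm_size_range, p_ctrl_range = p_ctrl_range,
                 sigma_range = sigma_range, metric = metric, mode = mode,
                 correction = correction, seed = as.integer(seed)),
            class = "synth_config")
}

## deterministic child seed per dataset, kept inside 32-bit integer range
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 104729) %% 2147483647)
}

#' Generate one synthetic meta-analysis dataset
#'
#' Fully reproducible from `config$seed` and `index`; the global RNG state
#' is restored on exit.  Parameter draws implying treatment probabilities
#' outside (0, 1) (possible in RR mode) and degenerate 2x2 tables are
#' rejection-resampled; the count of resamples is attached as the
#' `n_resampled` attribute.
#'
#' @param config a [synth_config()].
#' @param index dataset index within the cohort (1-based).
#' @return A [meta_dataset()] with label `"synth-<index>"`.
#' @export
generate_meta <- function(config, index = 1) {
  stopifnot(inherits(config, "synth_config"), index >= 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(child_seed(config$seed, index))

  if (!is.null(config$k_rct) && !is.null(config$k_nrs)) {
    k_rct <- config$k_rct; k_nrs <- config$k_nrs
  } else {
    k <- round(stats::rlnorm(1, log(9), 0.65))
    k <- min(max(k, config$k_range[1]), config$k_range[2])
    k_rct <- stats::rbinom(1, k, config$rct_prob)
    k_rct <- min(max(k_rct, 1L), k - 1L)
    k_nrs <- k - k_rct
  }
  design <- c(rep("RCT", k_rct), rep("NRS", k_nrs))
  n_resampled <- 0L

  draw_study <- function(des) {
    repeat {
      theta <- stats::rnorm(1, config$mu_true +
                              config$delta_nrs * (des == "NRS"),
                            config$tau_true)
      if (config$mode == "NORMAL") {
        sigma <- stats::runif(1, config$sigma_range[1], config$sigma_range[2])
        return(list(y = stats::rnorm(1, theta, sigma), se = sigma))
      }
      p_c <- stats::runif(1, config$p_ctrl_range[1], config$p_ctrl_range[2])
      p_t <- if (config$metric == "OR") stats::plogis(stats::qlogis(p_c) + theta)
             else exp(log(p_c) + theta)
      if (p_t <= 0 || p_t >= 1) { n_resampled <<- n_resampled + 1L; next }
      n1 <- sample(config$arm_size_range[1]:config$arm_size_range[2], 1)
      n2 <- sample(config$arm_size_range[1]:config$arm_size_range[2], 1)
      a <- stats::rbinom(1, n1, p_t)
      c0 <- stats::rbinom(1, n2, p_c)
      res <- tryCatch(
        effect_fun(config$metric)(a, n1, c0, n2, correction = config$correction),
        bfmeta_incomputable_study = function(e) NULL)
      if (is.null(res)) { n_resampled <<- n_resampled + 1L; next }
      return(list(y = res$y, se = res$se, counts = c(a, n1, c0, n2)))
    }
  }

  rows <- lapply(seq_along(design), function(i) {
    s <- draw_study(design[i])
    data.frame(study_id = sprintf("s%02d", i), design = design[i],
               y = s$y, se = s$se,
               events_treat = if (is.null(s$counts)) NA else s$counts[1],
               total_treat = if (is.null(s$counts)) NA else s$counts[2],
               events_ctrl = if (is.null(s$counts)) NA else s$counts[3],
               total_ctrl = if (is.null(s$counts)) NA else s$counts[4],
               stringsAsFactors = FALSE)
  })
  out <- meta_dataset(do.call(rbind, rows), metric = config$metric,
                      label = sprintf("synth-%d", index),
                      correction = config$correction)
  attr(out, "n_resampled") <- n_resampled
  out
}

#' Generate a cohort of synthetic meta-analyses
#'
#' @param config a [synth_config()].
#' @return A list of `n_meta` independent [meta_dataset()] objects; every
#'   dataset contains at least one RCT and one NRS.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  lapply(seq_len(config$n_meta), function(i) generate_meta(config, i))
}

#' Write a synthetic cohort to disk
#'
#' One CSV per dataset in the study-level schema of [write_meta_csv()], plus
#' a YAML manifest capturing the full generating configuration and seed.
#'
#' @param cohort a list of `meta_dataset` objects.
#' @param dir output directory (created if needed).
#' @param config the [synth_config()] that produced the cohort (recorded in
#'   the manifest).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort))
    write_meta_csv(cohort[[i]], file.path(dir, sprintf("meta_%03d.csv", i)),
                   sidecar = FALSE)
  manifest <- list(n_datasets = length(cohort),
                   metric = cohort[[1]]$metric,
                   config = if (is.null(config)) NULL else unclass(config))
  if (requireNamespace("yaml", quietly = TRUE))
    yaml::write_yaml(manifest, file.path(dir, "manifest.yml"))
  invisible(dir)
}
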