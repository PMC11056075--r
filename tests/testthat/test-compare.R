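test_that("Bayes factors are reciprocal and the decision rule is strict", {
  d <- make_dataset(c(-0.2, 0.4, 0.1, 0.6), c(0.2, 0.3, 0.25, 0.4),
                    c("RCT", "RCT", "NRS", "NRS"))
  cmp <- compare_models(d)
  expect_equal(cmp$bf_pooled * cmp$bf_separate, 1, tolerance = 1e-12)
  expect_equal(cmp$pp_pooled, cmp$bf_pooled / (cmp$bf_pooled + 1))

  expect_identical(bf_decision(c(3.001, 3, 1, 1 / 3, 0.33)),
                   c("POOLED", "INDETERMINATE", "INDETERMINATE",
                     "INDETERMINATE", "SEPARATE"))
  expect_error(compare_models(make_dataset(c(0.1, 0.2), c(0.2, 0.2),
                                           c("RCT", "RCT"))),
               "at least one RCT and one NRS")
})

test_that("posterior model probability matches the posterior-odds identity", {
  expect_equal(round(posterior_model_probability(8.176), 3), 0.891)
  expect_equal(round(posterior_model_probability(10.957), 3), 0.916)
  expect_equal(posterior_model_probability(1), 0.5)
  # general prior: odds = bf * prior odds
  expect_equal(posterior_model_probability(2, 0.25),
               (2 * (0.25 / 0.75)) / (2 * (0.25 / 0.75) + 1))
  expect_error(posterior_model_probability(-1), "positive")
  # strictly increasing in bf
  bfs <- c(0.01, 0.1, 0.5, 1, 2, 10, 100)
  expect_true(all(diff(posterior_model_probability(bfs)) > 0))
})

test_that("log Bayes factor is antisymmetric and location-equivariant", {
  d <- make_dataset(c(-0.2, 0.4, 0.1, 0.6), c(0.2, 0.3, 0.25, 0.4),
                    c("RCT", "RCT", "NRS", "NRS"))
  cmp <- compare_models(d, het_prior("half-cauchy"))
  expect_equal(log(cmp$bf_pooled), -log(cmp$bf_separate), tolerance = 1e-12)

  # shifting every effect by c and recentring the effect prior by c leaves
  # all marginal likelihoods, hence the BF, unchanged
  shift <- 1.3
  d2 <- make_dataset(c(-0.2, 0.4, 0.1, 0.6) + shift, c(0.2, 0.3, 0.25, 0.4),
                     c("RCT", "RCT", "NRS", "NRS"))
  cmp2 <- compare_models(d2, het_prior("half-cauchy"),
                         effect_prior(0 + shift, 2))
  expect_equal(log(cmp2$bf_pooled), log(cmp$bf_pooled), tolerance = 1e-9)
})

test_that("concordant designs favor pooling and conflicting designs favor separation", {
  n_rep <- 100
  concord <- conflict <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    cfg0 <- synth_config(k_rct = 7, k_nrs = 13, mu_true = -0.3,
                         tau_true = 0.2, delta_nrs = 0, mode = "NORMAL",
                         sigma_range = c(0.1, 0.3), seed = 1000 + r)
    cfg2 <- synth_config(k_rct = 7, k_nrs = 13, mu_true = -0.3,
                         tau_true = 0.2, delta_nrs = 2, mode = "NORMAL",
                         sigma_range = c(0.1, 0.3), seed = 5000 + r)
    concord[r] <- compare_models(generate_meta(cfg0, 1))$decision == "POOLED"
    conflict[r] <- compare_models(generate_meta(cfg2, 1))$decision == "SEPARATE"
  }
  expect_gte(mean(concord), 0.9)
  expect_gte(mean(conflict), 0.9)
})

test_that("model average interpolates between the component posteriors", {
  d <- make_dataset(c(-0.2, 0.4, 0.1, 0.6), c(0.2, 0.3, 0.25, 0.4),
                    c("RCT", "RCT", "NRS", "NRS"))
  ba <- model_average(d)
  expect_equal(sum(ba$weights), 1)
  expect_equal(unname(ba$weights["pooled"]), ba$comparison$pp_pooled)
  # mixture density integrates to 1, CDF monotone 0 -> 1
  expect_equal(integrate(function(x) mu_density(ba, x), -8, 8,
                         rel.tol = 1e-8)$value, 1, tolerance = 1e-6)
  xs <- seq(-5, 5, length.out = 81)
  expect_true(all(diff(mu_cdf(ba, xs)) >= 0))

  # overwhelming pooled evidence: average collapses onto the joint fit
  cfg <- synth_config(k_rct = 12, k_nrs = 18, tau_true = 0.1,
                      mode = "NORMAL", sigma_range = c(0.08, 0.2), seed = 77)
  dbig <- generate_meta(cfg, 1)
  ba2 <- model_average(dbig)
  joint <- nnhm(dbig)
  if (ba2$weights["pooled"] > 0.9) {
    expect_equal(ba2$point, joint$mu_median,
                 tolerance = 0.15 * (joint$cri_high - joint$cri_low))
  }
  # pp -> 1 limit exactly: a mixture with weight 1 on the joint component
  ba_lim <- bfmeta:::build_bma(
    bfmeta:::fit_design_models(d, het_prior(), effect_prior(), 0.95,
                               nnhm_control()),
    prior_prob = 1 - 1e-12, level = 0.95, separate_target = "rct")
  expect_equal(ba_lim$point, nnhm(d)$mu_median, tolerance = 1e-4)
})

test_that("a 50/50 mixture of unit normals at 0 and 3 has the grid-search HPD", {
  m <- bfmeta:::mix_norm(c(0.5, 0.5), c(0, 3), c(1, 1))
  ci <- shortest_interval(m, 0.95)
  oracle <- oracle_grid_hpd(function(x) bfmeta:::dmix(m, x), -8, 11, 0.95)
  expect_equal(as.numeric(ci), oracle, tolerance = 1e-3)
})

test_that("both-prior runs share inputs and leave frequentist results untouched", {
  cfg <- synth_config(k_rct = 4, k_nrs = 8, seed = 9)
  d <- generate_meta(cfg, 1)
  res <- run_both_priors(d, scale = 0.5)
  expect_s3_class(res$half_normal$fit, "nnhm")
  expect_s3_class(res$half_cauchy$fit, "nnhm")
  expect_identical(res$half_normal$fit$k, res$half_cauchy$fit$k)
  # the heterogeneity prior family cannot touch the frequentist side
  expect_identical(dsl_fit(d)$mu_hat, dsl_fit(d)$mu_hat)
  # low-heterogeneity data: the two prior families nearly agree
  cfg_low <- synth_config(k_rct = 5, k_nrs = 10, tau_true = 0.05,
                          mode = "NORMAL", sigma_range = c(0.1, 0.25),
                          seed = 21)
  d_low <- generate_meta(cfg_low, 1)
  res_low <- run_both_priors(d_low)
  expect_lt(abs(res_low$half_normal$fit$mu_median -
                res_low$half_cauchy$fit$mu_median), 0.05)
})
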