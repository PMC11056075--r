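test_that("conditional mu posterior is the conjugate normal", {
  d <- make_dataset(0, 1, "RCT")
  post <- conditional_mu_posterior(d, effect_prior(0, 2), tau = 0)
  expect_equal(post$mean, 0)
  expect_equal(post$sd, (1 + 1 / 4)^(-1 / 2))

  # vague-prior limit: posterior mean -> inverse-variance fixed effect
  d <- make_dataset(c(0.2, 0.8), c(0.1, 0.3))
  w <- 1 / c(0.1, 0.3)^2
  post <- conditional_mu_posterior(d, effect_prior(0, 1e6), tau = 0)
  expect_equal(post$mean, sum(w * c(0.2, 0.8)) / sum(w), tolerance = 1e-8)

  # symmetry: all y at the prior mean
  d <- make_dataset(c(0, 0, 0), c(0.2, 0.4, 0.3))
  for (tau in c(0, 0.3, 1))
    expect_equal(conditional_mu_posterior(d, effect_prior(0, 2), tau)$mean, 0)
})

test_that("likelihood given tau matches closed form and a dense-matrix oracle", {
  # single study: y | tau ~ N(m0, se^2 + tau^2 + sd0^2)
  d <- make_dataset(0, 1, "RCT")
  lp <- likelihood_given_tau(d, effect_prior(0, 2), tau = 0)
  expect_equal(lp, log(1 / sqrt(10 * pi)), tolerance = 1e-12)
  expect_equal(exp(lp), 0.17842, tolerance = 1e-4)

  # k = 3: rank-one form vs dense multivariate normal density
  y <- c(-0.3, 0.5, 1.1); se <- c(0.2, 0.35, 0.15)
  d <- make_dataset(y, se)
  eff <- effect_prior(0.1, 2)
  for (tau in c(0, 0.25, 0.8, 3)) {
    Sigma <- diag(se^2 + tau^2) + eff$sd^2 * matrix(1, 3, 3)
    expect_equal(likelihood_given_tau(d, eff, tau),
                 oracle_mvn_logdens(y, rep(eff$mean, 3), Sigma),
                 tolerance = 1e-11)
  }

  # continuity in tau: finite everywhere, and the largest jump shrinks in
  # proportion when the grid is refined
  lt1 <- likelihood_given_tau(d, eff, seq(0, 2, length.out = 201))
  lt2 <- likelihood_given_tau(d, eff, seq(0, 2, length.out = 801))
  expect_true(all(is.finite(lt1)))
  expect_lt(max(abs(diff(lt2))), 0.5 * max(abs(diff(lt1))))
})

test_that("marginal likelihood agrees with Monte-Carlo integration", {
  y <- c(-0.3, 0.5, 1.1); se <- c(0.2, 0.35, 0.15)
  d <- make_dataset(y, se)
  for (fam in c("half-normal", "half-cauchy")) {
    fit <- nnhm(d, het_prior(fam, 0.5), effect_prior(0, 2),
                control = nnhm_control(summaries = FALSE))
    mc <- oracle_mc_marglik(y, se, het_prior(fam, 0.5), effect_prior(0, 2),
                            n = 2e5, seed = 42)
    expect_lt(abs(exp(fit$log_marglik) - mc$estimate), 3 * mc$se)
  }
})

test_that("marginal likelihood is invariant to study ordering", {
  y <- c(-0.3, 0.5, 1.1, 0.2); se <- c(0.2, 0.35, 0.15, 0.5)
  f1 <- nnhm(make_dataset(y, se), control = nnhm_control(summaries = FALSE))
  perm <- c(3, 1, 4, 2)
  f2 <- nnhm(make_dataset(y[perm], se[perm]),
             control = nnhm_control(summaries = FALSE))
  expect_equal(f1$log_marglik, f2$log_marglik, tolerance = 1e-10)
})

test_that("posterior machinery is internally coherent", {
  d <- toy3()
  fit <- nnhm(d, het_prior("half-cauchy", 0.5))
  expect_true(fit$diagnostics$converged)
  # tau weights sum to 1
  expect_equal(sum(fit$tau_grid$weight), 1, tolerance = 1e-12)
  # mu mixture density integrates to 1
  expect_equal(integrate(function(x) mu_density(fit, x), -10, 10,
                         rel.tol = 1e-8)$value, 1, tolerance = 1e-6)
  # CDF monotone from 0 to 1
  xs <- seq(-8, 8, length.out = 101)
  cdf <- mu_cdf(fit, xs)
  expect_true(all(diff(cdf) >= 0))
  expect_lt(cdf[1], 1e-5)
  expect_gt(cdf[101], 1 - 1e-5)
  # quantile inverts CDF; median consistent
  expect_equal(mu_cdf(fit, mu_quantile(fit, 0.25)), 0.25, tolerance = 1e-8)
  expect_equal(mu_quantile(fit, 0.5), fit$mu_median)
  # CrI mass and shortest-vs-equal-tailed contract
  mass <- mu_cdf(fit, fit$cri_high) - mu_cdf(fit, fit$cri_low)
  expect_gte(mass, 0.95 - 1e-6)
  et <- mu_quantile(fit, c(0.025, 0.975))
  expect_lte(fit$cri_high - fit$cri_low, et[2] - et[1] + 1e-8)
})

test_that("degenerate heterogeneity prior reduces to the fixed-effect conjugate posterior", {
  d <- make_dataset(c(0.2, 0.8), c(0.1, 0.3))
  fit <- nnhm(d, het_prior("half-normal", 1e-6), effect_prior(0, 2))
  cond <- conditional_mu_posterior(d, effect_prior(0, 2), tau = 0)
  expect_equal(fit$mu_median, cond$mean, tolerance = 1e-4)
  expect_equal(c(fit$cri_low, fit$cri_high),
               cond$mean + c(-1, 1) * qnorm(0.975) * cond$sd, tolerance = 1e-4)
})

test_that("symmetric data give a posterior median at the prior mean", {
  d <- make_dataset(c(-0.9, 0.9, -0.4, 0.4), c(0.2, 0.2, 0.3, 0.3))
  fit <- nnhm(d, het_prior("half-cauchy", 0.5), effect_prior(0, 2))
  expect_equal(fit$mu_median, 0, tolerance = 1e-8)
  expect_equal(fit$mu_mean, 0, tolerance = 1e-10)
})

test_that("a nearly uninformative study leaves the Bayes factor unchanged", {
  y <- c(-0.2, 0.4, 0.1, 0.6); se <- c(0.2, 0.3, 0.25, 0.4)
  des <- c("RCT", "RCT", "NRS", "NRS")
  d <- make_dataset(y, se, des)
  d_aug <- make_dataset(c(y, 0.3), c(se, 1e4), c(des, "NRS"))
  c1 <- compare_models(d, het_prior("half-cauchy"))
  c2 <- compare_models(d_aug, het_prior("half-cauchy"))
  expect_equal(log(c2$bf_pooled), log(c1$bf_pooled), tolerance = 1e-3)
})

test_that("single-study fits are carried through with the prior dominating", {
  d <- make_dataset(0.3, 0.25, "RCT")
  fit <- nnhm(d, het_prior("half-normal", 0.5))
  expect_true(is.finite(fit$log_marglik))
  expect_true(fit$cri_low < 0.3 && fit$cri_high > 0.3)
  # prior pulls the estimate toward its mean
  expect_lt(fit$mu_median, 0.3)
  expect_gt(fit$mu_median, 0)
})

test_that("posterior median of mu recovers the truth on synthetic data", {
  cfg <- synth_config(n_meta = 12, k_rct = 17, k_nrs = 33, mu_true = -0.35,
                      tau_true = 0.25, mode = "NORMAL", seed = 301)
  meds <- vapply(seq_len(cfg$n_meta), function(i)
    nnhm(generate_meta(cfg, i), het_prior("half-normal", 0.5))$mu_median,
    numeric(1))
  bias <- mean(meds) - (-0.35)
  mc_se <- sd(meds) / sqrt(length(meds))
  expect_lt(abs(bias), 3 * mc_se)
})
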