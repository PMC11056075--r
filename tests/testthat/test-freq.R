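test_that("single-study and identical-study limits", {
  d1 <- make_dataset(0.5, 0.2, "RCT")
  f <- dsl_fit(d1)
  expect_equal(f$mu_hat, 0.5)
  expect_equal(f$tau2, 0)
  expect_equal(c(f$ci_low, f$ci_high),
               0.5 + c(-1, 1) * qnorm(0.975) * 0.2)

  d2 <- make_dataset(c(0.5, 0.5), c(0.2, 0.2))
  f <- dsl_fit(d2)
  expect_equal(f$Q, 0)
  expect_equal(f$tau2, 0)
  expect_equal(f$mu_hat, 0.5)
  expect_equal(f$se_mu, 0.2 / sqrt(2))
  expect_equal(f$I2, 0)

  # identical studies: HKSJ dispersion collapses to a point
  f <- hksj_fit(d2)
  expect_equal(f$se_mu, 0)
  expect_equal(f$ci_low, f$ci_high)

  # IVhet single study
  f <- ivhet_fit(d1)
  expect_equal(f$mu_hat, 0.5)
  expect_equal(c(f$ci_low, f$ci_high), 0.5 + c(-1, 1) * qnorm(0.975) * 0.2)
})

test_that("all three estimators match the formula-by-formula oracles", {
  sets <- list(list(y = c(0, 0.8, 1.6), se = c(0.2, 0.2, 0.2)),
               list(y = c(-0.5, 0.1, 0.4, 0.9), se = c(0.15, 0.3, 0.25, 0.5)),
               list(y = c(0.2, 0.25), se = c(0.1, 0.4)))
  for (s in sets) {
    d <- make_dataset(s$y, s$se)
    f <- dsl_fit(d); o <- oracle_dsl(s$y, s$se)
    expect_equal(f$mu_hat, o$mu, tolerance = 1e-10)
    expect_equal(f$tau2, o$tau2, tolerance = 1e-10)
    expect_equal(f$Q, o$Q, tolerance = 1e-10)
    expect_equal(c(f$ci_low, f$ci_high), o$ci, tolerance = 1e-10)

    f <- hksj_fit(d); o <- oracle_hksj(s$y, s$se)
    expect_equal(f$mu_hat, o$mu, tolerance = 1e-10)
    expect_equal(f$se_mu^2, o$v, tolerance = 1e-10)
    expect_equal(c(f$ci_low, f$ci_high), o$ci, tolerance = 1e-10)

    f <- ivhet_fit(d); o <- oracle_ivhet(s$y, s$se)
    expect_equal(f$mu_hat, o$mu, tolerance = 1e-10)
    expect_equal(f$se_mu^2, o$v, tolerance = 1e-10)
    expect_equal(c(f$ci_low, f$ci_high), o$ci, tolerance = 1e-10)
  }
})

test_that("HKSJ two-study case matches the t1 hand computation", {
  d <- make_dataset(c(0, 1), c(1, 1))
  f <- hksj_fit(d)
  expect_equal(f$tau2, 0)          # Q = 0.5 < df = 1
  expect_equal(f$mu_hat, 0.5)
  expect_equal(f$se_mu^2, 0.25)    # 0.5 / (1 * 2)
  expect_equal(f$df, 1)
  expect_true(f$unstable)
  expect_equal(c(f$ci_low, f$ci_high), 0.5 + c(-1, 1) * qt(0.975, 1) * 0.5,
               tolerance = 1e-6)
  expect_error(hksj_fit(make_dataset(0.5, 0.2, "RCT")), "at least 2")
})

test_that("HKSJ keeps the DSL point estimate; IVhet reduces to fixed effect at tau2 = 0", {
  d <- make_dataset(c(-0.5, 0.1, 0.4, 0.9), c(0.15, 0.3, 0.25, 0.5))
  expect_equal(hksj_fit(d)$mu_hat, dsl_fit(d)$mu_hat)

  # homogeneous data: tau2 = 0, IVhet == inverse-variance fixed effect == DSL
  dh <- make_dataset(c(0.29, 0.31, 0.30), c(0.4, 0.5, 0.45))
  f_iv <- ivhet_fit(dh)
  expect_equal(f_iv$tau2, 0)
  w <- 1 / c(0.4, 0.5, 0.45)^2
  mu_fe <- sum(w * c(0.29, 0.31, 0.30)) / sum(w)
  expect_equal(f_iv$mu_hat, mu_fe)
  expect_equal(f_iv$se_mu, 1 / sqrt(sum(w)), tolerance = 1e-12)
})

test_that("DSL and HKSJ agree with metafor", {
  skip_if_not_installed("metafor")
  y <- c(-0.5, 0.1, 0.4, 0.9, 0.05)
  se <- c(0.15, 0.3, 0.25, 0.5, 0.2)
  d <- make_dataset(y, se)
  m <- metafor::rma(yi = y, sei = se, method = "DL")
  f <- dsl_fit(d)
  expect_equal(f$mu_hat, as.numeric(m$beta), tolerance = 1e-8)
  expect_equal(f$tau2, m$tau2, tolerance = 1e-8)
  expect_equal(c(f$ci_low, f$ci_high), c(m$ci.lb, m$ci.ub), tolerance = 1e-8)

  mk <- metafor::rma(yi = y, sei = se, method = "DL", test = "knha")
  fk <- hksj_fit(d)
  expect_equal(c(fk$ci_low, fk$ci_high), c(mk$ci.lb, mk$ci.ub),
               tolerance = 1e-8)
})

test_that("estimator invariants hold on random datasets", {
  set.seed(11)
  for (rep in 1:25) {
    k <- sample(2:12, 1)
    y <- rnorm(k, 0.2, 0.7)
    se <- runif(k, 0.05, 0.8)
    d <- make_dataset(y, se)
    for (fit in list(dsl_fit(d), hksj_fit(d), ivhet_fit(d))) {
      # pooled estimate is a convex combination of the study effects
      expect_gte(fit$mu_hat, min(y)); expect_lte(fit$mu_hat, max(y))
      expect_gte(fit$tau2, 0)
      expect_true(fit$ci_low <= fit$mu_hat && fit$mu_hat <= fit$ci_high)
      expect_identical(fit$excludes_null,
                       fit$ci_low > 0 || fit$ci_high < 0)
    }
    # Q is invariant under shifting all effects by a constant
    expect_equal(dsl_fit(make_dataset(y + 3.7, se))$Q, dsl_fit(d)$Q,
                 tolerance = 1e-9)
    # IVhet CI is at least as wide as the fixed-effect IV CI
    fe_width <- 2 * qnorm(0.975) / sqrt(sum(1 / se^2))
    f_iv <- ivhet_fit(d)
    expect_gte(f_iv$ci_high - f_iv$ci_low, fe_width - 1e-12)
  }
})
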