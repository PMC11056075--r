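# Independent oracles: deliberately naive, formula-by-formula or brute-force
# implementations used to check the package's numerics.  They share no code
# with the implementation in R/.

# --- frequentist estimators, step by step ------------------------------------

oracle_dsl <- function(y, se, level = 0.95) {
  k <- length(y)
  w <- numeric(k)
  for (i in 1:k) w[i] <- 1 / se[i]^2
  mu_fe <- sum(w * y) / sum(w)
  Q <- 0
  for (i in 1:k) Q <- Q + w[i] * (y[i] - mu_fe)^2
  tau2 <- if (k == 1) 0 else max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- numeric(k)
  for (i in 1:k) ws[i] <- 1 / (se[i]^2 + tau2)
  mu <- sum(ws * y) / sum(ws)
  se_mu <- sqrt(1 / sum(ws))
  z <- qnorm(1 - (1 - level) / 2)
  list(mu = mu, se_mu = se_mu, tau2 = tau2, Q = Q,
       ci = c(mu - z * se_mu, mu + z * se_mu))
}

oracle_hksj <- function(y, se, level = 0.95) {
  k <- length(y)
  base <- oracle_dsl(y, se, level)
  ws <- 1 / (se^2 + base$tau2)
  v <- 0
  for (i in 1:k) v <- v + ws[i] * (y[i] - base$mu)^2
  v <- v / ((k - 1) * sum(ws))
  tq <- qt(1 - (1 - level) / 2, df = k - 1)
  list(mu = base$mu, v = v, tau2 = base$tau2, df = k - 1,
       ci = c(base$mu - tq * sqrt(v), base$mu + tq * sqrt(v)))
}

oracle_ivhet <- function(y, se, level = 0.95) {
  k <- length(y)
  tau2 <- oracle_dsl(y, se, level)$tau2
  w <- 1 / se^2
  what <- w / sum(w)
  mu <- sum(what * y)
  v <- 0
  for (i in 1:k) v <- v + what[i]^2 * (se[i]^2 + tau2)
  z <- qnorm(1 - (1 - level) / 2)
  list(mu = mu, v = v, tau2 = tau2,
       ci = c(mu - z * sqrt(v), mu + z * sqrt(v)))
}

# --- dense multivariate normal log density (no rank-one shortcut) ------------

oracle_mvn_logdens <- function(y, mean, Sigma) {
  k <- length(y)
  ch <- chol(Sigma)
  z <- backsolve(ch, y - mean, transpose = TRUE)
  -0.5 * (k * log(2 * pi)) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

# --- Monte-Carlo marginal likelihood over (mu, tau) from the priors ----------

oracle_mc_marglik <- function(y, se, het, eff, n = 1e6, seed = 1) {
  set.seed(seed)
  tau <- qhet(het, runif(n))
  mu <- rnorm(n, eff$mean, eff$sd)
  ll <- rep(0, n)
  for (i in seq_along(y))
    ll <- ll + dnorm(y[i], mu, sqrt(se[i]^2 + tau^2), log = TRUE)
  L <- exp(ll)
  list(estimate = mean(L), se = sd(L) / sqrt(n))
}

# --- grid-search shortest interval ------------------------------------------
# dense search over candidate lower endpoints via a numerically inverted CDF

oracle_grid_hpd <- function(dens, lo, hi, level = 0.95, n = 20001) {
  x <- seq(lo, hi, length.out = n)
  d <- dens(x)
  cdf <- cumsum((d[-1] + d[-n]) / 2 * diff(x))
  cdf <- c(0, cdf) / cdf[n - 1]
  qf <- function(p) approx(cdf, x, xout = p, ties = "ordered")$y
  a <- seq(0, 1 - level, length.out = 4001)
  lows <- qf(a); highs <- qf(a + level)
  i <- which.min(highs - lows)
  c(lows[i], highs[i])
}

# --- shared tiny datasets ----------------------------------------------------

toy3 <- function() {
  meta_dataset(data.frame(study_id = c("a", "b", "c"),
                          design = c("RCT", "NRS", "NRS"),
                          y = c(0, 0.8, 1.6), se = c(0.2, 0.2, 0.2)),
               metric = "OR", label = "toy3")
}

make_dataset <- function(y, se, design = NULL, metric = "OR") {
  k <- length(y)
  if (is.null(design)) design <- rep(c("RCT", "NRS"), length.out = k)
  meta_dataset(data.frame(study_id = sprintf("s%d", 1:k), design = design,
                          y = y, se = se), metric = metric, label = "test")
}
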