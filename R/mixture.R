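## Finite mixtures of normals: the marginal posterior of mu under the NNHM
## is exactly such a mixture (one component per tau grid point), and the
## model-averaged posterior is a mixture of two of them.

mix_norm <- function(w, mean, sd) {
  stopifnot(length(w) == length(mean), length(mean) == length(sd),
            all(w >= 0), all(sd > 0))
  w <- w / sum(w)
  structure(list(w = w, mean = mean, sd = sd), class = "mix_norm")
}

#' @export
print.mix_norm <- function(x, ...) {
  cat(sprintf("normal mixture with %d components\n", length(x$w)))
  invisible(x)
}

dmix <- function(mix, x) {
  vapply(x, function(xi) sum(mix$w * stats::dnorm(xi, mix$mean, mix$sd)),
         numeric(1))
}

pmix <- function(mix, x) {
  vapply(x, function(xi) sum(mix$w * stats::pnorm(xi, mix$mean, mix$sd)),
         numeric(1))
}

qmix <- function(mix, p) {
  lo <- min(mix$mean - 10 * mix$sd)
  hi <- max(mix$mean + 10 * mix$sd)
  vapply(p, function(pi) {
    if (pi <= 0) return(-Inf)
    if (pi >= 1) return(Inf)
    stats::uniroot(function(x) pmix(mix, x) - pi, lower = lo, upper = hi,
                   extendInt = "upX", tol = 1e-10)$root
  }, numeric(1))
}

mix_mean <- function(mix) sum(mix$w * mix$mean)

## combine two mixtures with outer weights (w1, 1 - w1)
mix_combine <- function(m1, m2, w1) {
  mix_norm(c(w1 * m1$w, (1 - w1) * m2$w),
           c(m1$mean, m2$mean), c(m1$sd, m2$sd))
}
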