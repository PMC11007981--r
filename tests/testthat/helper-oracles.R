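# independent oracles used across test files

# marginal alternative/null density ratio by adaptive quadrature over the
# random effect mu (independent of the closed form in the package)
ratio_quad_oracle <- function(z, sigma) {
  num <- integrate(function(mu) dnorm(z - mu) * dnorm(mu, 0, sigma),
                   -Inf, Inf, rel.tol = 1e-12, abs.tol = 0)$value
  num / dnorm(z)
}

# naive unvectorized pseudo-log-likelihood over a list of z-vectors
pseudo_loglik_naive <- function(zlist, pi0, sigma) {
  tot <- 0
  for (zv in zlist) {
    s <- 0
    for (zk in zv) {
      s <- s + exp(-0.5 * log1p(sigma^2) +
                     zk^2 * sigma^2 / (2 * (1 + sigma^2)))
    }
    tot <- tot + log(pi0 + (1 - pi0) * s / length(zv))
  }
  tot
}

# two-group posterior for a single statistic, straight from the densities
posterior_m1_oracle <- function(z, pi0, sigma) {
  f0 <- dnorm(z)
  f1 <- dnorm(z, 0, sqrt(1 + sigma^2))
  pi0 * f0 / (pi0 * f0 + (1 - pi0) * f1)
}

# the full-data marginal alternative density by trapezoid integration over
# beta in (-1, 1), writing the integrand exactly as the model states it:
# N_n(y; beta x, (1-beta^2) I) * sqrt(n-3)/(sqrt(2 pi) sigma (1-beta^2))
#   * exp(-(n-3) atanh(beta)^2 / (2 sigma^2))
log_f1_trapezoid_oracle <- function(stats, j, sigma, npts = 400001L) {
  n <- stats$n
  b <- seq(-1 + 1e-9, 1 - 1e-9, length.out = npts)
  lcond <- -(n / 2) * log(2 * pi) - (n / 2) * log1p(-b^2) -
    (stats$yy - 2 * b * stats$yx[j] + b^2 * stats$xx[j]) / (2 * (1 - b^2))
  lprior <- 0.5 * log(n - 3) - 0.5 * log(2 * pi) - log(sigma) -
    log1p(-b^2) - (n - 3) * atanh(b)^2 / (2 * sigma^2)
  lv <- lcond + lprior
  M <- max(lv)
  h <- b[2L] - b[1L]
  w <- rep(1, npts); w[c(1L, npts)] <- 0.5
  M + log(sum(w * exp(lv - M)) * h)
}

# direct (non-EM) maximization of the full-data composite log-likelihood,
# used to verify the EM fixed point
reg_direct_ml <- function(flat, quad_order = 41L) {
  nll <- function(th) {
    pi0 <- plogis(th[1L]); sigma <- exp(th[2L])
    rho <- groupfdr:::.pair_logratio(flat, sigma, quad_order)
    lmr <- groupfdr:::.group_log_mean_exp(rho, flat$m)
    -sum(groupfdr:::.log_mix(pi0, lmr))
  }
  o <- optim(c(qlogis(0.5), log(2)), nll, method = "Nelder-Mead",
             control = list(reltol = 1e-12, maxit = 2000))
  list(pi0 = plogis(o$par[1L]), sigma = exp(o$par[2L]), loglik = -o$value)
}
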