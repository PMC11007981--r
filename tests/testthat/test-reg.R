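# small helper: simulate one genotype-conditioned dataset
reg_sim <- function(N, m, n, pi0, sigma, rho = 0.3, seed = 1) {
  cfg <- sim_config(N = N, m = m, n = n, pi0 = pi0, sigma = sigma,
                    rho = rho, seed = seed)
  geno <- simulate_genotypes(cfg)
  cfg$seed <- NULL
  simulate_expression(geno, cfg)
}

test_that("log_f1_conditional matches the direct Gaussian density", {
  st <- gene_stats(c(1, 0), rbind(c(1, 0)))
  # beta = 0 reduces to the null density
  expect_equal(log_f1_conditional(st, 1, 0), sum(dnorm(c(1, 0), log = TRUE)))
  # direct two-term evaluation at beta = 0.5
  expect_equal(log_f1_conditional(st, 1, 0.5),
               sum(dnorm(c(1, 0), 0.5 * c(1, 0), sqrt(0.75), log = TRUE)),
               tolerance = 1e-12)
  # sign flip (beta, x) -> (-beta, -x)
  set.seed(41)
  y <- rnorm(6)
  x <- rnorm(6)
  s1 <- gene_stats(y, rbind(x))
  s2 <- gene_stats(y, rbind(-x))
  expect_equal(log_f1_conditional(s1, 1, 0.4), log_f1_conditional(s2, 1, -0.4))
  expect_error(log_f1_conditional(s1, 1, 1), "beta")
})

test_that("log_f1_marginal agrees with the trapezoid oracle and is stable in order", {
  set.seed(42)
  n <- 100
  x <- rnorm(n); x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  beta_true <- 0.4
  y <- rnorm(n, beta_true * x, sqrt(1 - beta_true^2))
  y <- (y - mean(y)) / sqrt(mean((y - mean(y))^2))
  st <- gene_stats(y, rbind(x))
  for (sigma in c(0.5, 2, 6)) {
    gh <- log_f1_marginal(st, 1, sigma, quad_order = 41L)
    tr <- log_f1_trapezoid_oracle(st, 1, sigma)
    # relative error on the density scale
    expect_lt(abs(expm1(gh - tr)), 1e-6)
  }
  # doubling the order changes nothing beyond the quadrature noise floor
  expect_lt(abs(log_f1_marginal(st, 1, 2, 41L) -
                  log_f1_marginal(st, 1, 2, 81L)), 1e-7)
  # sigma -> 0 recovers the conditional at beta = 0
  expect_equal(log_f1_marginal(st, 1, 1e-12, 41L),
               log_f1_conditional(st, 1, 0), tolerance = 1e-9)
  expect_error(log_f1_marginal(st, 1, 2, quad_order = 5L), "quad_order")
})

test_that("gene_lfdr_full behaves like a posterior probability", {
  set.seed(43)
  n <- 20
  x <- rnorm(n); x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  y <- rnorm(n)
  y <- y - sum(y * x) / sum(x * x) * x          # orthogonal: yx = 0
  y <- (y - mean(y)) / sqrt(mean((y - mean(y))^2))
  st <- gene_stats(y, rbind(x))
  expect_equal(st$yx[1], 0, tolerance = 1e-9)
  expect_equal(gene_lfdr_full(st, 1, 2), 1)
  # orthogonal data mildly favor the null
  l <- gene_lfdr_full(st, 0.4, 2)
  expect_gt(l, 0.4)
  # cross-check against direct integration of the density ratio over t
  ratio <- integrate(function(t) {
    vapply(t, function(ti) {
      b <- tanh(ti / sqrt(n - 3))
      if (abs(b) >= 1 - 1e-15) return(0)
      exp(log_f1_conditional(st, 1, b) -
            sum(dnorm(y, log = TRUE))) * dnorm(ti, 0, 2)
    }, 0)
  }, -Inf, Inf, rel.tol = 1e-10)$value
  expect_equal(l, 0.4 / (0.4 + 0.6 * ratio), tolerance = 1e-8)
  # sigma -> 0 limit equals pi0 exactly
  expect_equal(gene_lfdr_full(st, 0.37, 1e-12), 0.37, tolerance = 1e-9)
})

test_that("lfdr is invariant to rescaling genotypes when standardized first", {
  sim <- reg_sim(N = 30, m = 4, n = 50, pi0 = 0.3, sigma = 4, seed = 44)
  x2 <- sim$data
  x2$genotypes <- lapply(x2$genotypes, function(g) g * 7.3)
  f1 <- suppressWarnings(reg_fdr(sim$data, init = c(0.3, 4), max_iter = 1L,
                                 tol = Inf))
  f2 <- suppressWarnings(reg_fdr(x2, init = c(0.3, 4), max_iter = 1L,
                                 tol = Inf))
  expect_equal(fitted(f1), fitted(f2), tolerance = 1e-10)
  expect_true(all(fitted(f1) >= 0 & fitted(f1) <= 1))
})

test_that("EM increases the composite likelihood and matches direct maximization", {
  sim <- reg_sim(N = 150, m = 5, n = 40, pi0 = 0.3, sigma = 3, seed = 45)
  fit <- suppressWarnings(reg_fdr(sim$data, init = c(0.5, 1.5), tol = 1e-9,
                                  max_iter = 300L))
  expect_true(all(diff(fit$trace) > -1e-6 * (1 + abs(fit$trace[-1]))))
  # the EM fixed point maximizes the same composite likelihood that a
  # direct 2-parameter search maximizes
  flat <- groupfdr:::.reg_flatten(sim$data, NULL)
  direct <- reg_direct_ml(flat)
  expect_lt(abs(fit$loglik - direct$loglik), 1e-3 * (1 + abs(direct$loglik)))
  expect_lt(abs(coef(fit)[["pi0"]] - direct$pi0), 0.01)
  expect_lt(abs(coef(fit)[["sigma"]] - direct$sigma),
            0.02 * (1 + direct$sigma))
})

test_that("an all-null dataset drives the EM to the pi0 boundary", {
  sim <- reg_sim(N = 200, m = 3, n = 40, pi0 = 1, sigma = 3, seed = 46)
  expect_warning(fit <- reg_fdr(sim$data), "bound")
  expect_gt(coef(fit)[["pi0"]], 0.99)
})

test_that("the full-data fit recovers generating parameters", {
  # sigma is tightly identified (within 15% per run); pi0 has sampling SD
  # ~0.02 at N = 1000, so it is checked on the average across runs
  pi0s <- numeric(3)
  for (r in 1:3) {
    sim <- reg_sim(N = 1000, m = 10, n = 83, pi0 = 0.2, sigma = 5,
                   rho = 0.5, seed = 460 + r)
    cf <- coef(reg_fdr(sim$data))
    expect_lt(abs(cf[["sigma"]] - 5) / 5, 0.15)
    pi0s[r] <- cf[["pi0"]]
  }
  expect_lt(abs(mean(pi0s) - 0.2), 0.035)
})

test_that("full-data and summary-statistic lfdr agree on independent-SNP data", {
  sim <- reg_sim(N = 300, m = 8, n = 200, pi0 = 0.25, sigma = 4, rho = 0,
                 seed = 47)
  rfit <- reg_fdr(sim$data)
  zfit <- zreg_fdr(compute_summary(sim$data))
  shared <- intersect(names(fitted(rfit)), names(fitted(zfit)))
  expect_gt(cor(fitted(rfit)[shared], fitted(zfit)[shared]), 0.9)
})

test_that("gene_stats validates its inputs", {
  expect_error(gene_stats(rep(0, 4), matrix(rnorm(8), 2)), "zero")
  expect_error(gene_stats(rnorm(4), matrix(rnorm(9), 3)), "sample dimension")
})
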