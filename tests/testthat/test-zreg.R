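test_that("alt_null_ratio matches its closed form and the quadrature oracle", {
  expect_equal(alt_null_ratio(0, 0), 1)
  expect_equal(alt_null_ratio(c(-4, 7), 0), c(1, 1))
  expect_equal(alt_null_ratio(0, 1), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(alt_null_ratio(3, 2), exp(3.6) / sqrt(5), tolerance = 1e-12)
  expect_equal(alt_null_ratio(3, 2), 16.3672279749912, tolerance = 1e-8)
  # symmetric in z
  expect_equal(alt_null_ratio(-3, 2), alt_null_ratio(3, 2))
  # agreement with numeric integration of the mu-integral on a grid
  for (sigma in c(0.1, 1, 2, 5, 10)) {
    for (z in seq(-10, 10, by = 2.5)) {
      expect_equal(alt_null_ratio(z, sigma), ratio_quad_oracle(z, sigma),
                   tolerance = 1e-8)
    }
  }
})

test_that("gene_lfdr matches hand values and the m=1 Bayes posterior", {
  expect_equal(gene_lfdr(c(1, -2, 0.3), 1, 1), 1)
  expect_equal(gene_lfdr(0, 0.5, 1), 1 / (1 + 1 / sqrt(2)), tolerance = 1e-12)
  expect_equal(gene_lfdr(0, 0.5, 1), 0.585786437626905, tolerance = 1e-10)
  expect_equal(gene_lfdr(c(3, -1, 0), 0.5, 0), 0.5)
  # m = 1: exactly the two-group posterior computed from the densities
  for (z in c(-4, -1, 0, 0.7, 2.5)) {
    for (pi0 in c(0.1, 0.5, 0.9)) {
      expect_equal(gene_lfdr(z, pi0, 2.5), posterior_m1_oracle(z, pi0, 2.5),
                   tolerance = 1e-12)
    }
  }
  expect_warning(out <- gene_lfdr(1, 0, 1), "pi0 = 0")
  expect_equal(out, 0)
  expect_error(gene_lfdr(numeric(0), 0.5, 1), "at least one")
})

test_that("gene_lfdr is permutation-invariant and monotone in |z|", {
  set.seed(31)
  zv <- rnorm(8, 0, 2)
  expect_equal(gene_lfdr(zv, 0.3, 2), gene_lfdr(sample(zv), 0.3, 2))
  # raising one |z| strictly lowers the lfdr when sigma > 0
  l0 <- gene_lfdr(zv, 0.3, 2)
  zv[3] <- zv[3] + sign(zv[3]) * 1.5
  expect_lt(gene_lfdr(zv, 0.3, 2), l0)
})

test_that("pseudo_loglik agrees with a naive loop and handles edge cases", {
  expect_equal(pseudo_loglik(list(g = 0), 0.5, 1),
               log(0.5 + 0.5 / sqrt(2)), tolerance = 1e-12)
  set.seed(32)
  zl <- list(a = rnorm(3, 0, 2), b = rnorm(5), c = rnorm(1, 3))
  for (pi0 in c(0.2, 0.8)) {
    for (sigma in c(0.5, 4)) {
      expect_equal(pseudo_loglik(zl, pi0, sigma),
                   pseudo_loglik_naive(zl, pi0, sigma), tolerance = 1e-12)
    }
  }
  # sigma = 0: the ratio is identically 1, so the objective is 0
  expect_equal(pseudo_loglik(zl, 0.123, 0), 0)
  # extreme statistics must not overflow
  expect_true(is.finite(pseudo_loglik(list(g = c(45, -38)), 0.5, 10)))
})

test_that("the expected pseudo-log-likelihood peaks at the true parameters", {
  # averaged over simulated datasets, the objective at the truth beats
  # every clearly wrong parameter pair
  set.seed(33)
  truth <- c(0.2, 3)
  wrong <- rbind(c(0.5, 3), c(0.2, 1.5), c(0.2, 4.5), c(0.8, 0.5), c(0.05, 6))
  tot_true <- 0
  tot_wrong <- numeric(nrow(wrong))
  for (b in 1:30) {
    sim <- simulate_zstats(sim_config(N = 1000, m = 10, pi0 = truth[1],
                                      sigma = truth[2], rho = 0.1,
                                      seed = 330 + b))
    tot_true <- tot_true + pseudo_loglik(sim$data, truth[1], truth[2])
    for (w in seq_len(nrow(wrong))) {
      tot_wrong[w] <- tot_wrong[w] +
        pseudo_loglik(sim$data, wrong[w, 1], wrong[w, 2])
    }
  }
  expect_true(all(tot_true > tot_wrong))
})

test_that("zreg_fdr recovers the generating parameters", {
  # moderately large studies: estimates land close to the truth every run
  for (r in 1:5) {
    sim <- simulate_zstats(sim_config(N = 50000, m = 20, pi0 = 0.5,
                                      sigma = 4, rho = 0, seed = 340 + r))
    cf <- coef(zreg_fdr(sim$data))
    expect_lt(abs(cf[["pi0"]] - 0.5), 0.02)
    expect_lt(abs(cf[["sigma"]] - 4), 0.15)
  }
})

test_that("an all-null dataset drives the fit to the boundary", {
  sim <- simulate_zstats(sim_config(N = 3000, m = 10, pi0 = 1, sigma = 3,
                                    rho = 0.1, seed = 35))
  expect_warning(fit <- zreg_fdr(sim$data), "bound")
  expect_true(length(fit$boundary) > 0)
  # the objective is ~0: no mixture improvement over the null model
  expect_lt(abs(fit$loglik), 5)
})

test_that("fitted lfdr values respect the fit and lfdr_table matches", {
  sim <- simulate_zstats(sim_config(N = 500, m = 10, pi0 = 0.3, sigma = 4,
                                    rho = 0.2, seed = 36))
  fit <- zreg_fdr(sim$data)
  cf <- coef(fit)
  tab <- lfdr_table(sim$data, cf[["pi0"]], cf[["sigma"]])
  expect_equal(unname(fitted(fit)), tab$lfdr, tolerance = 1e-12)
  expect_true(all(tab$lfdr >= 0 & tab$lfdr <= 1))
  # all-zero z, m = 1 per gene: every gene has the same known lfdr
  tab0 <- lfdr_table(matrix(0, 5, 1), 0.5, 1)
  expect_equal(tab0$lfdr, rep(1 / (1 + 1 / sqrt(2)), 5), tolerance = 1e-12)
  # predict on new data agrees with direct computation
  newd <- eqtl_summary(list(g1 = c(0.5, -2), g2 = 4))
  pr <- predict(fit, newd)
  expect_equal(unname(pr[1]), gene_lfdr(c(0.5, -2), cf[["pi0"]], cf[["sigma"]]),
               tolerance = 1e-12)
})

test_that("fit object methods behave like a standard modelling fit", {
  sim <- simulate_zstats(sim_config(N = 400, m = 8, pi0 = 0.3, sigma = 3,
                                    rho = 0, seed = 37))
  fit <- zreg_fdr(sim$data)
  expect_named(coef(fit), c("pi0", "sigma"))
  expect_s3_class(fit, "groupfdr_fit")
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_output(print(fit), "pi0")
  expect_output(print(summary(fit)), "rejected")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]]$data, "eqtl_summary")
  expect_equal(length(sims[[1]]$truth$is_null), 400L)
})
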