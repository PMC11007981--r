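test_that("residualize centers, annihilates covariates, matches normal equations", {
  set.seed(11)
  M <- matrix(rnorm(30), 3)
  # no covariates: row-centering
  expect_equal(residualize(M), M - rowMeans(M))
  # a row equal to a covariate is annihilated
  C <- matrix(rnorm(10), 1)
  M2 <- rbind(C, M)
  expect_lt(max(abs(residualize(M2, C)[1, ])), 1e-10)
  # residuals from an independently coded normal-equation solve
  D <- cbind(1, t(C))
  H <- D %*% solve(crossprod(D)) %*% t(D)
  expect_equal(residualize(M, C), M - M %*% H, tolerance = 1e-10)
  # idempotence
  R1 <- residualize(M, C)
  expect_equal(residualize(R1, C), R1, tolerance = 1e-10)
  expect_lt(max(abs(rowMeans(R1))), 1e-10)
})

test_that("residualize rejects bad designs", {
  M <- matrix(rnorm(20), 2)
  C <- matrix(rnorm(10), 1, dimnames = list("pc1", NULL))
  # collinear covariates are named in the error
  expect_error(residualize(M, rbind(C, pc2 = 2 * C[1, ])), "pc2")
  # too few samples for the design
  expect_error(residualize(matrix(rnorm(6), 2, 3),
                           matrix(rnorm(9), 3)), "covariates plus intercept")
  # mismatched sample dimension
  expect_error(residualize(M, matrix(rnorm(4), 1)), "sample dimension")
})

test_that("fisher_z matches the series value and is odd and increasing", {
  expect_equal(fisher_z(0, 10), 0)
  expect_equal(fisher_z(0.5, 103), 10 * atanh(0.5), tolerance = 1e-12)
  expect_equal(fisher_z(0.5, 103), 5.49306144334055, tolerance = 1e-10)
  expect_equal(fisher_z(-0.5, 103), -fisher_z(0.5, 103))
  r <- seq(-0.95, 0.95, by = 0.05)
  z <- fisher_z(r, 28)
  expect_true(all(diff(z) > 0))
  expect_equal(sign(z), sign(r))
  expect_error(fisher_z(1, 10), "Fisher")
  expect_error(fisher_z(0.2, 3), "n must")
})

test_that("compute_summary reproduces hand-computed statistics on a toy dataset", {
  set.seed(21)
  n <- 12
  Y <- matrix(rnorm(2 * n), 2)
  G1 <- matrix(rnorm(2 * n), 2)
  G2 <- matrix(rnorm(2 * n), 2)
  d <- full_dataset(Y, list(G1, G2))
  s <- compute_summary(d)
  expect_s3_class(s, "eqtl_summary")
  expect_equal(s$m, c(2L, 2L))
  # hand calculation: center, correlate, Fisher transform
  hand <- function(y, x) {
    sqrt(n - 3) * atanh(cor(y - mean(y), x - mean(x)))
  }
  expect_equal(s$z, c(hand(Y[1, ], G1[1, ]), hand(Y[1, ], G1[2, ]),
                      hand(Y[2, ], G2[1, ]), hand(Y[2, ], G2[2, ])),
               tolerance = 1e-12)
})

test_that("orthogonal expression gives zero statistics; a planted signal wins", {
  set.seed(22)
  n <- 1000
  x <- rnorm(n)
  # orthogonalize y against x exactly
  y <- rnorm(n)
  y <- y - mean(y)
  xc <- x - mean(x)
  y <- y - sum(y * xc) / sum(xc * xc) * xc
  d0 <- full_dataset(matrix(y, 1), list(matrix(xc, 1)))
  expect_equal(compute_summary(d0)$z, 0, tolerance = 1e-8)
  # y driven by the first SNP out of 10
  G <- matrix(rnorm(10 * n), 10)
  y2 <- G[1, ] + rnorm(n)
  d1 <- full_dataset(matrix(y2, 1), list(G))
  z <- compute_summary(d1)$z
  expect_equal(which.max(abs(z)), 1L)
})

test_that("degenerate rows are dropped with warnings", {
  set.seed(23)
  n <- 20
  Y <- rbind(rnorm(n), rep(1, n))
  G <- list(rbind(rnorm(n), rep(2, n)), matrix(rnorm(n), 1))
  expect_warning(expect_warning(s <- compute_summary(full_dataset(Y, G)),
                                "SNP"), "gene")
  expect_equal(length(s$m), 1L)
  expect_equal(s$m, 1L)
  # perfect correlation: the SNP duplicating the expression row is dropped
  y <- rnorm(n)
  G2 <- list(rbind(y, rnorm(n)))
  expect_warning(s2 <- compute_summary(full_dataset(matrix(y, 1), G2)),
                 "SNP")
  expect_equal(s2$m, 1L)
})

test_that("missing genotypes are mean-imputed", {
  set.seed(24)
  n <- 30
  y <- rnorm(n)
  g <- rnorm(n)
  gna <- g
  gna[c(3, 7)] <- NA
  expect_message(
    s <- compute_summary(full_dataset(matrix(y, 1), list(matrix(gna, 1)))),
    "imputed")
  gimp <- gna
  gimp[is.na(gna)] <- mean(gna, na.rm = TRUE)
  expect_equal(s$z, fisher_z(cor(y, gimp), n), tolerance = 1e-12)
})

test_that("computed null statistics are standard normal across replicate runs", {
  set.seed(25)
  pass <- logical(100)
  for (r in 1:100) {
    n <- 50
    Y <- matrix(rnorm(40 * n), 40)
    G <- lapply(1:40, function(i) matrix(rnorm(5 * n), 5))
    z <- compute_summary(full_dataset(Y, G))$z
    pass[r] <- suppressWarnings(stats::ks.test(z, pnorm)$p.value) > 0.01
  }
  expect_gte(mean(pass), 0.95)
})

test_that("eqtl_summary groups a flat vector by first appearance, keeping order", {
  s <- eqtl_summary(c(1, 2, 3, 4, 5),
                    gene_ids = c("b", "a", "b", "a", "b"),
                    snp_ids = c("s1", "s2", "s3", "s4", "s5"))
  expect_equal(s$gene_ids, c("b", "a"))
  expect_equal(s$m, c(3L, 2L))
  expect_equal(s$z, c(1, 3, 5, 2, 4))
  expect_equal(s$snp_ids, c("s1", "s3", "s5", "s2", "s4"))
  expect_error(eqtl_summary(c(1, NA), gene_ids = c("a", "a")), "finite")
  expect_error(eqtl_summary(numeric(0), gene_ids = character(0)))
})
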