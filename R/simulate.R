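# ---- synthetic-data generators ---------------------------------------------

#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic-data generators.
#' Defaults reflect the study conditions the method targets: 10,000 genes,
#' 30 SNPs per gene, 200 samples, 20% alternative... i.e. `pi0 = 0.2`
#' means 20% of genes are NULL - the Bernoulli indicator decides the
#' gene-level null with probability `pi0`, matching the estimand of the
#' mixture fit.
#'
#' @param N number of genes.
#' @param m SNPs per gene: a single count, or a length-2 range from which
#'   per-gene counts are drawn uniformly.
#' @param n number of samples (used by the genotype-conditioned scheme;
#'   carried through the serial-z scheme for interface consistency only).
#' @param pi0 prior probability that a gene is null.
#' @param sigma SD of the Fisher-scale effect.
#' @param rho lag-1 serial correlation of z-statistics along SNPs (serial-z
#'   scheme) or the latent LD-decay correlation (genotype scheme).
#' @param maf_range minor-allele-frequency interval, a subset of (0, 0.5].
#' @param seed optional integer seed; when set, each generator call starts
#'   from it (identical config + seed gives bit-identical output).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(N = 10000L, m = 30L, n = 200L, pi0 = 0.2, sigma = 5,
                       rho = 0.1, maf_range = c(0.05, 0.5), seed = NULL) {
  stopifnot(N >= 1, n >= 4, pi0 >= 0, pi0 <= 1, sigma >= 0, abs(rho) < 1,
            length(m) %in% 1:2, all(m >= 1),
            length(maf_range) == 2L, maf_range[1L] > 0, maf_range[2L] <= 0.5,
            maf_range[1L] <= maf_range[2L])
  structure(list(N = as.integer(N), m = as.integer(m), n = as.integer(n),
                 pi0 = pi0, sigma = sigma, rho = rho,
                 maf_range = maf_range, seed = seed),
            class = "sim_config")
}

.sim_m <- function(cfg) {
  if (length(cfg$m) == 1L) rep.int(cfg$m, cfg$N)
  else sample(seq.int(cfg$m[1L], cfg$m[2L]), cfg$N, replace = TRUE)
}

.sim_truth <- function(cfg, m) {
  is_null <- runif(cfg$N) < cfg$pi0
  causal <- ifelse(is_null, NA_integer_,
                   1L + floor(runif(cfg$N) * m))        # uniform over SNPs
  effect <- ifelse(is_null, NA_real_, rnorm(cfg$N, 0, cfg$sigma))
  data.frame(gene_id = paste0("gene", seq_len(cfg$N)),
             is_null = is_null, causal_snp = as.integer(causal),
             effect = effect, stringsAsFactors = FALSE)
}

#' Simulate grouped z-statistics with serial correlation
#'
#' Direct generator on the z-statistic scale. Null genes get a stationary
#' Gaussian AR(1) chain along their SNPs (standard normal marginals, lag-1
#' correlation `rho`). An alternative gene draws a causal SNP uniformly
#' and a Fisher-scale effect `mu ~ N(0, sigma^2)`, sets the causal
#' statistic to `N(mu, 1)`, and extends left and right with the *null*
#' Markov kernel `z[j+-1] | z[j] ~ N(rho z[j], 1 - rho^2)`. By
#' construction the non-causal statistics given the causal one are
#' distributed exactly as under the null, which is the conditional
#' structure the pseudo-likelihood assumes.
#'
#' @param cfg a [sim_config()].
#' @return list with `data` (an [eqtl_summary]), `truth` (data frame with
#'   `is_null`, `causal_snp`, `effect`), and `config`.
#' @export
simulate_zstats <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  m <- .sim_m(cfg)
  truth <- .sim_truth(cfg, m)
  mmax <- max(m)
  N <- cfg$N
  rho <- cfg$rho
  sd1 <- sqrt(1 - rho^2)
  # anchor column: causal SNP for alternative genes, first SNP for nulls
  k <- ifelse(truth$is_null, 1L, truth$causal_snp)
  mu <- ifelse(truth$is_null, 0, truth$effect)
  Z <- matrix(NA_real_, N, mmax)
  Z[cbind(seq_len(N), k)] <- rnorm(N, mu, 1)
  for (j in seq_len(mmax)[-1L]) {               # extend rightwards
    rows <- which(k < j & m >= j)
    if (length(rows)) {
      Z[rows, j] <- rho * Z[rows, j - 1L] + sd1 * rnorm(length(rows))
    }
  }
  for (j in rev(seq_len(mmax - 1L))) {          # extend leftwards
    rows <- which(k > j)
    if (length(rows)) {
      Z[rows, j] <- rho * Z[rows, j + 1L] + sd1 * rnorm(length(rows))
    }
  }
  zlist <- if (length(unique(m)) == 1L) {
    Z
  } else {
    lapply(seq_len(N), function(i) Z[i, seq_len(m[i])])
  }
  data <- eqtl_summary(zlist, n = cfg$n)
  data$gene_ids <- truth$gene_id
  list(data = data, truth = truth, config = cfg)
}

#' Simulate LD-correlated genotype dosages
#'
#' Synthetic stand-in for real genotype matrices: per gene, two haplotypes
#' are generated from a latent Gaussian AR(1) process across SNPs
#' (correlation `rho`), thresholded at the allele-frequency quantile (MAF
#' drawn uniformly from `maf_range` per SNP) and summed, giving dosages in
#' {0, 1, 2} with Hardy-Weinberg marginals and LD that decays along the
#' SNP index. SNPs that come out monomorphic are regenerated (with a
#' fresh latent draw, so their LD with neighbours is broken - they are
#' rare for the default MAF range and sample sizes).
#'
#' @param cfg a [sim_config()].
#' @return list of `N` dosage matrices (SNPs x samples).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  m <- .sim_m(cfg)
  n <- cfg$n
  rho <- cfg$rho
  sd1 <- sqrt(1 - rho^2)
  lapply(seq_len(cfg$N), function(i) {
    mi <- m[i]
    draw <- function(rows) {
      L1 <- matrix(NA_real_, rows, mi)
      L2 <- matrix(NA_real_, rows, mi)
      L1[, 1L] <- rnorm(rows)
      L2[, 1L] <- rnorm(rows)
      if (mi > 1L) for (j in 2:mi) {
        L1[, j] <- rho * L1[, j - 1L] + sd1 * rnorm(rows)
        L2[, j] <- rho * L2[, j - 1L] + sd1 * rnorm(rows)
      }
      maf <- runif(mi, cfg$maf_range[1L], cfg$maf_range[2L])
      thr <- qnorm(maf)
      t((L1 < rep(thr, each = rows)) + (L2 < rep(thr, each = rows)))
    }
    G <- draw(n)
    for (tries in 1:20) {
      v <- apply(G, 1L, function(g) length(unique(g)))
      if (all(v > 1L)) break
      bad <- which(v == 1L)
      Gfresh <- draw(n)
      G[bad, ] <- Gfresh[bad, , drop = FALSE]
    }
    storage.mode(G) <- "double"
    rownames(G) <- paste0("gene", i, "_snp", seq_len(mi))
    G
  })
}

#' Simulate expression conditional on genotypes
#'
#' Three-step scheme: each gene is null with probability `pi0`; an
#' alternative gene draws a causal SNP uniformly and a Fisher-scale effect
#' `t ~ N(0, sigma^2)`, giving `beta = tanh(t / sqrt(n - 3))`, and its
#' expression is `N(beta x_k, 1 - beta^2)` elementwise with `x_k` the
#' standardized causal dosage row; null genes are i.i.d. `N(0, 1)`. The
#' unconditional variance of every expression row is 1 by construction.
#'
#' @param genotypes list of dosage matrices from [simulate_genotypes()]
#'   (or real data; rows are standardized internally).
#' @param cfg a [sim_config()]; note the seed is NOT re-set here when
#'   `genotypes` was just produced in the same stream - pass `seed = NULL`
#'   in that case, or distinct seeds for the two calls.
#' @return list with `data` (an `eqtl_full`), `truth`, and `config`.
#' @export
simulate_expression <- function(genotypes, cfg) {
  stopifnot(inherits(cfg, "sim_config"), is.list(genotypes),
            length(genotypes) == cfg$N)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n
  m <- vapply(genotypes, nrow, 0L)
  truth <- .sim_truth(cfg, m)
  Y <- matrix(NA_real_, cfg$N, n)
  for (i in seq_len(cfg$N)) {
    if (truth$is_null[i]) {
      Y[i, ] <- rnorm(n)
    } else {
      beta <- tanh(truth$effect[i] / sqrt(n - 3))
      xk <- genotypes[[i]][truth$causal_snp[i], ]
      xk <- (xk - mean(xk)) / sqrt(mean((xk - mean(xk))^2))
      Y[i, ] <- rnorm(n, beta * xk, sqrt(1 - beta^2))
    }
  }
  rownames(Y) <- truth$gene_id
  data <- full_dataset(Y, genotypes, gene_ids = truth$gene_id)
  list(data = data, truth = truth, config = cfg)
}
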