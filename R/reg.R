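# ---- full-data model -------------------------------------------------------
#
# Null:        Y_i ~ N_n(0, I)            (rows standardized).
# Alternative: Y_i | causal SNP j, beta ~ N_n(beta X_j, (1 - beta^2) I),
#              with sqrt(n-3) atanh(beta) ~ N(0, sigma^2).
# Everything needed from the data is the per-gene sufficient statistics
# (|Y|^2, Y.X_j, |X_j|^2); the genotype marginal cancels from the lfdr.

#' Sufficient statistics of one gene for the full-data model
#'
#' @param y expression vector for the gene (residualized, standardized).
#' @param x SNPs x samples genotype matrix for the gene (same treatment).
#' @return object of class `gene_stats`: `yy`, `yx`, `xx`, `n`, `m`.
#' @export
gene_stats <- function(y, x) {
  y <- as.numeric(y)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != length(y)) stop("y and x must share the sample dimension")
  s <- list(yy = sum(y * y), yx = unname(as.vector(x %*% y)),
            xx = unname(rowSums(x * x)), n = length(y), m = nrow(x))
  if (s$yy <= 0) stop("expression vector is identically zero")
  if (any(s$yx^2 > s$yy * s$xx * (1 + 1e-10))) {
    stop("inner products violate Cauchy-Schwarz; inputs are inconsistent")
  }
  structure(s, class = "gene_stats")
}

#' Conditional alternative log-density given the causal SNP and effect
#'
#' `log N_n(Y; beta X_j, (1 - beta^2) I)` evaluated from sufficient
#' statistics. At `beta = 0` this equals the null log-density
#' `-(n/2) log(2 pi) - |Y|^2 / 2`.
#'
#' @param stats a [gene_stats] object.
#' @param j SNP index within the gene.
#' @param beta effect-size correlation(s) in (-1, 1); may be a vector.
#' @return log-density value(s).
#' @export
log_f1_conditional <- function(stats, j, beta) {
  stopifnot(inherits(stats, "gene_stats"), j >= 1L, j <= stats$m)
  if (any(abs(beta) >= 1)) stop("|beta| must be < 1")
  n <- stats$n
  omb <- 1 - beta^2
  -(n / 2) * log(2 * pi) - (n / 2) * log(omb) -
    (stats$yy - 2 * beta * stats$yx[j] + beta^2 * stats$xx[j]) / (2 * omb)
}

# Gauss-Hermite nodes, cached by order
.gh_env <- new.env(parent = emptyenv())
.gh_nodes <- function(order) {
  key <- as.character(order)
  if (is.null(.gh_env[[key]])) {
    gh <- pracma::gaussHermite(order)
    .gh_env[[key]] <- list(x = gh$x, w = gh$w)
  }
  .gh_env[[key]]
}

# log(1 - tanh(t)^2) = -2 log cosh(t), computed without overflow
.log1m_tanh2 <- function(t) {
  a <- abs(t)
  -2 * (a + log1p(exp(-2 * a)) - log(2))
}

# Adaptive Gauss-Hermite rule for the Fisher-scale effect integral: nodes
# are centered at the Gaussian-product mode mu* = zhat sigma^2/(1+sigma^2)
# and scaled by s* = sigma/sqrt(1+sigma^2), because on the t scale the
# correlation likelihood is approximately N(zhat, 1). Prior-centered nodes
# would miss the likelihood peak once sigma is large.
.adaptive_gh_logvals <- function(zhat, sigma, n, quad_order) {
  gh <- .gh_nodes(quad_order)
  s2 <- sigma^2
  vstar <- s2 / (1 + s2)
  t <- zhat * vstar + sqrt(2 * vstar) * gh$x
  arg <- t / sqrt(n - 3)
  l1mb2 <- .log1m_tanh2(arg)
  list(t = t, beta = tanh(arg), l1mb2 = l1mb2,
       lw = log(gh$w) + gh$x^2 + 0.5 * log(2 * vstar) -
         0.5 * log(2 * pi) - log(sigma) - t^2 / (2 * s2))
}

#' Marginal alternative log-density with the random effect integrated out
#'
#' Integrates [log_f1_conditional()] over the effect-size prior by
#' substituting `beta = tanh(t / sqrt(n - 3))` with `t ~ N(0, sigma^2)`,
#' which turns the integral over `beta in (-1, 1)` into a Gauss-Hermite
#' quadrature in `t`; the node values are combined in log space. As
#' `sigma -> 0` the result decreases to the null log-density.
#'
#' @inheritParams log_f1_conditional
#' @param sigma positive SD of the Fisher-scale random effect.
#' @param quad_order number of quadrature nodes (>= 11; default 41).
#' @return the log marginal density `log f1(Y | X_j)`.
#' @export
log_f1_marginal <- function(stats, j, sigma, quad_order = 41L) {
  stopifnot(inherits(stats, "gene_stats"), sigma > 0)
  if (quad_order < 11L) stop("quad_order must be at least 11")
  n <- stats$n
  r <- .clamp(stats$yx[j] / sqrt(stats$yy * stats$xx[j]),
              -1 + 1e-12, 1 - 1e-12)
  nd <- .adaptive_gh_logvals(sqrt(n - 3) * atanh(r), sigma, n, quad_order)
  omb <- exp(nd$l1mb2)
  vals <- nd$lw - (n / 2) * log(2 * pi) - (n / 2) * nd$l1mb2 -
    (stats$yy - 2 * nd$beta * stats$yx[j] + nd$beta^2 * stats$xx[j]) / (2 * omb)
  vals[nd$l1mb2 < -700] <- -Inf
  out <- .logsumexp(vals)
  if (is.nan(out) || all(!is.finite(vals))) {
    stop("non-finite quadrature node at beta = ",
         nd$beta[which(!is.finite(vals))[1L]])
  }
  unname(out)
}

#' Gene-level lfdr from full data
#'
#' Posterior null probability of one gene under the full-data model:
#' `pi0 f0(Y) / (pi0 f0(Y) + (1 - pi0) mean_j f1(Y | X_j))`, with the
#' SNP average accumulated in log space. The genotype marginal cancels, so
#' no model for the SNPs is needed.
#'
#' @inheritParams log_f1_marginal
#' @param pi0 prior null probability.
#' @return value in `[0, 1]`; exactly `pi0` in the `sigma -> 0` limit.
#' @export
gene_lfdr_full <- function(stats, pi0, sigma, quad_order = 41L) {
  stopifnot(inherits(stats, "gene_stats"), pi0 >= 0, pi0 <= 1)
  if (pi0 == 1) return(1)
  logf0 <- -(stats$n / 2) * log(2 * pi) - stats$yy / 2
  lf1 <- vapply(seq_len(stats$m), function(j)
    log_f1_marginal(stats, j, sigma, quad_order), 0)
  lmr <- .logsumexp(lf1) - log(stats$m) - logf0
  .lfdr_from_lmr(pi0, lmr)[1L]
}

# ---- flat representation across genes for the EM ---------------------------

# rows standardized to mean 0, variance 1 (population 1/n convention)
.standardize_rows <- function(M) {
  M <- M - rowMeans(M)
  s <- sqrt(rowMeans(M * M))
  s[s < 1e-12] <- NA_real_
  M / s
}

.reg_flatten <- function(x, covariates) {
  Y <- .standardize_rows(residualize(x$expression, covariates))
  keep_gene <- !is.na(Y[, 1L])
  flat <- list()
  yx <- xx <- numeric(0)
  m <- integer(0)
  gid <- character(0)
  n <- x$n
  yx_list <- vector("list", nrow(Y))
  xx_list <- vector("list", nrow(Y))
  for (i in seq_len(nrow(Y))) {
    if (!keep_gene[i]) next
    G <- x$genotypes[[i]]
    if (anyNA(G)) {
      mu <- rowMeans(G, na.rm = TRUE)
      na <- which(is.na(G), arr.ind = TRUE)
      G[na] <- mu[na[, 1L]]
    }
    G <- .standardize_rows(residualize(G, covariates))
    ok <- !is.na(G[, 1L])
    if (!any(ok)) {
      keep_gene[i] <- FALSE
      next
    }
    G <- G[ok, , drop = FALSE]
    yxi <- as.vector(G %*% Y[i, ])
    # a perfectly correlated SNP makes the conditional density singular
    sane <- abs(yxi) < n * (1 - 1e-12)
    if (!any(sane)) {
      keep_gene[i] <- FALSE
      next
    }
    yx_list[[i]] <- yxi[sane]
    xx_list[[i]] <- rowSums(G * G)[sane]
    m <- c(m, sum(sane))
    gid <- c(gid, x$gene_ids[i])
  }
  if (sum(keep_gene) < length(keep_gene)) {
    warning("dropped ", sum(!keep_gene), " gene(s) with constant expression ",
            "or no usable SNPs")
  }
  yx <- unlist(yx_list[keep_gene], use.names = FALSE)
  xx <- unlist(xx_list[keep_gene], use.names = FALSE)
  list(yx = yx, xx = xx, m = m, gene = rep.int(seq_along(m), m),
       yy = rep.int(n, length(m)), n = n, gene_ids = gid)
}

# per-pair log(f1_marginal / f0) for all gene-SNP pairs at once; optionally
# also the posterior mean of t^2 (the squared Fisher-scale effect) per pair
.pair_pass <- function(flat, sigma, quad_order, want_et2 = FALSE) {
  gh <- .gh_nodes(quad_order)
  n <- flat$n
  yyg <- flat$yy[flat$gene]
  r <- .clamp(flat$yx / sqrt(yyg * flat$xx), -1 + 1e-12, 1 - 1e-12)
  zhat <- sqrt(n - 3) * atanh(r)
  # kernel works on the f1/f0 ratio scale: the (2 pi)^(n/2) factor cancels
  .reg_pair_pass(flat$yx, flat$xx, yyg, zhat, sigma, n,
                 gh$x, log(gh$w) + gh$x^2, want_et2)
}

.pair_logratio <- function(flat, sigma, quad_order) {
  .pair_pass(flat, sigma, quad_order)$rho
}

#' Fit the full-data mixture by EM
#'
#' Estimates `(pi0, sigma)` by an EM algorithm whose latent variables are
#' the gene's null indicator, its causal-SNP index, and the Fisher-scale
#' effect itself. The E-step computes each gene's posterior null
#' probability (its current lfdr), causal responsibilities proportional
#' to the per-SNP marginal densities, and the posterior mean of the
#' squared Fisher-scale effect per pair (all from one quadrature pass);
#' the M-step is then closed form - `pi0` becomes the mean posterior null
#' probability and `sigma^2` the responsibility-weighted mean of the
#' posterior squared effect, the standard variance-component update. Each
#' iteration is an exact EM step, so the composite log-likelihood never
#' decreases; this is asserted at every iteration.
#'
#' Expression and genotype rows are residualized against the covariates
#' and standardized to unit (population) variance first, so that the null
#' is `N_n(0, I)` and the effect is a correlation.
#'
#' @param x an `eqtl_full` dataset from [full_dataset()] or
#'   [simulate_expression()].
#' @param covariates optional covariates x samples matrix.
#' @param init optional `c(pi0, sigma)` initial values; by default the
#'   summary-statistic fit of [zreg_fdr()] on the same data provides a
#'   warm start.
#' @param quad_order Gauss-Hermite node count for the effect integral.
#' @param max_iter,tol EM iteration cap and absolute tolerance on the
#'   change in composite log-likelihood.
#' @return object of class `c("reg_fdr", "groupfdr_fit")`; `loglik` is the
#'   composite log-likelihood relative to the all-null model, `trace` its
#'   per-iteration values, `lfdr` the per-gene posterior null
#'   probabilities at the final parameters.
#' @export
reg_fdr <- function(x, covariates = NULL, init = NULL, quad_order = 41L,
                    max_iter = 100L, tol = 1e-6) {
  stopifnot(inherits(x, "eqtl_full"))
  if (quad_order < 11L) stop("quad_order must be at least 11")
  if (is.null(covariates)) covariates <- x$covariates
  flat <- .reg_flatten(x, covariates)
  n <- flat$n
  if (n < 4) stop("need at least 4 samples")

  if (is.null(init)) {
    r <- flat$yx / sqrt(flat$yy[flat$gene] * flat$xx)
    zfit <- zreg_fdr(eqtl_summary(fisher_z(r, n), gene_ids =
                                    flat$gene_ids[flat$gene], n = n),
                     compute_lfdr = FALSE)
    init <- coef(zfit)
  }
  pi0 <- .clamp(init[[1L]], .pi0_box[1L], .pi0_box[2L])
  sigma <- .clamp(init[[2L]], 0.05, .sigma_box[2L])

  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  lfdr <- NULL
  for (it in seq_len(max_iter)) {
    pass <- .pair_pass(flat, sigma, quad_order, want_et2 = TRUE)
    rho <- pass$rho
    lmr <- .group_log_mean_exp(rho, flat$m)
    ll <- sum(.log_mix(pi0, lmr))
    # the quadrature gives each iterate a ~1e-7-relative noise floor, so
    # exact monotonicity holds only up to that scale
    if (ll < ll_old - 1e-6 * (1 + abs(ll_old))) {
      stop("EM composite log-likelihood decreased (", ll_old, " -> ", ll,
           "); this indicates a bug")
    }
    trace <- c(trace, ll)
    # E-step
    lfdr <- .lfdr_from_lmr(pi0, lmr)
    wpair <- (1 - lfdr)[flat$gene] *
      exp(rho - (lmr + log(flat$m))[flat$gene])
    if (abs(ll - ll_old) < tol || ll < ll_old) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    # M-step (closed form)
    pi0 <- .clamp(mean(lfdr), .pi0_box[1L], .pi0_box[2L])
    sw <- sum(wpair)
    if (sw > 0) {
      sigma <- .clamp(sqrt(sum(wpair * pass$et2) / sw),
                      .sigma_box[1L], .sigma_box[2L])
    }
  }
  if (!converged) {
    warning("EM did not converge in ", max_iter,
            " iterations; returning the last iterate")
  }
  if (trace[length(trace)] <= 2) {
    # flat ridge: the mixture adds nothing over the all-null model
    pi0 <- .pi0_box[2L]
    sigma <- .sigma_box[1L]
    lfdr <- rep(pi0, length(lfdr))
    warning("effect-size signal indistinguishable from the null ",
            "(composite-likelihood improvement <= 2); reporting the ",
            "degenerate corner: pi0 at its upper bound, sigma at its ",
            "lower bound")
  } else if (pi0 >= 1 - .pi0_box[1L] * 1.05) {
    warning("pi0 estimate is at its upper bound: the data look all-null")
  }
  names(lfdr) <- flat$gene_ids

  structure(list(coefficients = c(pi0 = pi0, sigma = sigma),
                 loglik = trace[length(trace)],
                 null_loglik = sum(-(n / 2) * log(2 * pi) - flat$yy / 2),
                 trace = trace,
                 iterations = length(trace),
                 converged = converged,
                 lfdr = lfdr,
                 gene_ids = flat$gene_ids,
                 n_genes = length(flat$m),
                 n_pairs = length(flat$yx),
                 m = flat$m,
                 n = n,
                 quad_order = quad_order,
                 tol = tol,
                 method = "reg",
                 call = match.call()),
            class = c("reg_fdr", "groupfdr_fit"))
}
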