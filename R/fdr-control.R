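# ---- decision procedures ---------------------------------------------------

#' Adaptive lfdr thresholding
#'
#' Sorts the gene-level lfdr values ascending (stable, ties broken by
#' original index) and rejects the largest prefix whose running mean stays
#' at or below the target level `alpha`. The mean lfdr of the rejected set
#' estimates its FDR, so the procedure controls the gene-level FDR at
#' `alpha` when the lfdr values are (consistently estimated) posterior
#' null probabilities.
#'
#' @param lfdr numeric vector of lfdr values in `[0, 1]`.
#' @param alpha target FDR level in (0, 1).
#' @param gene_ids optional labels.
#' @param method tag recorded in the result.
#' @return object of class `fdr_discoveries`: `rejected` (original
#'   indices), `L`, `est_fdr` (running mean at L; 0 when L = 0), `alpha`.
#' @examples
#' fdr_reject(c(0.01, 0.02, 0.10, 0.30), 0.05)  # rejects 3 genes
#' @export
fdr_reject <- function(lfdr, alpha, gene_ids = NULL, method = "lfdr") {
  lfdr <- as.numeric(lfdr)
  if (any(!is.finite(lfdr)) || any(lfdr < 0) || any(lfdr > 1)) {
    stop("lfdr values must be finite and in [0, 1]")
  }
  stopifnot(length(alpha) == 1L, alpha > 0, alpha < 1)
  ord <- order(lfdr)                       # radix sort: stable in the index
  cmean <- cumsum(lfdr[ord]) / seq_along(ord)
  L <- max(0L, which(cmean <= alpha))   # running mean is nondecreasing
  rejected <- if (L > 0L) ord[seq_len(L)] else integer(0)
  structure(list(alpha = alpha,
                 rejected = rejected,
                 L = L,
                 est_fdr = if (L > 0L) cmean[L] else 0,
                 gene_ids = if (!is.null(gene_ids)) gene_ids[rejected] else NULL,
                 n = length(lfdr),
                 method = method),
            class = "fdr_discoveries")
}

#' @export
print.fdr_discoveries <- function(x, ...) {
  cat("Adaptive FDR thresholding (", x$method, "): ", x$L, " of ", x$n,
      " genes rejected at alpha = ", x$alpha, "\n", sep = "")
  if (x$L > 0L) {
    cat("  estimated FDR of the rejected set:",
        format(x$est_fdr, digits = 4), "\n")
  }
  invisible(x)
}

#' Bonferroni gene-level p-value
#'
#' @param pvec SNP-level p-values for one gene.
#' @return `min(1, m * min(pvec))`.
#' @export
bonferroni_gene_p <- function(pvec) {
  if (length(pvec) < 1L) stop("empty p-value vector")
  min(1, length(pvec) * min(pvec))
}

#' Simes gene-level p-value
#'
#' @param pvec SNP-level p-values for one gene.
#' @return `min_j m * p_(j) / j` over the sorted p-values.
#' @examples
#' simes_gene_p(c(0.01, 0.02, 0.9))  # 0.03
#' @export
simes_gene_p <- function(pvec) {
  if (length(pvec) < 1L) stop("empty p-value vector")
  m <- length(pvec)
  min(1, min(m * sort(pvec) / seq_len(m)))
}

#' Permutation min-p gene-level p-values
#'
#' The observed statistic for each gene is the smallest two-sided SNP-level
#' p-value (equivalently, the largest |correlation|); its null distribution
#' comes from permuting the sample labels of the expression row. One shared
#' permutation stream is used across genes (standard practice for gene-level
#' eQTL scans; much faster and valid because genes are judged marginally).
#' The reported p-value is `(1 + #(perm >= obs)) / (B + 1)` and is never 0.
#'
#' @param x an `eqtl_full` dataset.
#' @param B number of permutations (>= 100; values below 1000 give coarse
#'   p-value resolution and trigger a warning).
#' @param covariates optional covariate matrix.
#' @param seed optional integer seed for the permutation stream.
#' @return numeric vector of gene-level p-values.
#' @export
permutation_minp <- function(x, B = 1000L, covariates = NULL, seed = NULL) {
  stopifnot(inherits(x, "eqtl_full"))
  if (B < 100L) stop("B must be at least 100")
  if (B < 1000L) {
    warning("B = ", B, " gives p-value resolution ", signif(1 / (B + 1), 2),
            "; with thousands of simultaneous tests even 10,000 ",
            "permutations may be too few")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(covariates)) covariates <- x$covariates
  n <- x$n
  Y <- .standardize_rows(residualize(x$expression, covariates))
  permmat <- t(vapply(seq_len(B), function(b) sample.int(n), integer(n)))
  N <- nrow(Y)
  p <- numeric(N)
  for (i in seq_len(N)) {
    G <- .standardize_rows(residualize(x$genotypes[[i]], covariates))
    G <- G[!is.na(G[, 1L]), , drop = FALSE]
    if (nrow(G) == 0L || is.na(Y[i, 1L])) {
      p[i] <- NA_real_
      next
    }
    y <- Y[i, ]
    obs <- max(abs(as.vector(G %*% y))) / n
    yperm <- matrix(y[permmat], nrow = B)
    stat <- apply(abs(yperm %*% t(G)) / n, 1L, max)
    p[i] <- (1 + sum(stat >= obs)) / (B + 1)
  }
  p
}

#' Storey q-values with a fixed tuning parameter
#'
#' Estimates the null proportion from the upper tail of the p-value
#' distribution, `pi0 = min(1, #(p > lambda) / (N (1 - lambda)))`, and
#' returns `pi0` times the step-up (Benjamini-Hochberg) adjusted p-values.
#' With `pi0 = 1` the q-values reduce exactly to BH.
#'
#' @param pvec p-values.
#' @param lambda tuning point in (0, 1); default 0.5.
#' @return list with `pi0` and `qvalues` (monotone in p, capped at 1).
#' @export
storey_qvalue <- function(pvec, lambda = 0.5) {
  stopifnot(lambda > 0, lambda < 1)
  if (any(!is.finite(pvec)) || any(pvec < 0) || any(pvec > 1)) {
    stop("p-values must be finite and in [0, 1]")
  }
  N <- length(pvec)
  pi0 <- min(1, sum(pvec > lambda) / (N * (1 - lambda)))
  q <- pmin(1, pi0 * p.adjust(pvec, method = "BH"))
  list(pi0 = pi0, qvalues = q)
}

#' Calibrate the nominal FDR level of the lfdr pipeline
#'
#' Finds, by bisection over replicate simulations, the nominal level at
#' which the mean realized false discovery proportion of the
#' simulate-fit-threshold pipeline equals a target (the "adjusted"
#' variant used in power comparisons when the plug-in procedure is
#' slightly anti-conservative). The replicate ensemble (per-replicate
#' lfdr and truth) is built once and reused across bisection steps.
#'
#' @param config a [sim_config()] describing the study conditions.
#' @param target target mean FDP.
#' @param reps number of replicate datasets.
#' @param seed integer seed.
#' @param mode `"z"` for the serial-z scheme, `"full"` for the
#'   genotype-conditioned scheme.
#' @param tol calibration tolerance on the mean FDP.
#' @param ensemble optional precomputed list of `list(lfdr, is_null)`
#'   replicates, overriding the simulation.
#' @return the calibrated nominal level (a scalar in (0, 1)).
#' @export
calibrated_alpha <- function(config, target = 0.05, reps = 100L, seed = 1L,
                             mode = c("z", "full"), tol = 0.002,
                             ensemble = NULL) {
  mode <- match.arg(mode)
  if (is.null(ensemble)) {
    seeds <- .new_seed_stream(seed, reps)
    ensemble <- lapply(seq_len(reps), function(r) {
      cfg <- config
      cfg$seed <- seeds[r]
      if (mode == "z") {
        sim <- simulate_zstats(cfg)
        fit <- zreg_fdr(sim$data)
      } else {
        geno <- simulate_genotypes(cfg)
        sim <- simulate_expression(geno, cfg)
        fit <- zreg_fdr(compute_summary(sim$data))
      }
      list(lfdr = fitted(fit), is_null = sim$truth$is_null)
    })
  }
  mean_fdp <- function(a) {
    mean(vapply(ensemble, function(e) {
      rej <- fdr_reject(e$lfdr, a)
      if (rej$L == 0L) 0 else sum(e$is_null[rej$rejected]) / rej$L
    }, 0))
  }
  lo <- 1e-5
  hi <- min(0.8, 4 * target)
  if (mean_fdp(target) <= target + tol) {
    # already controlled at (or below) the nominal level
    a <- target
    if (mean_fdp(a) >= target - tol) return(a)
    lo <- target               # conservative: calibrate upward
  } else {
    hi <- target
  }
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    f <- mean_fdp(mid)
    if (abs(f - target) <= tol) return(mid)
    if (f > target) hi <- mid else lo <- mid
    if (hi - lo < 1e-6) break
  }
  (lo + hi) / 2
}
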