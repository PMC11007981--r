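#' Residualize rows of a matrix on covariates
#'
#' Replaces each row of `M` by its least-squares residual on an intercept
#' plus the covariate rows of `C`. With `C = NULL` (or zero rows) this is
#' plain row-centering. Expression and genotype matrices are residualized
#' separately against the same covariates before correlating, which is
#' equivalent to computing partial correlations.
#'
#' @param M numeric matrix, features x samples.
#' @param C numeric matrix of covariates, covariates x samples, or `NULL`.
#' @return matrix of the same shape as `M`; every row has mean zero.
#' @examples
#' M <- matrix(rnorm(30), 3)
#' C <- matrix(rnorm(10), 1)
#' rowMeans(residualize(M, C))  # ~ 0
#' @export
residualize <- function(M, C = NULL) {
  M <- as.matrix(M)
  storage.mode(M) <- "double"
  n <- ncol(M)
  if (is.null(C) || length(C) == 0L) {
    return(M - rowMeans(M))
  }
  C <- as.matrix(C)
  storage.mode(C) <- "double"
  if (nrow(C) == 0L) return(M - rowMeans(M))
  if (ncol(C) != n) {
    stop("covariates and data must share the sample dimension (",
         ncol(C), " vs ", n, ")")
  }
  cc <- nrow(C)
  if (n <= cc + 1L) {
    stop("need more samples (", n, ") than covariates plus intercept (",
         cc + 1L, ")")
  }
  if (is.null(rownames(C))) rownames(C) <- paste0("covariate", seq_len(cc))
  D <- cbind("(intercept)" = rep(1, n), t(C))
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- colnames(D)[qrD$pivot[seq.int(qrD$rank + 1L, ncol(D))]]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  t(qr.resid(qrD, t(M)))
}

#' Fisher-transformed, scaled correlation statistic
#'
#' Maps a Pearson correlation `r` observed on `n` samples to
#' `sqrt(n - 3) * atanh(r)`, which is approximately standard normal under
#' the null of no association and has approximately unit variance under the
#' alternative as well. `n` is not adjusted for covariates removed upstream;
#' for small samples with many covariates the null variance is slightly
#' underestimated.
#'
#' @param r correlation(s) in (-1, 1).
#' @param n sample size, at least 4.
#' @return numeric vector of z-statistics, same sign as `r`.
#' @examples
#' fisher_z(0.5, 103)  # 10 * atanh(0.5)
#' @export
fisher_z <- function(r, n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 4) {
    stop("n must be a single integer >= 4")
  }
  if (any(!is.finite(r))) stop("r must be finite")
  if (any(abs(r) >= 1)) {
    stop("|r| >= 1: perfect correlation has no finite Fisher statistic; ",
         "drop or jitter the offending pair")
  }
  sqrt(n - 3) * atanh(r)
}

#' Bundle full expression/genotype data for gene-level testing
#'
#' @param expression numeric matrix, genes x samples.
#' @param genotypes list of numeric matrices, one per gene, SNPs x samples
#'   (dosages or residualized values).
#' @param covariates optional covariates x samples matrix.
#' @param gene_ids,snp_ids optional labels; defaults come from dimnames.
#' @return an object of class `eqtl_full`.
#' @export
full_dataset <- function(expression, genotypes, covariates = NULL,
                         gene_ids = NULL, snp_ids = NULL) {
  expression <- as.matrix(expression)
  storage.mode(expression) <- "double"
  if (!is.list(genotypes)) genotypes <- list(genotypes)
  genotypes <- lapply(genotypes, function(g) {
    g <- as.matrix(g)
    storage.mode(g) <- "double"
    g
  })
  N <- nrow(expression)
  n <- ncol(expression)
  if (length(genotypes) != N) {
    stop("need one genotype matrix per gene (", N, " genes, ",
         length(genotypes), " matrices)")
  }
  for (i in seq_len(N)) {
    if (ncol(genotypes[[i]]) != n) {
      stop("genotype matrix for gene ", i, " has ", ncol(genotypes[[i]]),
           " samples; expression has ", n)
    }
    if (nrow(genotypes[[i]]) < 1L) stop("gene ", i, " has no SNPs")
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (ncol(covariates) != n) stop("covariates must have ", n, " samples")
  }
  if (is.null(gene_ids)) gene_ids <- rownames(expression)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(N))
  if (is.null(snp_ids)) {
    snp_ids <- lapply(seq_len(N), function(i) {
      ids <- rownames(genotypes[[i]])
      if (is.null(ids)) ids <- paste0(gene_ids[i], "_snp", seq_len(nrow(genotypes[[i]])))
      ids
    })
  }
  structure(list(expression = expression, genotypes = genotypes,
                 covariates = covariates, gene_ids = as.character(gene_ids),
                 snp_ids = snp_ids, n = n),
            class = "eqtl_full")
}

#' @export
print.eqtl_full <- function(x, ...) {
  cat("Full eQTL dataset:", length(x$gene_ids), "genes,",
      sum(vapply(x$genotypes, nrow, 0L)), "gene-SNP pairs,",
      x$n, "samples\n")
  if (!is.null(x$covariates)) cat("Covariates:", nrow(x$covariates), "\n")
  invisible(x)
}

#' Grouped z-statistic container
#'
#' Holds per-gene ragged vectors of Fisher-scaled z-statistics, the form of
#' summary data the pseudo-likelihood fit consumes. `z` may be a list of
#' numeric vectors (one per gene), a genes-by-SNPs matrix, a data frame with
#' columns `gene_id`, `z` (and optionally `snp_id`), or a flat numeric
#' vector accompanied by `gene_ids` of the same length giving group labels.
#'
#' @param z the z-statistics, in any of the layouts above.
#' @param gene_ids,snp_ids optional labels.
#' @param n the sample size the z-statistics were computed from (`NA` if
#'   unknown; it plays no role in the summary-level fit).
#' @return object of class `eqtl_summary` with fields `z` (flat numeric),
#'   `m` (group sizes), `gene` (group index per statistic), `gene_ids`,
#'   `snp_ids`, `n`.
#' @export
eqtl_summary <- function(z, gene_ids = NULL, snp_ids = NULL, n = NA_real_) {
  if (inherits(z, "eqtl_summary")) return(z)
  if (is.data.frame(z)) {
    if (!all(c("gene_id", "z") %in% names(z))) {
      stop("data frame input needs columns gene_id and z")
    }
    gene_ids <- as.character(z$gene_id)
    if (is.null(snp_ids) && "snp_id" %in% names(z)) snp_ids <- as.character(z$snp_id)
    z <- as.numeric(z$z)
  }
  if (is.matrix(z)) {
    ids <- rownames(z)
    m <- rep.int(ncol(z), nrow(z))
    flat <- as.numeric(t(z))
    gid <- if (!is.null(ids)) ids else paste0("gene", seq_len(nrow(z)))
  } else if (is.list(z)) {
    m <- lengths(z)
    flat <- as.numeric(unlist(z, use.names = FALSE))
    gid <- if (!is.null(names(z))) names(z) else paste0("gene", seq_along(z))
  } else {
    if (is.null(gene_ids) || length(gene_ids) != length(z)) {
      stop("a flat z vector needs gene_ids of the same length")
    }
    gid_levels <- unique(gene_ids)
    idx <- match(gene_ids, gid_levels)
    ord <- order(idx)          # stable: keeps file order within gene
    flat <- as.numeric(z)[ord]
    if (!is.null(snp_ids)) snp_ids <- snp_ids[ord]
    m <- tabulate(idx, nbins = length(gid_levels))
    gid <- as.character(gid_levels)
  }
  if (length(flat) == 0L) stop("no z-statistics supplied")
  if (any(!is.finite(flat))) stop("all z-statistics must be finite")
  if (any(m < 1L)) stop("every gene must retain at least one SNP")
  if (!is.na(n) && n < 4) stop("n must be >= 4 when z came from correlations")
  structure(list(z = flat, m = as.integer(m),
                 gene = rep.int(seq_along(m), m),
                 gene_ids = gid,
                 snp_ids = if (is.null(snp_ids)) NULL else as.character(snp_ids),
                 n = as.numeric(n)),
            class = "eqtl_summary")
}

#' @export
print.eqtl_summary <- function(x, ...) {
  cat("Grouped eQTL summary statistics\n")
  cat("  genes:", length(x$m), "  gene-SNP pairs:", length(x$z), "\n")
  cat("  SNPs per gene: min", min(x$m), "median", stats::median(x$m),
      "max", max(x$m), "\n")
  cat("  sample size n:", if (is.na(x$n)) "unknown" else x$n, "\n")
  invisible(x)
}

# coerce the layouts zreg_fdr accepts into eqtl_summary
.as_summary <- function(z, n = NA_real_) {
  if (inherits(z, "eqtl_summary")) z else eqtl_summary(z, n = n)
}

#' Compute grouped z-statistics from full data
#'
#' Residualizes expression and genotypes against the covariates (plain
#' centering when there are none), then converts each gene-SNP Pearson
#' correlation to a Fisher-scaled z-statistic. Missing genotype values are
#' mean-imputed per SNP before residualization. Monomorphic SNPs (constant
#' after residualization) and perfectly correlated SNPs are dropped with a
#' warning; a gene is dropped only when all of its SNPs are, or when its
#' expression row is constant.
#'
#' @param x an `eqtl_full` object from [full_dataset()].
#' @param covariates optional covariate matrix overriding `x$covariates`.
#' @return an [eqtl_summary] object.
#' @export
compute_summary <- function(x, covariates = NULL) {
  stopifnot(inherits(x, "eqtl_full"))
  if (is.null(covariates)) covariates <- x$covariates
  n <- x$n
  if (n < 4) stop("need at least 4 samples to Fisher-scale correlations")
  Y <- residualize(x$expression, covariates)
  N <- nrow(Y)
  zlist <- vector("list", N)
  snps <- vector("list", N)
  keep <- logical(N)
  dropped_snps <- 0L
  dropped_genes <- character(0)
  eps <- 1e-12
  for (i in seq_len(N)) {
    y <- Y[i, ]
    yy <- sum(y * y)
    if (yy <= eps * n) {
      dropped_genes <- c(dropped_genes, x$gene_ids[i])
      next
    }
    G <- x$genotypes[[i]]
    if (anyNA(G)) {
      mu <- rowMeans(G, na.rm = TRUE)
      na <- which(is.na(G), arr.ind = TRUE)
      G[na] <- mu[na[, 1L]]
      message("gene ", x$gene_ids[i], ": mean-imputed ", nrow(na),
              " missing genotype value(s)")
    }
    G <- residualize(G, covariates)
    xx <- rowSums(G * G)
    ok <- xx > eps * n
    if (!all(ok)) dropped_snps <- dropped_snps + sum(!ok)
    if (!any(ok)) {
      dropped_genes <- c(dropped_genes, x$gene_ids[i])
      next
    }
    G <- G[ok, , drop = FALSE]
    xx <- xx[ok]
    ids <- x$snp_ids[[i]][ok]
    r <- as.vector(G %*% y) / sqrt(xx * yy)
    sane <- abs(r) < 1 - 1e-12
    if (!all(sane)) dropped_snps <- dropped_snps + sum(!sane)
    if (!any(sane)) {
      dropped_genes <- c(dropped_genes, x$gene_ids[i])
      next
    }
    zlist[[i]] <- fisher_z(r[sane], n)
    snps[[i]] <- ids[sane]
    keep[i] <- TRUE
  }
  if (dropped_snps > 0L) {
    warning("dropped ", dropped_snps,
            " SNP(s): monomorphic or perfectly correlated with expression")
  }
  if (length(dropped_genes) > 0L) {
    warning("dropped ", length(dropped_genes),
            " gene(s) with no usable SNPs: ",
            paste(head(dropped_genes, 5L), collapse = ", "),
            if (length(dropped_genes) > 5L) ", ..." else "")
  }
  zlist <- zlist[keep]
  names(zlist) <- x$gene_ids[keep]
  eqtl_summary(zlist, snp_ids = unlist(snps[keep], use.names = FALSE), n = n)
}
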