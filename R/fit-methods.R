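# shared methods for the two fit classes

#' @export
print.groupfdr_fit <- function(x, digits = 4, ...) {
  cat(if (x$method == "zreg") "Summary-statistic (pseudo-likelihood)"
      else "Full-data (EM)",
      "grouped-eQTL mixture fit\n")
  cat("  genes:", x$n_genes, "  gene-SNP pairs:", x$n_pairs, "\n")
  cat("  pi0    =", format(x$coefficients[["pi0"]], digits = digits),
      " (prior null probability)\n")
  cat("  sigma  =", format(x$coefficients[["sigma"]], digits = digits),
      " (Fisher-scale effect SD)\n")
  cat("  log-likelihood (vs all-null):",
      format(x$loglik, digits = digits + 2), "\n")
  cat("  converged:", x$converged,
      if (length(x$boundary)) paste0(" [boundary: ",
                                     paste(x$boundary, collapse = ", "), "]")
      else "", "\n")
  invisible(x)
}

#' @export
coef.groupfdr_fit <- function(object, ...) object$coefficients

#' @export
logLik.groupfdr_fit <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = object$n_genes, class = "logLik")
}

#' @export
fitted.groupfdr_fit <- function(object, ...) object$lfdr

#' @export
summary.groupfdr_fit <- function(object, alpha = 0.05, ...) {
  out <- list(fit = object, alpha = alpha)
  if (!is.null(object$lfdr)) {
    out$lfdr_quantiles <- quantile(object$lfdr, c(0, .05, .25, .5, .75, 1))
    out$discoveries <- fdr_reject(object$lfdr, alpha,
                                  gene_ids = object$gene_ids)
  }
  structure(out, class = "summary.groupfdr_fit")
}

#' @export
print.summary.groupfdr_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$lfdr_quantiles)) {
    cat("\nlfdr quantiles:\n")
    print(round(x$lfdr_quantiles, 4))
    cat("\nAdaptive thresholding at FDR", x$alpha, ":",
        x$discoveries$L, "genes rejected (estimated FDR",
        format(x$discoveries$est_fdr, digits = 3), ")\n")
  }
  invisible(x)
}

#' lfdr for new summary data from a fitted mixture
#'
#' @param object a `zreg_fdr` fit.
#' @param newdata grouped z-statistics in any layout [eqtl_summary()]
#'   accepts; defaults to the training lfdr values.
#' @param ... unused.
#' @return named vector of gene-level lfdr values.
#' @export
predict.zreg_fdr <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$lfdr)
  d <- .as_summary(newdata)
  cf <- object$coefficients
  lmr <- .group_log_mean_exp(.log_ratio_terms(d$z, cf[["sigma"]]), d$m)
  out <- .lfdr_from_lmr(cf[["pi0"]], lmr)
  names(out) <- d$gene_ids
  out
}

#' Simulate grouped z-statistic datasets from a fitted mixture
#'
#' Draws new datasets from the fitted `(pi0, sigma)` using the serial-z
#' generator [simulate_zstats()]. Group sizes are taken from the fitted
#' data; `rho` defaults to independent statistics.
#'
#' @param object a `zreg_fdr` fit.
#' @param nsim number of datasets.
#' @param seed optional integer seed.
#' @param rho lag-1 serial correlation for the simulated statistics.
#' @param ... unused.
#' @return list of `nsim` simulation results (each with `data` and `truth`).
#' @export
simulate.zreg_fdr <- function(object, nsim = 1, seed = NULL, rho = 0, ...) {
  if (!is.null(seed)) set.seed(seed)
  cf <- object$coefficients
  m <- if (length(unique(object$m)) == 1L) object$m[1L] else range(object$m)
  lapply(seq_len(nsim), function(i) {
    simulate_zstats(sim_config(N = object$n_genes, m = m,
                               n = if (is.na(object$n)) 200 else object$n,
                               pi0 = cf[["pi0"]], sigma = cf[["sigma"]],
                               rho = rho))
  })
}

#' Diagnostic plot for a pseudo-likelihood fit
#'
#' Left: contour of the pseudo-log-likelihood per gene over a grid around
#' the estimate (the flat small-`sigma` ridge is usually visible). Right:
#' histogram of the gene-level lfdr values.
#'
#' @param x a `zreg_fdr` fit.
#' @param d the data the model was fitted to (needed for the surface);
#'   omit to plot only the lfdr histogram.
#' @param grid_points grid resolution per axis.
#' @param ... passed to [graphics::contour()].
#' @export
plot.zreg_fdr <- function(x, d = NULL, grid_points = 31L, ...) {
  op <- par(mfrow = c(1, if (is.null(d)) 1 else 2))
  on.exit(par(op))
  if (!is.null(d)) {
    d <- .as_summary(d)
    cf <- x$coefficients
    p_grid <- seq(max(0.02, cf[["pi0"]] - 0.15),
                  min(0.98, cf[["pi0"]] + 0.15), length.out = grid_points)
    s_grid <- seq(max(0.05, cf[["sigma"]] * 0.5), cf[["sigma"]] * 1.5,
                  length.out = grid_points)
    surf <- outer(p_grid, s_grid,
                  Vectorize(function(p, s) pseudo_loglik(d, p, s)))
    contour(p_grid, s_grid, surf / length(d$m), nlevels = 25,
            xlab = expression(pi[0]), ylab = expression(sigma),
            main = "pseudo-log-likelihood / gene", ...)
    points(cf[["pi0"]], cf[["sigma"]], pch = 3, col = 2, lwd = 2)
  }
  if (!is.null(x$lfdr)) {
    hist(x$lfdr, breaks = 40, main = "gene-level lfdr", xlab = "lfdr")
  }
  invisible(x)
}
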