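# ---- two-group mixture on the z-statistic scale ----------------------------
#
# Null:        z ~ N(0, 1).
# Alternative: z ~ N(mu, 1) with mu ~ N(0, sigma^2), so marginally
#              z ~ N(0, 1 + sigma^2).
# The density ratio p1/p0 therefore has the closed form
#   (1 + sigma^2)^(-1/2) * exp(z^2 sigma^2 / (2 (1 + sigma^2))).

.log_ratio_terms <- function(z, sigma) {
  s2 <- sigma * sigma
  z * z * (s2 / (2 * (1 + s2))) - 0.5 * log1p(s2)
}

#' Alternative/null density ratio for a z-statistic
#'
#' Ratio of the marginal alternative density (normal with the random effect
#' integrated out, i.e. `N(0, 1 + sigma^2)`) to the standard normal null
#' density. Computed in log space and exponentiated; symmetric in `z`.
#'
#' @param z numeric vector of z-statistics.
#' @param sigma non-negative SD of the Fisher-scale random effect.
#' @return positive numeric vector, `1` everywhere when `sigma = 0`.
#' @examples
#' alt_null_ratio(0, 1)   # 1/sqrt(2)
#' alt_null_ratio(3, 2)   # 5^(-1/2) * exp(3.6)
#' @export
alt_null_ratio <- function(z, sigma) {
  stopifnot(length(sigma) == 1L, is.finite(sigma), sigma >= 0)
  if (any(!is.finite(z))) stop("z must be finite")
  exp(.log_ratio_terms(z, sigma))
}

#' Gene-level local false discovery rate from a z-vector
#'
#' Posterior probability that a gene is null given its vector of SNP-level
#' z-statistics, under the single-causal-SNP mixture:
#' `1 / (1 + ((1 - pi0)/pi0) * mean_k p1(z_k)/p0(z_k))`. The average over
#' SNPs is accumulated in log space; the result is symmetric in the order
#' of the SNPs and strictly decreasing in each `|z_k|` when `sigma > 0`.
#'
#' @param zvec numeric vector of z-statistics for one gene (length >= 1).
#' @param pi0 prior null probability.
#' @param sigma random-effect SD.
#' @return a value in `[0, 1]`.
#' @examples
#' gene_lfdr(0, pi0 = 0.5, sigma = 1)  # 1/(1 + 1/sqrt(2))
#' @export
gene_lfdr <- function(zvec, pi0, sigma) {
  if (length(zvec) < 1L) stop("zvec must contain at least one z-statistic")
  stopifnot(length(pi0) == 1L, pi0 >= 0, pi0 <= 1,
            length(sigma) == 1L, sigma >= 0)
  if (any(!is.finite(zvec))) stop("zvec must be finite")
  lmr <- .logsumexp(.log_ratio_terms(zvec, sigma)) - log(length(zvec))
  .lfdr_from_lmr(pi0, lmr)[1L]
}

#' Pseudo-log-likelihood of the grouped z-statistic mixture
#'
#' The sum over genes of
#' `log(pi0 + (1 - pi0) * mean_k p1(z_k)/p0(z_k))`, i.e. the log of the
#' likelihood ratio of the two-group mixture to the all-null model. The
#' shared conditional density of the non-causal statistics cancels from the
#' ratio, so only `pi0` and `sigma` remain.
#'
#' @param d grouped z-statistics in any layout [eqtl_summary()] accepts.
#' @param pi0 prior null probability.
#' @param sigma random-effect SD.
#' @return a finite scalar.
#' @export
pseudo_loglik <- function(d, pi0, sigma) {
  d <- .as_summary(d)
  stopifnot(length(pi0) == 1L, pi0 >= 0, pi0 <= 1,
            length(sigma) == 1L, is.finite(sigma), sigma >= 0)
  pi0 <- .clamp(pi0, .pi0_box[1L], .pi0_box[2L])
  ll <- .zreg_obj_grad(d$z^2, d$m, pi0, sigma)[1L]
  if (!is.finite(ll)) {
    lmr <- .group_log_mean_exp(.log_ratio_terms(d$z, sigma), d$m)
    bad <- which(!is.finite(.log_mix(pi0, lmr)))[1L]
    stop("non-finite pseudo-log-likelihood contribution from gene ",
         d$gene_ids[bad])
  }
  ll
}

# method-of-moments start: pi0 from the fraction of |z| > 2 in excess of the
# null rate, sigma from the excess second moment of z
.mom_start <- function(d) {
  f0 <- 2 * pnorm(-2)
  exc <- mean(abs(d$z) > 2)
  mbar <- mean(d$m)
  # a causal statistic with moderate sigma lands beyond |2| roughly half
  # the time; treat the excess exceedance as (1 - pi0)/m * (0.5 - f0)
  palt <- max(exc - f0, 0) / (0.5 - f0)
  pi0_s <- .clamp(1 - mbar * palt, 0.05, 0.95)
  s2 <- mbar * max(mean(d$z^2) - 1, 0.01) / max(1 - pi0_s, 0.05)
  c(pi0_s, .clamp(sqrt(s2), 0.05, .sigma_box[2L]))
}

#' Fit the summary-statistic (pseudo-likelihood) mixture
#'
#' Maximizes the pseudo-log-likelihood of [pseudo_loglik()] over
#' `(pi0, sigma)` by quasi-Newton search with analytic gradients on
#' transformed coordinates (logit `pi0`, log `sigma`), inside the box
#' `pi0 in [1e-6, 1 - 1e-6]`, `sigma in [1e-4, 50]`. Several starting
#' points are used by default - `(0.5, 1)`, `(0.5, 3)` and a
#' method-of-moments start - because the objective has a flat ridge at
#' small `sigma` where the null and alternative components are hard to
#' separate; the best converged optimum is returned.
#'
#' @param z grouped z-statistics: an [eqtl_summary], a genes-by-SNPs
#'   matrix, a list of per-gene vectors, or a data frame with columns
#'   `gene_id` and `z`.
#' @param n sample size behind the z-statistics (optional; recorded only).
#' @param starts optional matrix or list of `(pi0, sigma)` starting values
#'   replacing the defaults.
#' @param tol relative convergence tolerance on the objective.
#' @param max_iter iteration cap per start.
#' @param compute_lfdr compute per-gene lfdr values at the optimum.
#' @return an object of class `c("zreg_fdr", "groupfdr_fit")` with
#'   components `coefficients` (named `pi0`, `sigma`), `loglik`,
#'   `converged`, `gradient_norm`, `lfdr`, `gene_ids`, `n_genes`,
#'   `boundary`, and the table of evaluated `starts`.
#' @examples
#' sim <- simulate_zstats(sim_config(N = 500, m = 10, pi0 = 0.2, sigma = 4,
#'                                   rho = 0.1, seed = 1))
#' fit <- zreg_fdr(sim$data)
#' coef(fit)
#' @export
zreg_fdr <- function(z, n = NULL, starts = NULL, tol = 1e-9,
                     max_iter = 500L, compute_lfdr = TRUE) {
  d <- .as_summary(z, n = if (is.null(n)) NA_real_ else n)
  z2 <- d$z^2
  m <- d$m

  if (is.null(starts)) {
    starts <- rbind(c(0.5, 1), c(0.5, 3), .mom_start(d))
  } else {
    if (is.list(starts)) starts <- do.call(rbind, starts)
    starts <- matrix(as.numeric(starts), ncol = 2L)
  }
  starts[, 1L] <- .clamp(starts[, 1L], .pi0_box[1L] * 10, 1 - .pi0_box[1L] * 10)
  starts[, 2L] <- .clamp(starts[, 2L], .sigma_box[1L] * 10, .sigma_box[2L] / 2)

  last <- new.env(parent = emptyenv())
  fn <- function(th) {
    r <- .zreg_obj_grad(z2, m, plogis(th[1L]), exp(th[2L]))
    last$th <- th
    last$r <- r
    -r[1L]
  }
  gr <- function(th) {
    if (is.null(last$th) || !identical(last$th, th)) fn(th)
    r <- last$r
    p <- plogis(th[1L])
    s <- exp(th[2L])
    -c(r[2L] * p * (1 - p), r[3L] * s)
  }
  lower <- c(qlogis(.pi0_box[1L]), log(.sigma_box[1L]))
  upper <- c(qlogis(.pi0_box[2L]), log(.sigma_box[2L]))

  runs <- vector("list", nrow(starts))
  for (s in seq_len(nrow(starts))) {
    th0 <- c(qlogis(starts[s, 1L]), log(starts[s, 2L]))
    runs[[s]] <- tryCatch(
      nlminb(th0, fn, gr, lower = lower, upper = upper,
             control = list(rel.tol = tol, iter.max = max_iter,
                            eval.max = 4L * max_iter)),
      error = function(e) e)
  }
  ok <- !vapply(runs, inherits, TRUE, what = "error")
  if (!any(ok)) {
    stop("all optimizer starts failed: ",
         paste(vapply(runs, conditionMessage, ""), collapse = "; "))
  }
  obj <- vapply(runs[ok], function(r) r$objective, 0)
  best <- runs[ok][[which.min(obj)]]
  pi0_hat <- plogis(best$par[1L])
  sigma_hat <- exp(best$par[2L])
  grad <- gr(best$par)
  converged <- best$convergence == 0L

  boundary <- character(0)
  if (-best$objective <= 2) {
    # the mixture improves on the all-null model by less than its two
    # parameters are worth: the likelihood ridge {sigma = 0} u {pi0 = 1} is
    # the effective optimum; report its canonical corner
    boundary <- c(boundary, "degenerate")
    pi0_hat <- .pi0_box[2L]
    sigma_hat <- .sigma_box[1L]
    warning("effect-size signal indistinguishable from the null ",
            "(pseudo-likelihood improvement <= 2); reporting the ",
            "degenerate corner: pi0 at its upper bound, sigma at its ",
            "lower bound")
  } else {
    if (sigma_hat <= .sigma_box[1L] * 1.05) {
      boundary <- c(boundary, "sigma_lower")
      warning("sigma estimate is at its lower bound: the effect-size ",
              "signal is indistinguishable from the null")
    }
    if (pi0_hat >= 1 - .pi0_box[1L] * 1.05) {
      boundary <- c(boundary, "pi0_upper")
      warning("pi0 estimate is at its upper bound: the data look all-null")
    }
  }
  if (!converged) {
    warning("optimizer did not report convergence: ", best$message)
  }

  lfdr <- NULL
  if (compute_lfdr) {
    lmr <- .group_log_mean_exp(.log_ratio_terms(d$z, sigma_hat), d$m)
    lfdr <- .lfdr_from_lmr(pi0_hat, lmr)
    names(lfdr) <- d$gene_ids
  }

  colnames(starts) <- c("pi0", "sigma")
  structure(list(coefficients = c(pi0 = pi0_hat, sigma = sigma_hat),
                 loglik = -best$objective,
                 converged = converged,
                 gradient_norm = sqrt(sum(grad^2)),
                 message = best$message,
                 lfdr = lfdr,
                 gene_ids = d$gene_ids,
                 n_genes = length(d$m),
                 n_pairs = length(d$z),
                 m = d$m,
                 n = d$n,
                 boundary = boundary,
                 starts = starts,
                 tol = tol,
                 method = "zreg",
                 call = match.call()),
            class = c("zreg_fdr", "groupfdr_fit"))
}

#' Per-gene lfdr table for given mixture parameters
#'
#' Applies [gene_lfdr()] to every gene of a grouped summary dataset.
#'
#' @inheritParams pseudo_loglik
#' @param method tag recorded in the result (`"zreg"` or `"reg"`).
#' @return data frame with columns `gene_id` and `lfdr`, with the
#'   parameters attached as attributes.
#' @export
lfdr_table <- function(d, pi0, sigma, method = "zreg") {
  d <- .as_summary(d)
  lmr <- .group_log_mean_exp(.log_ratio_terms(d$z, sigma), d$m)
  out <- data.frame(gene_id = d$gene_ids,
                    lfdr = .lfdr_from_lmr(pi0, lmr),
                    stringsAsFactors = FALSE)
  attr(out, "pi0") <- pi0
  attr(out, "sigma") <- sigma
  attr(out, "method") <- method
  out
}
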