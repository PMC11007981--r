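# ---- replicate experiments and operating characteristics -------------------

#' Realized false discovery proportion
#'
#' @param rej an `fdr_discoveries` object (or a vector of rejected gene
#'   indices).
#' @param truth truth table with logical column `is_null` (as produced by
#'   the simulators).
#' @return fraction of rejections that are null genes; 0 when nothing is
#'   rejected.
#' @export
realized_fdp <- function(rej, truth) {
  idx <- if (inherits(rej, "fdr_discoveries")) rej$rejected else as.integer(rej)
  if (length(idx) == 0L) return(0)
  sum(truth$is_null[idx]) / length(idx)
}

#' Realized power (true positive rate among alternative genes)
#'
#' @inheritParams realized_fdp
#' @return fraction of alternative genes rejected; 0 when there are none.
#' @export
detection_power <- function(rej, truth) {
  idx <- if (inherits(rej, "fdr_discoveries")) rej$rejected else as.integer(rej)
  n_alt <- sum(!truth$is_null)
  if (n_alt == 0L) return(0)
  sum(!truth$is_null[idx]) / n_alt
}

#' Replicate study of the summary-statistic pipeline
#'
#' For each cell of a `(pi0, sigma, rho)` grid: simulate grouped
#' z-statistics, fit the pseudo-likelihood mixture, apply adaptive
#' thresholding at each level, and record the parameter estimates and the
#' realized FDP and power. Per-replicate seeds are derived from `seed`
#' once, so results do not depend on evaluation order.
#'
#' @param cells data frame with columns `pi0`, `sigma`, `rho` (one row per
#'   study cell).
#' @param reps replicates per cell.
#' @param N,m,n simulation dimensions (see [sim_config()]).
#' @param alphas FDR levels to threshold at.
#' @param seed integer seed.
#' @param oracle use the true `(pi0, sigma)` instead of fitting (for
#'   checking the thresholding rule itself).
#' @param verbose print a line per cell.
#' @return object of class `oc_study`: `per_rep` (list of per-cell data
#'   frames) and `summary` (one row per cell with means and SDs).
#' @export
run_table1 <- function(cells, reps = 200L, N = 10000L, m = 30L, n = 200L,
                       alphas = c(0.05, 0.10), seed = 1L, oracle = FALSE,
                       verbose = FALSE) {
  cells <- as.data.frame(cells)
  stopifnot(all(c("pi0", "sigma", "rho") %in% names(cells)))
  ncell <- nrow(cells)
  seeds <- matrix(.new_seed_stream(seed, ncell * reps), nrow = reps)
  per_rep <- vector("list", ncell)
  for (ci in seq_len(ncell)) {
    rows <- vector("list", reps)
    for (r in seq_len(reps)) {
      cfg <- sim_config(N = N, m = m, n = n, pi0 = cells$pi0[ci],
                        sigma = cells$sigma[ci], rho = cells$rho[ci],
                        seed = seeds[r, ci])
      sim <- simulate_zstats(cfg)
      if (oracle) {
        tab <- lfdr_table(sim$data, cells$pi0[ci], cells$sigma[ci])
        est <- c(pi0 = cells$pi0[ci], sigma = cells$sigma[ci])
        lf <- tab$lfdr
        conv <- TRUE
      } else {
        fit <- suppressWarnings(zreg_fdr(sim$data))
        est <- coef(fit)
        lf <- fitted(fit)
        conv <- fit$converged
      }
      met <- unlist(lapply(alphas, function(a) {
        rej <- fdr_reject(lf, a)
        c(realized_fdp(rej, sim$truth), detection_power(rej, sim$truth))
      }))
      names(met) <- as.vector(rbind(paste0("fdp_", alphas),
                                    paste0("power_", alphas)))
      rows[[r]] <- c(pi0_hat = unname(est[1L]), sigma_hat = unname(est[2L]),
                     converged = as.numeric(conv), met)
    }
    per_rep[[ci]] <- as.data.frame(do.call(rbind, rows))
    if (verbose) {
      cat(sprintf("cell (pi0=%.2f, sigma=%g, rho=%.2f): mean pi0_hat=%.4f, mean sigma_hat=%.4f\n",
                  cells$pi0[ci], cells$sigma[ci], cells$rho[ci],
                  mean(per_rep[[ci]]$pi0_hat), mean(per_rep[[ci]]$sigma_hat)))
    }
  }
  summ <- do.call(rbind, lapply(seq_len(ncell), function(ci) {
    pr <- per_rep[[ci]]
    out <- cells[ci, , drop = FALSE]
    for (col in names(pr)) {
      out[[paste0("mean_", col)]] <- mean(pr[[col]])
      out[[paste0("sd_", col)]] <- sd(pr[[col]])
    }
    out
  }))
  rownames(summ) <- NULL
  structure(list(cells = cells, per_rep = per_rep, summary = summ,
                 reps = reps, N = N, m = m, n = n, alphas = alphas,
                 oracle = oracle, seed = seed),
            class = "oc_study")
}

#' @export
print.oc_study <- function(x, ...) {
  cat("Operating-characteristic study:", x$reps, "replicates/cell, N =",
      x$N, "genes, m =", paste(x$m, collapse = "-"), "SNPs/gene",
      if (x$oracle) "(oracle parameters)" else "", "\n")
  cols <- c("pi0", "sigma", "rho", "mean_pi0_hat", "mean_sigma_hat",
            grep("^mean_fdp", names(x$summary), value = TRUE))
  print(x$summary[, cols], digits = 4)
  invisible(x)
}

#' Power comparison of gene-level testing pipelines
#'
#' On genotype-conditioned simulations, compares (i) the lfdr pipeline,
#' (ii) its calibrated variant whose nominal level is tuned so the mean
#' realized FDP equals the target, (iii) permutation min-p followed by
#' Storey q-values, and (iv) Bonferroni gene p-values followed by Storey
#' q-values. All methods are run on the same replicate datasets.
#'
#' @param config a [sim_config()] (its `seed` is ignored; per-replicate
#'   seeds derive from `seed`).
#' @param reps number of replicate datasets.
#' @param alpha target FDR level.
#' @param B permutations per replicate.
#' @param seed integer seed.
#' @return object of class `power_comparison`: `per_rep` (data frame) and
#'   `summary` (mean power and FDP per method), plus the calibrated level.
#' @export
run_power_comparison <- function(config, reps = 20L, alpha = 0.05, B = 500L,
                                 seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- .new_seed_stream(seed, reps)
  keep <- list()
  for (r in seq_len(reps)) {
    cfg <- config
    cfg$seed <- seeds[r]
    geno <- simulate_genotypes(cfg)
    cfg2 <- cfg
    cfg2$seed <- NULL                    # continue the same RNG stream
    sim <- simulate_expression(geno, cfg2)
    summ <- suppressWarnings(compute_summary(sim$data))
    fit <- suppressWarnings(zreg_fdr(summ))
    perm_p <- suppressWarnings(permutation_minp(sim$data, B = B))
    # per-SNP two-sided normal p-values -> Bonferroni per gene
    pz <- 2 * pnorm(-abs(summ$z))
    bonf_p <- vapply(split(pz, summ$gene), bonferroni_gene_p, 0)
    # align on the genes the summary step retained (drops are rare)
    idx <- match(summ$gene_ids, sim$truth$gene_id)
    keep[[r]] <- list(lfdr = fitted(fit), truth = sim$truth[idx, ],
                      perm_q = storey_qvalue(perm_p[idx])$qvalues,
                      bonf_q = storey_qvalue(bonf_p)$qvalues)
  }
  ensemble <- lapply(keep, function(e)
    list(lfdr = e$lfdr, is_null = e$truth$is_null))
  alpha_cal <- calibrated_alpha(config, target = alpha, ensemble = ensemble)
  rows <- lapply(keep, function(e) {
    rej_z <- fdr_reject(e$lfdr, alpha)
    rej_a <- fdr_reject(e$lfdr, alpha_cal)
    perm_idx <- which(e$perm_q <= alpha)
    bonf_idx <- which(e$bonf_q <= alpha)
    c(power_zreg = detection_power(rej_z, e$truth),
      fdp_zreg = realized_fdp(rej_z, e$truth),
      power_zreg_adj = detection_power(rej_a, e$truth),
      fdp_zreg_adj = realized_fdp(rej_a, e$truth),
      power_perm = detection_power(perm_idx, e$truth),
      fdp_perm = realized_fdp(perm_idx, e$truth),
      power_bonf = detection_power(bonf_idx, e$truth),
      fdp_bonf = realized_fdp(bonf_idx, e$truth))
  })
  per_rep <- as.data.frame(do.call(rbind, rows))
  structure(list(per_rep = per_rep,
                 summary = colMeans(per_rep),
                 alpha = alpha, alpha_calibrated = alpha_cal,
                 config = config, reps = reps, B = B, seed = seed),
            class = "power_comparison")
}

#' @export
print.power_comparison <- function(x, ...) {
  cat("Power comparison at target FDR", x$alpha, "(", x$reps,
      "replicates; calibrated nominal level",
      format(x$alpha_calibrated, digits = 3), ")\n")
  print(round(x$summary, 4))
  invisible(x)
}

#' Expected pseudo-log-likelihood surface
#'
#' Monte-Carlo estimate of the expected pseudo-log-likelihood per gene:
#' datasets are simulated at the true `(pi0, sigma)` and the
#' pseudo-log-likelihood is averaged over them at every grid point. For a
#' correctly specified model the surface peaks at the truth; this is the
#' standard diagnostic that the pseudo-likelihood is a sound estimating
#' function under the serial-z scheme.
#'
#' @param pi0,sigma true parameter values used for simulation.
#' @param pi0_grid,sigma_grid evaluation grids.
#' @param mc_datasets number of Monte-Carlo datasets.
#' @param N,m,n,rho simulation dimensions.
#' @param seed integer seed.
#' @return object of class `pll_surface`: `surface` (matrix, rows =
#'   `pi0_grid`), the grids, and `argmax` (the grid point with the
#'   largest average).
#' @export
pseudo_loglik_surface <- function(pi0 = 0.2, sigma = 3,
                                  pi0_grid = seq(0.05, 0.5, by = 0.05),
                                  sigma_grid = seq(1, 5, by = 0.5),
                                  mc_datasets = 20L, N = 2000L, m = 30L,
                                  n = 200L, rho = 0.1, seed = 1L) {
  seeds <- .new_seed_stream(seed, mc_datasets)
  acc <- matrix(0, length(pi0_grid), length(sigma_grid))
  for (b in seq_len(mc_datasets)) {
    sim <- simulate_zstats(sim_config(N = N, m = m, n = n, pi0 = pi0,
                                      sigma = sigma, rho = rho,
                                      seed = seeds[b]))
    d <- sim$data
    z2 <- d$z^2
    for (i in seq_along(pi0_grid)) {
      for (j in seq_along(sigma_grid)) {
        acc[i, j] <- acc[i, j] +
          .zreg_obj_grad(z2, d$m, pi0_grid[i], sigma_grid[j])[1L]
      }
    }
  }
  surf <- acc / (mc_datasets * N)
  am <- which(surf == max(surf), arr.ind = TRUE)[1L, ]
  structure(list(surface = surf, pi0_grid = pi0_grid,
                 sigma_grid = sigma_grid,
                 argmax = c(pi0 = pi0_grid[am[1L]],
                            sigma = sigma_grid[am[2L]]),
                 truth = c(pi0 = pi0, sigma = sigma),
                 mc_datasets = mc_datasets, N = N, m = m, rho = rho),
            class = "pll_surface")
}

#' @export
print.pll_surface <- function(x, ...) {
  cat("Expected pseudo-log-likelihood surface (", x$mc_datasets,
      " Monte-Carlo datasets, N = ", x$N, ")\n", sep = "")
  cat("  truth:  pi0 =", x$truth[["pi0"]], " sigma =", x$truth[["sigma"]], "\n")
  cat("  argmax: pi0 =", x$argmax[["pi0"]], " sigma =", x$argmax[["sigma"]], "\n")
  invisible(x)
}

#' @export
plot.pll_surface <- function(x, nlevels = 30, ...) {
  contour(x$pi0_grid, x$sigma_grid, x$surface, nlevels = nlevels,
          xlab = expression(pi[0]), ylab = expression(sigma), ...)
  points(x$truth[["pi0"]], x$truth[["sigma"]], pch = 3, col = 2, lwd = 2)
  points(x$argmax[["pi0"]], x$argmax[["sigma"]], pch = 1, col = 4, lwd = 2)
  invisible(x)
}
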