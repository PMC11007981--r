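# ---- TSV / JSON contracts --------------------------------------------------
#
# Canonical dialect: tab-separated, UTF-8, header row, no quoting, numeric
# values written with %.10g. '#' comment lines are permitted before the
# header only.

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, header = TRUE, sep = "\t", quote = "",
             comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Read grouped summary statistics from TSV
#'
#' Expects columns `gene_id`, `snp_id`, and either `z` or `p` (optionally
#' with `sign`). p-values are converted through the two-sided standard
#' normal quantile, `|z| = qnorm(p/2, lower.tail = FALSE)`; an absent sign
#' column yields `|z|`, which is sufficient because the mixture is
#' symmetric. Rows are grouped by gene preserving file order within genes.
#'
#' @param path TSV file path.
#' @return an [eqtl_summary] object.
#' @export
read_summary <- function(path) {
  tab <- .read_tsv(path)
  if (nrow(tab) == 0L) stop("empty summary file: ", path)
  if (!all(c("gene_id", "snp_id") %in% names(tab))) {
    stop("summary TSV needs columns gene_id and snp_id")
  }
  if ("z" %in% names(tab)) {
    z <- suppressWarnings(as.numeric(tab$z))
    if (anyNA(z)) {
      stop("non-numeric z value at line ", which(is.na(z))[1L] + 1L)
    }
  } else if ("p" %in% names(tab)) {
    p <- suppressWarnings(as.numeric(tab$p))
    if (anyNA(p)) stop("non-numeric p value at line ", which(is.na(p))[1L] + 1L)
    if (any(p <= 0)) {
      stop("p = 0 at line ", which(p <= 0)[1L] + 1L,
           ": apply a floor (e.g. half the smallest attainable p) first")
    }
    if (any(p > 1)) stop("p > 1 at line ", which(p > 1)[1L] + 1L)
    z <- qnorm(p / 2, lower.tail = FALSE)
    if ("sign" %in% names(tab)) z <- z * sign(as.numeric(tab$sign))
  } else {
    stop("summary TSV needs a z column or a p column")
  }
  eqtl_summary(z, gene_ids = as.character(tab$gene_id),
               snp_ids = as.character(tab$snp_id))
}

#' Write grouped summary statistics to TSV
#'
#' @param d an [eqtl_summary] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(d, path) {
  d <- .as_summary(d)
  snp <- if (is.null(d$snp_ids)) {
    unlist(lapply(seq_along(d$m), function(i) paste0("snp", seq_len(d$m[i]))))
  } else d$snp_ids
  lines <- c("gene_id\tsnp_id\tz",
             sprintf("%s\t%s\t%.10g", d$gene_ids[d$gene], snp, d$z))
  writeLines(lines, path)
  invisible(path)
}

#' Read a features-by-samples TSV matrix
#'
#' First column = feature ID, remaining header = sample IDs.
#' @param path TSV file path.
#' @return numeric matrix with feature rownames.
#' @export
read_matrix_tsv <- function(path) {
  tab <- .read_tsv(path)
  M <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- as.character(tab[[1L]])
  M
}

#' @rdname read_matrix_tsv
#' @param M numeric matrix (features x samples).
#' @param id_col name for the feature-ID column.
#' @export
write_matrix_tsv <- function(M, path, id_col = "feature_id") {
  samples <- colnames(M)
  if (is.null(samples)) samples <- paste0("sample", seq_len(ncol(M)))
  header <- paste(c(id_col, samples), collapse = "\t")
  body <- vapply(seq_len(nrow(M)), function(i) {
    paste(c(rownames(M)[i], sprintf("%.10g", M[i, ])), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Assemble a full dataset from TSV files
#'
#' @param expr_path expression matrix TSV (genes x samples).
#' @param geno_path genotype dosage matrix TSV (SNPs x samples).
#' @param map_path two-column TSV (`gene_id`, `snp_id`) defining the
#'   gene-SNP grouping.
#' @param covar_path optional covariate matrix TSV.
#' @return an `eqtl_full` object restricted to mapped genes.
#' @export
read_full_dataset <- function(expr_path, geno_path, map_path,
                              covar_path = NULL) {
  expr <- read_matrix_tsv(expr_path)
  geno <- read_matrix_tsv(geno_path)
  map <- .read_tsv(map_path)
  if (!all(c("gene_id", "snp_id") %in% names(map))) {
    stop("map TSV needs columns gene_id and snp_id")
  }
  missing_snp <- setdiff(map$snp_id, rownames(geno))
  if (length(missing_snp)) {
    stop("SNPs in map but not in genotypes: ",
         paste(head(missing_snp, 5L), collapse = ", "))
  }
  genes <- unique(map$gene_id)
  genes <- genes[genes %in% rownames(expr)]
  if (length(genes) == 0L) stop("no mapped gene is present in the expression matrix")
  genolist <- lapply(genes, function(g) {
    snps <- map$snp_id[map$gene_id == g]
    geno[snps, , drop = FALSE]
  })
  covar <- if (!is.null(covar_path)) read_matrix_tsv(covar_path) else NULL
  full_dataset(expr[genes, , drop = FALSE], genolist, covariates = covar,
               gene_ids = genes)
}

#' Write fitted mixture parameters as JSON
#'
#' @param fit a `groupfdr_fit` object.
#' @param path output path.
#' @export
write_params_json <- function(fit, path) {
  stopifnot(inherits(fit, "groupfdr_fit"))
  obj <- list(pi0 = unname(fit$coefficients[["pi0"]]),
              sigma = unname(fit$coefficients[["sigma"]]),
              loglik = fit$loglik,
              n_genes = fit$n_genes,
              converged = fit$converged,
              method = fit$method,
              package_version = as.character(utils::packageVersion("groupfdr")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @return `read_params_json` returns the parameter list.
#' @export
read_params_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write the per-gene lfdr / rejection table
#'
#' Columns: `gene_id`, `lfdr` (`%.10g`), `rank` (1..N by ascending lfdr,
#' ties by original order), `rejected` (0/1). Deterministic byte-for-byte
#' for identical inputs.
#'
#' @param lfdr named numeric vector of gene-level lfdr values (or an
#'   [lfdr_table()] data frame).
#' @param rej an `fdr_discoveries` object from [fdr_reject()] on the same
#'   lfdr vector (optional; omitting it writes `rejected = 0`).
#' @param path output path.
#' @export
write_results <- function(lfdr, rej = NULL, path) {
  if (is.data.frame(lfdr)) {
    ids <- lfdr$gene_id
    lf <- lfdr$lfdr
  } else {
    ids <- names(lfdr)
    if (is.null(ids)) ids <- paste0("gene", seq_along(lfdr))
    lf <- as.numeric(lfdr)
  }
  rk <- integer(length(lf))
  rk[order(lf)] <- seq_along(lf)
  rejected <- integer(length(lf))
  if (!is.null(rej)) rejected[rej$rejected] <- 1L
  lines <- c("gene_id\tlfdr\trank\trejected",
             sprintf("%s\t%.10g\t%d\t%d", ids, lf, rk, rejected))
  writeLines(lines, path)
  invisible(path)
}
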