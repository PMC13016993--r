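# Genome-wide single-marker association scan: MAF filtering, genotype
# principal components as population-structure covariates, per-marker OLS
# with a t-test on the dosage effect, Bonferroni thresholding, and
# candidate-gene window extraction around significant markers.
#
# This scan is a transparent PC-adjusted OLS. It deliberately does not
# reimplement multi-stage mixed-model methods (e.g. FarmCPU); kinship-aware
# scanning is out of scope, and every results header records the scan
# method used.

#' Subset a genotype matrix to selected markers
#'
#' @param G a `genotype_matrix`.
#' @param idx integer/logical index or marker ids.
#' @return a `genotype_matrix` with the selected markers.
#' @export
subset_markers <- function(G, idx) {
  if (is.character(idx)) {
    miss <- setdiff(idx, G$markers$id)
    if (length(miss) > 0)
      stop("marker id(s) not found: ", paste(miss, collapse = ", "))
    idx <- match(idx, G$markers$id)
  }
  genotype_matrix(G$dosages[, idx, drop = FALSE],
                  G$markers[idx, , drop = FALSE])
}

#' Per-marker minor allele frequency
#'
#' Computed from non-missing dosages as `min(f, 1 - f)` with
#' `f = mean(dosage) / 2`.
#'
#' @param G a `genotype_matrix`.
#' @return named numeric vector of MAFs.
#' @export
marker_maf <- function(G) {
  f <- colMeans(G$dosages, na.rm = TRUE) / 2
  stats::setNames(pmin(f, 1 - f), G$markers$id)
}

#' Exclude markers below a minor-allele-frequency cutoff
#'
#' Markers with MAF strictly below `cutoff` are removed; a marker exactly at
#' the cutoff is retained.
#'
#' @param G a `genotype_matrix`.
#' @param cutoff MAF cutoff (default 0.03).
#' @return filtered `genotype_matrix`; attribute `n_removed` counts the
#'   excluded markers.
#' @export
maf_filter <- function(G, cutoff = 0.03) {
  maf <- marker_maf(G)
  keep <- maf >= cutoff
  if (!any(keep)) stop("all markers fall below the MAF cutoff")
  out <- subset_markers(G, which(keep))
  attr(out, "n_removed") <- sum(!keep)
  out
}

# Mean-imputed, accession x marker dosage matrix.
impute_dosages <- function(G) {
  X <- G$dosages
  mode(X) <- "double"
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas) > 0) {
    cm <- colMeans(X, na.rm = TRUE)
    X[nas] <- cm[nas[, 2]]
  }
  X
}

#' Genotype principal components
#'
#' Scores from the singular value decomposition of the column-centered
#' (optionally standardized) dosage matrix, missing dosages mean-imputed per
#' marker. Signs follow a deterministic convention: within each component
#' the largest-magnitude loading is positive.
#'
#' @param G a `genotype_matrix`.
#' @param k number of components (default 3).
#' @param standardize divide each marker column by its SD (default FALSE).
#' @return accession x k score matrix with attribute `variance_explained`
#'   (proportion per retained component).
#' @export
genotype_pcs <- function(G, k = 3, standardize = FALSE) {
  n <- n_accessions(G)
  if (k >= n) stop("k must be smaller than the number of accessions")
  X <- impute_dosages(G)
  X <- scale(X, center = TRUE, scale = standardize)
  X[is.nan(X)] <- 0  # zero-variance markers under standardization
  sv <- svd(X, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(k)], k, k), 2, flip, `*`)
  dimnames(scores) <- list(rownames(G$dosages), paste0("PC", seq_len(k)))
  attr(scores, "variance_explained") <- (sv$d^2 / sum(sv$d^2))[seq_len(k)]
  scores
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate in (0, 1) (default 0.05).
#' @param n_markers number of tested markers.
#' @return `alpha / n_markers`; attribute `printed` carries the
#'   3-significant-figure rendering.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_markers) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_markers < 1) stop("n_markers must be at least 1")
  x <- alpha / n_markers
  attr(x, "printed") <- signif(x, 3)
  x
}

#' Single-marker association scan with PC covariates
#'
#' For each marker, ordinary least squares of the phenotype on (intercept,
#' the k PC covariates, dosage); the reported p-value is the two-sided
#' t-test on the dosage coefficient with n - k - 2 degrees of freedom.
#' Missing dosages are mean-imputed per marker at scan time only.
#' Zero-variance markers get beta = 0, p = 1 and a flag.
#'
#' @param G a `genotype_matrix` (MAF-filter first; the threshold uses the
#'   number of markers actually tested).
#' @param y named numeric vector of accession-level phenotype values (e.g.
#'   mixed-model predictions); names are matched against `G`'s accessions
#'   and the scan runs on the intersection.
#' @param pcs PC score matrix from [genotype_pcs()], or NULL for no
#'   structure correction.
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param trait trait name recorded in the result.
#' @return object of class `gwas_result`: list with `table` (per marker:
#'   id, chrom, pos, maf, beta, se, p, zero_variance flag),
#'   `n_markers_tested`, `alpha`, `threshold`, `covariates`, `trait`,
#'   `n_accessions_used`.
#' @export
single_marker_scan <- function(G, y, pcs = NULL, alpha = 0.05,
                               trait = "trait") {
  if (is.null(names(y))) stop("y must be named by accession id")
  common <- intersect(rownames(G$dosages), names(y))
  if (length(common) < 10)
    stop("fewer than 10 accessions shared between genotypes and phenotypes")
  X <- impute_dosages(G)[common, , drop = FALSE]
  yv <- y[common]
  k <- 0L
  C <- matrix(1, nrow = length(common), ncol = 1)
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    if (is.null(rownames(pcs))) stop("pcs must be named by accession id")
    C <- cbind(C, pcs[common, , drop = FALSE])
    k <- ncol(pcs)
  }
  n <- length(common)
  df <- n - k - 2L
  if (df < 1) stop("not enough accessions for the covariate set")

  qrC <- qr(C)
  yr <- qr.resid(qrC, yv)
  Xr <- qr.resid(qrC, X)
  sxx <- colSums(Xr^2)
  syy <- sum(yr^2)
  zero <- sxx < 1e-10
  beta <- ifelse(zero, 0, colSums(Xr * yr) / sxx)
  ssr <- pmax(syy - beta^2 * sxx, 0)
  se <- ifelse(zero, NA_real_, sqrt(ssr / df / sxx))
  tstat <- ifelse(zero, 0, beta / se)
  p <- ifelse(zero, 1, 2 * stats::pt(-abs(tstat), df))

  tab <- data.frame(id = G$markers$id, chrom = G$markers$chrom,
                    pos = G$markers$pos, maf = unname(marker_maf(G)),
                    beta = unname(beta), se = unname(se), p = unname(p),
                    zero_variance = unname(zero), stringsAsFactors = FALSE)
  structure(list(table = tab,
                 n_markers_tested = nrow(tab),
                 alpha = alpha,
                 threshold = as.numeric(bonferroni_threshold(alpha, nrow(tab))),
                 covariates = paste0(k, " PCs"),
                 trait = trait,
                 n_accessions_used = n),
            class = "gwas_result")
}

#' @method print gwas_result
#' @export
print.gwas_result <- function(x, ...) {
  nsig <- sum(x$table$p < x$threshold)
  cat("PC-adjusted single-marker scan for", x$trait, "\n")
  cat(sprintf("  %d markers tested on %d accessions (%s)\n",
              x$n_markers_tested, x$n_accessions_used, x$covariates))
  cat(sprintf("  Bonferroni threshold %.3g (alpha = %g): %d significant\n",
              x$threshold, x$alpha, nsig))
  invisible(x)
}

#' Significant markers of a scan
#'
#' @param result a `gwas_result`.
#' @return the rows of the scan table with `p < threshold`.
#' @export
significant_markers <- function(result) {
  stopifnot(inherits(result, "gwas_result"))
  result$table[result$table$p < result$threshold, , drop = FALSE]
}

#' Q-Q diagnostic table for scan p-values
#'
#' @param p vector of p-values.
#' @return data.frame of `expected` and `observed` -log10(p) quantiles,
#'   sorted ascending.
#' @export
qq_table <- function(p) {
  p <- sort(p[!is.na(p)])
  n <- length(p)
  data.frame(expected = -log10((seq_len(n) - 0.5) / n),
             observed = -log10(p))
}

#' Genes within a window around a marker
#'
#' Returns the genes whose 1-based inclusive span overlaps
#' `[pos - half_width, pos + half_width]` on the marker's chromosome; a gene
#' touching the window boundary counts as overlapping. Chromosome names are
#' normalized for matching (leading Chr/chr stripped).
#'
#' @param genes gene table from [read_gff3_genes()].
#' @param chrom,pos marker chromosome and position.
#' @param half_width window half-width in bp (default 75,000).
#' @return the overlapping gene rows in position order, with a `distance`
#'   column (0 when the marker lies inside the gene). Unknown chromosome
#'   gives an empty table with a warning.
#' @export
candidate_window <- function(genes, chrom, pos, half_width = 75000) {
  gn <- normalize_chrom(genes$chrom)
  cn <- normalize_chrom(chrom)
  if (!cn %in% gn) {
    warning("chromosome ", chrom, " not present in gene table")
    return(genes[0, , drop = FALSE])
  }
  lo <- pos - half_width
  hi <- pos + half_width
  hit <- gn == cn & genes$start <= hi & genes$end >= lo
  out <- genes[hit, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  out$distance <- pmax(0L, out$start - pos, pos - out$end)
  out
}
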