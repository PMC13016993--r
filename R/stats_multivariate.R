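# Descriptive and multivariate trait statistics: CV and adjusted
# Fisher-Pearson skewness, pairwise Pearson correlations with significance,
# trait-space PCA on the correlation matrix, and trait clustering in the
# retained PC space.

#' Descriptive statistics of a trait
#'
#' @param values numeric vector, n >= 3 (NAs dropped).
#' @return list: `n`, `mean`, `sd`, `cv` (percent, `NA` with flag
#'   `cv_undefined` when the mean is 0), `skewness` (adjusted
#'   Fisher-Pearson, i.e. the sample-size-corrected G1 estimator).
#' @export
descriptive_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3) stop("at least 3 values are required")
  m <- mean(values)
  s <- stats::sd(values)
  cv_undef <- m == 0
  list(n = length(values), mean = m, sd = s,
       cv = if (cv_undef) NA_real_ else 100 * s / m,
       cv_undefined = cv_undef,
       skewness = e1071::skewness(values, type = 2))
}

#' Pairwise Pearson correlation matrix with p-values
#'
#' Correlations use pairwise-complete observations; p-values come from the
#' t-distribution with n - 2 degrees of freedom per pair. Constant columns
#' give `NA` correlations and are flagged.
#'
#' @param traits numeric matrix or data.frame, accessions x traits.
#' @return list: `r`, `p`, `n` (matrices with unit/zero/NA diagonal
#'   conventions: r diagonal 1, p diagonal 0), `constant` (logical per
#'   trait).
#' @export
correlation_matrix <- function(traits) {
  M <- as.matrix(traits)
  if (ncol(M) < 2) stop("at least 2 traits are required")
  k <- ncol(M)
  cn <- colnames(M)
  const <- apply(M, 2, function(x) stats::sd(x, na.rm = TRUE) == 0 ||
                   all(is.na(x)))
  r <- suppressWarnings(stats::cor(M, use = "pairwise.complete.obs"))
  n <- crossprod(!is.na(M))
  r[const, ] <- NA; r[, const] <- NA
  diag(r) <- ifelse(const, NA, 1)
  tstat <- r * sqrt(pmax(n - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), pmax(n - 2, 1))
  p[n < 3] <- NA
  diag(p) <- ifelse(const, NA, 0)
  dimnames(r) <- dimnames(p) <- dimnames(n) <- list(cn, cn)
  list(r = r, p = p, n = n, constant = const)
}

#' Principal component analysis of the trait matrix
#'
#' Complete-case eigen-decomposition of the correlation matrix
#' (`standardize = TRUE`, the default) or covariance matrix. Component signs
#' follow a deterministic convention (largest-magnitude loading positive).
#'
#' @param traits numeric matrix or data.frame, accessions x traits.
#' @param standardize scale traits to unit variance (default TRUE).
#' @return list of class `trait_pca`: `scores` (accessions x PCs),
#'   `loadings` (traits x PCs), `var_pct` (percent variance per PC, sums to
#'   100), `sdev`, `n_used`.
#' @export
pca_traits <- function(traits, standardize = TRUE) {
  M <- as.matrix(traits)
  cc <- stats::complete.cases(M)
  if (sum(cc) < nrow(M))
    warning(sum(!cc), " incomplete accession(s) dropped for PCA")
  M <- M[cc, , drop = FALSE]
  if (nrow(M) < 3) stop("fewer than 3 complete cases")
  pc <- stats::prcomp(M, center = TRUE, scale. = standardize)
  k <- ncol(pc$rotation)
  flip <- vapply(seq_len(k), function(j) {
    v <- pc$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 var_pct = 100 * pc$sdev^2 / sum(pc$sdev^2),
                 sdev = pc$sdev, n_used = nrow(M)),
            class = "trait_pca")
}

#' Cluster traits in the retained PC space
#'
#' Places each trait at its loading coordinates scaled by the component
#' standard deviations, over the first `n_pcs` components, and clusters by
#' Ward-linkage agglomerative clustering (default) or k-means.
#'
#' @param pca a `trait_pca`.
#' @param k number of clusters (default 3).
#' @param n_pcs PC coordinates used (default 2).
#' @param method `"ward"` (hierarchical, Euclidean, Ward.D2 linkage;
#'   deterministic) or `"kmeans"` (set the RNG seed for reproducibility).
#' @return named integer vector: cluster index per trait.
#' @export
cluster_traits <- function(pca, k = 3, n_pcs = 2,
                           method = c("ward", "kmeans")) {
  stopifnot(inherits(pca, "trait_pca"))
  method <- match.arg(method)
  n_traits <- nrow(pca$loadings)
  if (k < 2) stop("k must be at least 2")
  if (k > n_traits) stop("k cannot exceed the number of traits")
  n_pcs <- min(n_pcs, ncol(pca$loadings))
  coords <- pca$loadings[, seq_len(n_pcs), drop = FALSE] %*%
    diag(pca$sdev[seq_len(n_pcs)], n_pcs, n_pcs)
  if (method == "ward") {
    hc <- stats::hclust(stats::dist(coords), method = "ward.D2")
    stats::cutree(hc, k = k)
  } else {
    km <- stats::kmeans(coords, centers = k, nstart = 25)
    stats::setNames(km$cluster, rownames(coords))
  }
}
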