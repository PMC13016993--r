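# Independent oracles and tiny fixture builders used across the suite.

# Brute-force anatomical conductance oracle, done entirely in SI units from
# the raw field-unit inputs; independent of the package's implementation.
oracle_gsw_max_si <- function(SD_mm2, PAmax_um2, GCW_um,
                              d = 0.0000249, v = 0.0245) {
  SD_m2 <- SD_mm2 * 1000 * 1000        # 1 mm^-2 = 1e6 m^-2
  PA_m2 <- PAmax_um2 / 1e6 / 1e6       # 1 um^2 = 1e-12 m^2
  l_m <- (GCW_um / 2) / 1e6            # pore depth = GCW/2, um -> m
  (d * SD_m2 * PA_m2) / (v * (l_m + (pi / 2) * sqrt(PA_m2 / pi)))
}

# Closed-form REML estimators for a balanced one-way random-effects layout
# (a accessions x r replicates): sigma2_e = MSE, sigma2_a = (MSB - MSE)/r.
oracle_balanced_reml <- function(y, accession) {
  acc <- factor(accession)
  a <- nlevels(acc)
  r <- length(y) / a
  gm <- mean(y)
  means <- tapply(y, acc, mean)
  msb <- r * sum((means - gm)^2) / (a - 1)
  mse <- sum((y - means[acc])^2) / (a * (r - 1))
  c(sigma2_accession = (msb - mse) / r, sigma2_residual = mse)
}

# One-way ANOVA F statistic from the definitional sums of squares.
oracle_anova_f <- function(values, groups) {
  g <- factor(groups)
  k <- nlevels(g)
  n <- length(values)
  gm <- mean(values)
  means <- tapply(values, g, mean)
  ssb <- sum(table(g) * (means - gm)^2)
  ssw <- sum((values - means[g])^2)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Adjusted Fisher-Pearson skewness from the definitional formula.
oracle_skewness_adj <- function(x) {
  n <- length(x)
  m <- mean(x)
  g1 <- (sum((x - m)^3) / n) / (sum((x - m)^2) / n)^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

# Tiny genotype matrix built directly from a dosage matrix.
make_G <- function(dosages, chrom = "Chr01", pos = NULL,
                   ref = NULL, alt = NULL) {
  m <- ncol(dosages)
  if (is.null(pos)) pos <- seq(100L, by = 100L, length.out = m)
  if (is.null(ref)) ref <- rep("C", m)
  if (is.null(alt)) alt <- rep("T", m)
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("acc%02d", seq_len(nrow(dosages)))
  genotype_matrix(dosages,
                  data.frame(id = sprintf("m%02d", seq_len(m)),
                             chrom = chrom, pos = pos, ref = ref, alt = alt,
                             stringsAsFactors = FALSE))
}

# Inbred panel with one marker of given allele frequency plus fillers.
random_panel <- function(n, m, maf = NULL, seed = 1) {
  set.seed(seed)
  f <- if (is.null(maf)) stats::runif(m, 0.05, 0.5) else rep(maf, m)
  dos <- vapply(f, function(fi) 2L * stats::rbinom(n, 1L, fi), integer(n))
  rownames(dos) <- sprintf("acc%03d", seq_len(n))
  make_G(dos)
}

write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  path
}

vcf_fixture <- function(path, records,
                        samples = c("acc1", "acc2")) {
  head <- c("##fileformat=VCFv4.2", "##contig=<ID=Chr01>",
            paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", samples), collapse = "\t"))
  write_lines_lf(c(head, records), path)
}
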