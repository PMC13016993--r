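test_that("MAF filter excludes strictly-below-cutoff markers", {
  n <- 1000
  freqs <- c(0.02, 0.03, 0.10, 0.25, 0.01, 0.40, 0.029, 0.05, 0.5, 0.35)
  dos <- vapply(freqs, function(f) {
    d <- integer(n)
    d[seq_len(round(f * n))] <- 2L
    d
  }, integer(n))
  rownames(dos) <- sprintf("a%03d", 1:n)
  G <- make_G(dos)
  Gf <- maf_filter(G, 0.03)
  maf <- marker_maf(G)
  expect_equal(n_markers(Gf), sum(maf >= 0.03))
  expect_equal(n_markers(Gf), 7)           # 3 of 10 fall below 3%
  expect_false("m05" %in% Gf$markers$id)   # f = 0.01 removed
  expect_true("m02" %in% Gf$markers$id)    # f = 0.03 exactly retained
  expect_equal(attr(Gf, "n_removed"), 3)
  expect_error(maf_filter(G, 0.9), "below")
})

test_that("Bonferroni threshold is alpha over markers, printed to 3 s.f.", {
  th <- bonferroni_threshold(0.05, 234264)
  expect_equal(attr(th, "printed"), 2.13e-7)
  expect_equal(as.numeric(bonferroni_threshold(0.05, 1)), 0.05)
  expect_equal(as.numeric(bonferroni_threshold(0.05, 2000)), 2.5e-5)
  expect_equal(as.numeric(th) * 234264, 0.05)
})

test_that("genotype PCs are deterministic and separate structure", {
  G <- random_panel(30, 50, seed = 2)
  G$dosages[2, ] <- G$dosages[1, ]  # two identical accessions
  pcs <- genotype_pcs(G, k = 3)
  expect_equal(pcs[1, ], pcs[2, ], tolerance = 1e-10)
  expect_true(all(diff(attr(pcs, "variance_explained")) <= 1e-12))
  expect_identical(pcs, genotype_pcs(G, k = 3))
  expect_error(genotype_pcs(G, k = 30), "smaller")

  # two allele-frequency-differentiated clusters: PC1 separates with AUC >= .95
  set.seed(77)
  n <- 60; m <- 80
  fA <- stats::runif(m, 0.1, 0.4)
  fB <- pmin(0.9, fA + 0.4)
  dos <- rbind(vapply(fA, function(f) 2L * stats::rbinom(n / 2, 1, f), integer(n / 2)),
               vapply(fB, function(f) 2L * stats::rbinom(n / 2, 1, f), integer(n / 2)))
  rownames(dos) <- sprintf("a%02d", 1:n)
  pc1 <- genotype_pcs(make_G(dos), k = 2)[, 1]
  grp <- rep(c(0, 1), each = n / 2)
  auc <- (mean(rank(pc1)[grp == 1]) - (n / 2 + 1) / 2) / (n / 2)
  expect_gte(max(auc, 1 - auc), 0.95)
})

test_that("scan coefficients agree with per-marker lm fits", {
  G <- random_panel(80, 12, seed = 5)
  set.seed(6)
  y <- stats::setNames(0.4 * G$dosages[, 3] + stats::rnorm(80),
                       rownames(G$dosages))
  pcs <- genotype_pcs(G, k = 3)
  res <- single_marker_scan(G, y, pcs)
  for (j in c(1, 3, 7)) {
    ref <- summary(stats::lm(y ~ pcs + G$dosages[, j]))$coefficients
    expect_equal(res$table$beta[j], ref[5, "Estimate"], tolerance = 1e-10)
    expect_equal(res$table$se[j], ref[5, "Std. Error"], tolerance = 1e-10)
    expect_equal(res$table$p[j], ref[5, "Pr(>|t|)"], tolerance = 1e-10)
  }
  expect_equal(res$threshold * res$n_markers_tested, res$alpha)
})

test_that("a near-noiseless causal marker is estimated and detected", {
  G <- random_panel(100, 10, maf = 0.3, seed = 8)
  set.seed(9)
  y <- stats::setNames(0.5 * G$dosages[, 4] + stats::rnorm(100, 0, 1e-6),
                       rownames(G$dosages))
  res <- single_marker_scan(G, y, pcs = NULL)
  expect_equal(res$table$beta[4], 0.5, tolerance = 1e-4)
  expect_lt(res$table$p[4], 1e-10)
})

test_that("zero-variance and missing dosages are handled at scan time", {
  G <- random_panel(50, 6, seed = 10)
  G$dosages[, 2] <- 0L                       # monomorphic
  G$dosages[c(3, 9, 20), 5] <- NA            # missing, mean-imputed
  set.seed(11)
  y <- stats::setNames(stats::rnorm(50), rownames(G$dosages))
  res <- single_marker_scan(G, y)
  expect_true(res$table$zero_variance[2])
  expect_equal(res$table$beta[2], 0)
  expect_equal(res$table$p[2], 1)
  expect_false(any(is.na(res$table$p)))
})

test_that("PC adjustment is near-neutral on a structure-free panel", {
  G <- random_panel(200, 60, seed = 12)
  set.seed(13)
  y <- stats::setNames(stats::rnorm(200), rownames(G$dosages))
  b0 <- single_marker_scan(G, y, pcs = NULL)$table$beta
  b3 <- single_marker_scan(G, y, pcs = genotype_pcs(G, 3))$table$beta
  expect_gt(stats::cor(b0, b3), 0.99)
  expect_lt(max(abs(b0 - b3)), 0.1)
})

test_that("candidate windows use inclusive 75 kb overlap", {
  pos <- 1000000L
  genes <- data.frame(
    gene_id = paste0("g", 1:5),
    chrom = "Chr01",
    start = c(pos - 80000L, pos - 74000L, pos + 75000L, pos + 80001L, pos - 200L),
    end   = c(pos - 76000L, pos - 70000L, pos + 76000L, pos + 90000L, pos + 200L),
    strand = "+", stringsAsFactors = FALSE)
  hits <- candidate_window(genes, "Chr01", pos)
  expect_equal(hits$gene_id, c("g2", "g5", "g3"))  # position order
  expect_equal(hits$distance[hits$gene_id == "g5"], 0L)
  expect_equal(hits$distance[hits$gene_id == "g3"], 75000L)
  # touching the boundary counts; fully beyond 75 kb does not
  expect_false("g1" %in% hits$gene_id)
  expect_true("g3" %in% hits$gene_id)
  # chromosome names normalize across naming conventions
  hits2 <- candidate_window(genes, "1", pos)
  expect_equal(hits2$gene_id, hits$gene_id)
  expect_warning(empty <- candidate_window(genes, "Chr09", pos), "not present")
  expect_equal(nrow(empty), 0)
})

test_that("qq table pairs sorted observed with uniform expected quantiles", {
  p <- c(0.5, 0.01, 0.9, 0.2)
  qq <- qq_table(p)
  expect_equal(qq$observed, -log10(sort(p)))
  expect_equal(qq$expected, -log10((1:4 - 0.5) / 4))
})
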