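# A 3-locus panel carrying every allele combination (plus extras for
# frequency-based tie breaks).
combo_panel <- function(extra_hap1 = 5) {
  combos <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  dos <- rbind(2L * combos,
               matrix(0L, nrow = extra_hap1, ncol = 3))
  rownames(dos) <- sprintf("acc%02d", seq_len(nrow(dos)))
  make_G(dos, pos = c(77550396L, 78561058L, 78619413L),
         ref = c("C", "C", "G"), alt = c("T", "T", "A"))
}

test_that("allele strings concatenate carried bases in marker order", {
  G <- combo_panel()
  ht <- build_haplotypes(G, c("m01", "m02", "m03"))
  a <- ht$assignments
  expect_equal(a$allele_string[a$accession == "acc01"], "CCG")
  expect_equal(a$class[a$accession == "acc01"], "Hap1")
  expect_equal(a$allele_string[a$accession == "acc08"], "TTA")
  expect_equal(a$class[a$accession == "acc08"], "Hap8")
  expect_equal(nrow(ht$classes), 8)  # all 2^3 combinations present
  expect_equal(sum(ht$classes$n), nrow(a))
  # Hap1 is the all-reference class and, with extras, the most frequent
  expect_equal(ht$classes$allele_string[1], "CCG")
  expect_equal(ht$classes$alt_count, c(0L, 1L, 1L, 1L, 2L, 2L, 2L, 3L))
})

test_that("heterozygous and missing accessions are excluded with a count", {
  G <- combo_panel()
  G$dosages[2, 1] <- 1L
  G$dosages[3, 2] <- NA
  expect_message(ht <- build_haplotypes(G, c("m01", "m02", "m03")),
                 "2 accession")
  expect_equal(ht$n_excluded, 2)
  expect_false(any(ht$assignments$accession %in% c("acc02", "acc03")))
  expect_error(build_haplotypes(G, c("m01", "nope")), "not in genotype")
})

test_that("anchor ordering fixes class labels independent of frequency", {
  G <- combo_panel(extra_hap1 = 0)
  anchor <- c("CCG", "CTG", "TCG", "CCA", "TTG", "CTA", "TCA", "TTA")
  ht <- build_haplotypes(G, c("m01", "m02", "m03"), anchor = anchor)
  expect_equal(ht$classes$allele_string, anchor)
  expect_equal(ht$classes$class, paste0("Hap", 1:8))
})

test_that("marker order permutes strings but not class membership", {
  G <- combo_panel()
  h1 <- build_haplotypes(G, c("m01", "m02", "m03"))
  h2 <- build_haplotypes(G, c("m03", "m02", "m01"))
  for (cl in h1$classes$class) {
    set1 <- sort(h1$assignments$accession[h1$assignments$class == cl])
    s <- h1$classes$allele_string[h1$classes$class == cl]
    s_rev <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    cl2 <- h2$classes$class[h2$classes$allele_string == s_rev]
    set2 <- sort(h2$assignments$accession[h2$assignments$class == cl2])
    expect_equal(set1, set2)
  }
})

test_that("group statistics use the n-1 denominator and flag singletons", {
  G <- combo_panel(extra_hap1 = 2)
  ht <- build_haplotypes(G, c("m01", "m02", "m03"))
  vals <- stats::setNames(rep(0, nrow(ht$assignments)),
                          ht$assignments$accession)
  vals[ht$assignments$accession[ht$assignments$class == "Hap1"]] <- c(3, 5, 7)
  gs <- haplotype_group_stats(ht, vals)
  expect_equal(gs$mean[gs$class == "Hap1"], 5)
  expect_equal(gs$sd[gs$class == "Hap1"], 2)
  expect_true(all(gs$sd_undefined[gs$n == 1]))
  expect_true(all(is.na(gs$sd[gs$n == 1])))
})

test_that("class means fall with alt-allele count under a negative effect", {
  hits <- vapply(1:20, function(s) {
    cfg <- sim_config(n_accessions = 200, n_markers = 20, n_reps = 2,
                      field_rows = 20, field_cols = 20, seed = s)
    g <- simulate_genotypes(cfg)
    ht <- build_haplotypes(g$G, attr(g$truth, "causal_ids"))
    val <- stats::setNames(
      attr(simulate_field_phenotypes(g$G, g$truth, cfg),
           "accession_truth")$SD_total,
      g$truth$accession)
    gs <- haplotype_group_stats(ht, val)
    ac <- ht$classes$alt_count[match(gs$class, ht$classes$class)]
    stats::cor(gs$mean, ac, method = "spearman") < 0
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("one-way ANOVA F matches the definitional oracle", {
  vals <- c(4.1, 5.2, 4.8, 7.9, 8.3, 8.8, 12.0, 11.4, 12.6)
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- anova_tukey_letters(vals, grp)
  expect_equal(res$F, oracle_anova_f(vals, grp), tolerance = 1e-10)
  expect_equal(unname(res$df), c(2, 6))
  # cross-check Tukey p-values against stats::TukeyHSD on the same fit
  ref <- stats::TukeyHSD(stats::aov(vals ~ factor(grp)))[[1]][, "p adj"]
  expect_equal(sort(res$tukey$p), sort(unname(ref)), tolerance = 1e-10)
})

test_that("compact letters separate exactly the significant Tukey pairs", {
  set.seed(4)
  # two identical groups share a letter
  v <- c(stats::rnorm(5, 10), stats::rnorm(5, 10))
  g <- rep(c("x", "y"), each = 5)
  r <- anova_tukey_letters(v, g)
  expect_equal(r$letters[["x"]], r$letters[["y"]])
  # three fully separated groups get three distinct letters
  v2 <- c(0, 0, 0, 10, 10, 10, 20, 20, 20) + stats::rnorm(9, 0, 1e-6)
  g2 <- rep(c("lo", "mid", "hi"), each = 3)
  r2 <- anova_tukey_letters(v2, g2)
  expect_equal(length(unique(r2$letters)), 3)
  # property: share a letter <=> Tukey p >= alpha, on a mixed fixture
  set.seed(12)
  v3 <- c(stats::rnorm(6, 0), stats::rnorm(6, 0.5), stats::rnorm(6, 4),
          stats::rnorm(6, 4.2), stats::rnorm(6, 9))
  g3 <- rep(paste0("g", 1:5), each = 6)
  r3 <- anova_tukey_letters(v3, g3)
  share <- function(a, b) {
    la <- strsplit(r3$letters[[a]], "")[[1]]
    lb <- strsplit(r3$letters[[b]], "")[[1]]
    length(intersect(la, lb)) > 0
  }
  for (i in seq_len(nrow(r3$tukey))) {
    expect_equal(share(r3$tukey$group1[i], r3$tukey$group2[i]),
                 r3$tukey$p[i] >= 0.05,
                 info = paste(r3$tukey$group1[i], r3$tukey$group2[i]))
  }
  expect_error(anova_tukey_letters(1:5, rep("a", 5)), "2 groups")
})
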