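small_cfg <- function(...) {
  sim_config(n_accessions = 60, n_markers = 30, n_reps = 2,
             field_rows = 12, field_cols = 10, ...)
}

test_that("generated dosages are homozygous and seed-deterministic", {
  cfg <- small_cfg(seed = 3)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$G$dosages, g2$G$dosages)
  expect_true(all(g1$G$dosages %in% c(0L, 2L)))
  g3 <- simulate_genotypes(small_cfg(seed = 4))
  expect_false(identical(g1$G$dosages, g3$G$dosages))
  expect_true(all(attr(g1$truth, "causal_ids") %in% g1$G$markers$id))
})

test_that("causal-block correlation tracks rho", {
  # rho = 0: empirical allele correlation near zero at n = 360
  cors0 <- vapply(1:20, function(s) {
    tr <- simulate_genotypes(sim_config(n_accessions = 360, n_markers = 10,
                                        causal_rho = 0, seed = s))$truth
    stats::cor(tr$a1, tr$a2)
  }, numeric(1))
  expect_lt(abs(mean(cors0)), 0.1)
  # rho = 0.6: clearly positive correlation between the linked loci
  cors6 <- vapply(1:20, function(s) {
    tr <- simulate_genotypes(sim_config(n_accessions = 360, n_markers = 10,
                                        causal_rho = 0.6, seed = s))$truth
    stats::cor(tr$a1, tr$a2)
  }, numeric(1))
  expect_gt(mean(cors6), 0.4)
  expect_error(sim_config(causal_rho = 1.2), "causal_rho")
})

test_that("marker frequencies respect the configured MAF range", {
  freqs <- unlist(lapply(1:20, function(s) {
    g <- simulate_genotypes(sim_config(n_accessions = 360, n_markers = 8,
                                       maf_range = c(0.5, 0.5), seed = s))
    keep <- setdiff(g$G$markers$id, attr(g$truth, "causal_ids"))
    colMeans(g$G$dosages[, keep]) / 2
  }))
  expect_true(all(freqs >= 0.4 & freqs <= 0.6))
})

test_that("noise-free field phenotypes reproduce accession values exactly", {
  cfg <- small_cfg(seed = 9,
                   sigma_residual = c(SD_total = 0, An = 0, gsw = 0, iWUE = 0),
                   row_effect_scale = 0, col_effect_scale = 0,
                   beta_AveT = c(SD_total = 0, An = 0, gsw = 0, iWUE = 0),
                   beta_AveH = c(SD_total = 0, An = 0, gsw = 0, iWUE = 0))
  g <- simulate_genotypes(cfg)
  ph <- simulate_field_phenotypes(g$G, g$truth, cfg)
  truth <- attr(ph, "accession_truth")
  want <- truth$SD_total[match(ph$accession, truth$accession)]
  expect_equal(ph$SD_total, want, tolerance = 1e-12)
})

test_that("with only spatial effects, row+column+accession explain plots", {
  # residual noise ~0 while row/column gradients stay large: every plot value
  # must then decompose exactly into accession value + row + column effects
  cfg <- small_cfg(seed = 10,
                   sigma_residual = c(SD_total = 1e-12, An = 1e-12,
                                      gsw = 1e-12, iWUE = 1e-12),
                   row_effect_scale = 1e6, col_effect_scale = 1e6)
  g <- simulate_genotypes(cfg)
  ph <- simulate_field_phenotypes(g$G, g$truth, cfg)
  fit <- stats::lm(SD_total ~ factor(row) + factor(column) + accession,
                   data = ph)
  expect_lt(max(abs(stats::resid(fit))), 1e-4)
})

test_that("accession-mean variance grows with the accession variance", {
  med_var <- vapply(c(0.1, 1, 10), function(s2a) {
    vs <- vapply(1:20, function(s) {
      cfg <- small_cfg(seed = s,
                       sigma_accession = c(SD_total = sqrt(s2a), An = 1,
                                           gsw = 0.01, iWUE = 1),
                       sigma_residual = c(SD_total = 0.5, An = 0.5,
                                          gsw = 0.01, iWUE = 0.5),
                       causal_effects = c(SD_total = 0, An = 0, gsw = 0,
                                          iWUE = 0))
      g <- simulate_genotypes(cfg)
      ph <- simulate_field_phenotypes(g$G, g$truth, cfg)
      stats::var(tapply(ph$SD_total, ph$accession, mean))
    }, numeric(1))
    stats::median(vs)
  }, numeric(1))
  expect_true(all(diff(med_var) > 0))
})

test_that("impression counts are Poisson around density x field area", {
  cfg <- sim_config(seed = 21)
  dens <- stats::setNames(rep(100, 250), sprintf("A%03d", 1:250))
  impr <- simulate_impressions(dens, cfg)
  ad <- impr[impr$surface == "adaxial", ]
  counts <- unlist(ad$counts)
  expect_gt(length(counts), 1000)
  expect_lt(abs(mean(counts) - 100 * 0.59), 3)
  # abaxial densities exceed adaxial by the configured 25.5 percent
  ab <- impr[impr$surface == "abaxial", ]
  expect_lt(abs(mean(unlist(ab$counts)) - 125.5 * 0.59), 3)
})

test_that("density and stomatal size are negatively correlated", {
  rs <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = s)
    set.seed(1000 + s)
    dens <- stats::setNames(exp(stats::rnorm(360, log(130), 0.25)),
                            sprintf("A%03d", 1:360))
    impr <- simulate_impressions(dens, cfg)
    anat <- derive_anatomy(impr)
    acc <- sub("_p[0-9]+$", "", anat$plant_id)
    d <- tapply(anat$SD_total, acc, mean)
    sz <- tapply(anat$SS_mean, acc, mean)
    stats::cor(d, sz)
  }, numeric(1))
  expect_gt(mean(rs), -0.45)
  expect_lt(mean(rs), -0.15)
})

test_that("light-response curves follow the BWB-generative model", {
  cfg <- sim_config(seed = 2)
  cfg$bwb$sigma_gsw <- 0
  rec <- simulate_light_response(cfg, "X", "WW", 1, hap_class = 1)
  expect_equal(nrow(rec), 11)
  m <- cfg$bwb$m_WW[1]
  expect_equal(rec$gsw,
               pmax(m * rec$An * rec$Hs / rec$Cs + cfg$bwb$g0,
                    cfg$bwb$gsw_floor),
               tolerance = 1e-12)
  # dark limit: An = -Rd at zero light
  cfg0 <- cfg
  cfg0$light_curve$ppfd <- c(0, cfg$light_curve$ppfd[-1])
  rec0 <- simulate_light_response(cfg0, "X", "WW", 1, hap_class = 1)
  expect_equal(rec0$An[1], -cfg$light_curve$Rd, tolerance = 1e-12)
  expect_error(sim_config(light_curve = list(phi = 0.06, theta = 1.5,
                                             Amax_WW = 35, Amax_WS = 20,
                                             Rd = 1.5, Hs = 0.6, Cs = 390,
                                             ppfd = 1:11)),
               "theta")
})

test_that("water stress lowers Amax always and the slope for classes 1-5", {
  cfg <- sim_config(seed = 6)
  gx <- simulate_gas_exchange(cfg)
  expect_equal(nrow(gx), 8 * 2 * 3 * 11)
  top <- gx[gx$ppfd == 1600, ]
  an_by <- tapply(top$An, top$treatment, mean)
  expect_lt(an_by["WS"], an_by["WW"])
  fits <- fit_bwb_all(gx)
  hap <- attr(gx, "hap_class")
  mbar <- tapply(fits$m, list(hap[fits$accession], fits$treatment), mean)
  expect_true(all(mbar[1:5, "WS"] < mbar[1:5, "WW"] - 2))
  # classes 6-8 generate from identical slopes; fitted means differ only by
  # estimation noise
  expect_identical(cfg$bwb$m_WS[6:8], cfg$bwb$m_WW[6:8])
  expect_true(all(abs(mbar[6:8, "WS"] - mbar[6:8, "WW"]) < 1))
})
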