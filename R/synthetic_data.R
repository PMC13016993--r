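# Seedable synthetic-data generator emulating the statistical structure of
# an inbred sorghum diversity panel: {0,2} dosage genotypes with a MAF
# spectrum and a correlated 3-SNP causal block on chromosome 1; plot-level
# field phenotypes with row/column and weather fixed effects plus accession
# random effects; Poisson leaf-impression counts with negatively correlated
# density-size variation; and BWB-generative light-response curves whose
# slope m drops under water stress for haplotype classes 1-5 only.
#
# Each sub-generator draws from its own child seed derived from
# `config$seed`, so stages can be regenerated independently and
# deterministically.

#' Simulation configuration
#'
#' Defaults describe the emulated panel: 360 inbred accessions genotyped at
#' 5,000 SNPs on 10 chromosomes, MAF between 0.05 and 0.5, and a 3-SNP
#' causal block on chromosome 1 (positions 77,550,396 / 78,561,058 /
#' 78,619,413; C/T, C/T, G/A) with pairwise allele correlation `causal_rho`.
#' Alternative alleles at the block decrease stomatal density, An and gsw
#' and increase iWUE. Field plots carry row/column spatial effects, batch
#' weather covariates (AveT deg C, AveH %), accession random intercepts and
#' residual noise. Light-response curves follow a non-rectangular hyperbola
#' An(Q) feeding the BWB relation gsw = m*An*Hs/Cs + g0, with
#' treatment-dependent slope per haplotype class: classes 1-5 drop m under
#' water stress (WS), classes 6-8 keep it unchanged.
#'
#' @param n_accessions,n_markers,n_chromosomes panel dimensions.
#' @param maf_range range the per-marker alternative-allele frequency is
#'   drawn from.
#' @param causal_maf allele frequency at the 3 causal loci.
#' @param causal_rho allele-copying probability inducing correlation among
#'   the causal loci, in [0, 1).
#' @param causal_effects per-alt-allele additive effect on each trait.
#' @param trait_means,sigma_accession,sigma_residual trait intercepts and
#'   standard deviations of accession and residual effects (trait units).
#' @param n_reps plots per accession.
#' @param field_rows,field_cols field layout; must hold
#'   `n_accessions * n_reps` plots.
#' @param row_effect_scale,col_effect_scale SD of spatial effects as a
#'   multiple of `sigma_residual`.
#' @param beta_AveT,beta_AveH weather fixed-effect coefficients per trait.
#' @param batch_AveT,batch_AveH weather covariates of the phenotyping
#'   batches.
#' @param impressions list: field-of-view area (mm^2), fields per
#'   impression, plants per accession, stomata scored per impression,
#'   abaxial/adaxial ratios for density and dimensions, mean dimensions
#'   (um), accession-level log-scale SD, per-stoma log-scale SD, and target
#'   density-size correlation.
#' @param bwb list: per-haplotype-class slope m under WW and WS, intercept
#'   g0 (mol m^-2 s^-1), gsw noise SD and the truncation floor.
#' @param light_curve list: quantum yield phi, curvature theta in (0, 1],
#'   Amax per treatment, dark respiration Rd, leaf-surface humidity Hs
#'   (fraction) and CO2 Cs (umol mol^-1), and the PPFD schedule (the
#'   acclimation level 1600 plus ten descending steps).
#' @param seed master seed (integer); fully determines all output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_accessions = 360, n_markers = 5000,
                       n_chromosomes = 10,
                       maf_range = c(0.05, 0.5),
                       causal_maf = 0.3, causal_rho = 0.4,
                       causal_effects = c(SD_total = -8, An = -1.2,
                                          gsw = -0.02, iWUE = 4),
                       trait_means = c(SD_total = 290, An = 30,
                                       gsw = 0.35, iWUE = 88),
                       sigma_accession = c(SD_total = 15, An = 2,
                                           gsw = 0.04, iWUE = 8),
                       sigma_residual = c(SD_total = 10, An = 1.5,
                                          gsw = 0.03, iWUE = 6),
                       n_reps = 3, field_rows = 36, field_cols = 30,
                       row_effect_scale = 0.3, col_effect_scale = 0.3,
                       beta_AveT = c(SD_total = 0.5, An = 0.15,
                                     gsw = 0.002, iWUE = 0.3),
                       beta_AveH = c(SD_total = -0.2, An = 0.05,
                                     gsw = 0.001, iWUE = -0.2),
                       batch_AveT = c(24, 26, 28, 30),
                       batch_AveH = c(65, 60, 55, 50),
                       impressions = list(fov_area = 0.59, n_fields = 2,
                                          n_plants = 3, stomata_range = c(4, 5),
                                          abaxial_density_factor = 1.255,
                                          abaxial_dim_factors = c(SL = 1.094,
                                                                  SCW = 1.124,
                                                                  PL = 1.089,
                                                                  GCW = 1.030),
                                          SL_mean = 28, SCW_mean = 20,
                                          PL_ratio = 0.5, GCW_ratio = 0.3,
                                          acc_log_sd = 0.1, stoma_log_sd = 0.05,
                                          density_size_cor = -0.3),
                       bwb = list(m_WW = c(9.5, 9.0, 8.5, 8.0, 7.5,
                                           5.5, 5.0, 4.5),
                                  m_WS = c(4.5, 4.6, 4.3, 4.2, 4.1,
                                           5.5, 5.0, 4.5),
                                  g0 = 0.05, sigma_gsw = 0.02,
                                  gsw_floor = 0.005),
                       light_curve = list(phi = 0.06, theta = 0.7,
                                          Amax_WW = 35, Amax_WS = 20,
                                          Rd = 1.5, Hs = 0.60, Cs = 390,
                                          ppfd = c(1600, 1500, 1400, 1200,
                                                   1000, 800, 600, 400,
                                                   200, 100, 50)),
                       seed = 1) {
  if (causal_rho < 0 || causal_rho >= 1)
    stop("causal_rho must lie in [0, 1)")
  if (any(sigma_accession < 0) || any(sigma_residual < 0))
    stop("variance components must be non-negative")
  if (light_curve$theta <= 0 || light_curve$theta > 1)
    stop("light_curve theta must lie in (0, 1]")
  if (field_rows * field_cols < n_accessions * n_reps)
    stop("field layout (", field_rows, " x ", field_cols,
         ") smaller than accessions x replicates (",
         n_accessions * n_reps, ")")
  traits <- c("SD_total", "An", "gsw", "iWUE")
  for (v in list(causal_effects, trait_means, sigma_accession,
                 sigma_residual, beta_AveT, beta_AveH))
    stopifnot(all(traits %in% names(v)))
  cfg <- as.list(environment())
  cfg$traits <- traits
  cfg$causal <- data.frame(
    id = c("S01_77550396", "S01_78561058", "S01_78619413"),
    chrom = "Chr01",
    pos = c(77550396L, 78561058L, 78619413L),
    ref = c("C", "C", "G"), alt = c("T", "T", "A"),
    stringsAsFactors = FALSE)
  structure(cfg, class = "sim_config")
}

# Child seed for a sub-generator; kept below 2^31.
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(offset)
}

#' Simulate panel genotypes with an embedded causal block
#'
#' Dosages are drawn as homozygous {0, 2} (inbred panel). Each non-causal
#' marker's alternative-allele frequency comes from `maf_range`. The three
#' causal loci share frequency `causal_maf`; loci 2 and 3 copy locus 1's
#' allele with probability `causal_rho`, inducing positive linkage between
#' them.
#'
#' @param config a [sim_config()].
#' @return list with `G` (a [genotype_matrix()]) and `truth`, a data.frame
#'   per accession: alt-allele indicator at each causal locus, `alt_count`,
#'   `hap_string` (allele configuration, reference base for dosage 0), and
#'   the causal genetic value for each trait. Attribute `causal_ids` names
#'   the causal markers.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 1L))
  n <- config$n_accessions
  acc <- sprintf("ACC%03d", seq_len(n))
  m_rest <- config$n_markers - nrow(config$causal)
  if (m_rest < 0) stop("n_markers must be at least ", nrow(config$causal))

  chrom_lab <- sprintf("Chr%02d", seq_len(config$n_chromosomes))
  chrom_idx <- sort(rep_len(seq_len(config$n_chromosomes), m_rest))
  pos <- unlist(lapply(split(seq_len(m_rest), chrom_idx), function(i)
    sort(sample.int(7e7, length(i)))), use.names = FALSE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m_rest, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  mk <- data.frame(id = sprintf("S%02d_%d", chrom_idx, pos),
                   chrom = chrom_lab[chrom_idx], pos = pos,
                   ref = ref, alt = alt, stringsAsFactors = FALSE)

  f <- stats::runif(m_rest, config$maf_range[1], config$maf_range[2])
  dos <- vapply(f, function(fi) 2L * stats::rbinom(n, 1L, fi),
                integer(n))

  # causal block: allele copying induces correlation causal_rho
  f0 <- config$causal_maf
  a1 <- stats::rbinom(n, 1L, f0)
  copy2 <- stats::rbinom(n, 1L, config$causal_rho)
  copy3 <- stats::rbinom(n, 1L, config$causal_rho)
  a2 <- ifelse(copy2 == 1L, a1, stats::rbinom(n, 1L, f0))
  a3 <- ifelse(copy3 == 1L, a1, stats::rbinom(n, 1L, f0))
  alleles <- cbind(a1, a2, a3)

  mk_all <- rbind(mk, config$causal)
  dos_all <- cbind(dos, 2L * alleles)
  colnames(dos_all) <- mk_all$id
  ord <- order(match(mk_all$chrom, chrom_lab), mk_all$pos)
  mk_all <- mk_all[ord, ]
  dos_all <- dos_all[, ord, drop = FALSE]
  dup <- duplicated(mk_all$id) |
    ave(mk_all$pos, mk_all$chrom, FUN = function(p) c(FALSE, diff(p) == 0)) > 0
  if (any(dup)) {  # rare positional collision with a causal locus
    keepers <- !dup | mk_all$id %in% config$causal$id
    mk_all <- mk_all[keepers, ]
    dos_all <- dos_all[, keepers, drop = FALSE]
  }
  rownames(dos_all) <- acc
  G <- genotype_matrix(dos_all, mk_all)

  hap <- apply(alleles, 1, function(a)
    paste0(ifelse(a == 1, config$causal$alt, config$causal$ref),
           collapse = ""))
  truth <- data.frame(accession = acc, a1 = a1, a2 = a2, a3 = a3,
                      alt_count = rowSums(alleles),
                      hap_string = hap, stringsAsFactors = FALSE)
  for (tr in config$traits)
    truth[[paste0("g_", tr)]] <- 2 * rowSums(alleles) * config$causal_effects[[tr]]
  attr(truth, "causal_ids") <- config$causal$id
  list(G = G, truth = truth)
}

#' Simulate plot-level field phenotypes
#'
#' Each plot value is
#' `mu + row + column + beta_T*AveT + beta_H*AveH + causal effect +
#'  accession random effect + N(0, sigma_residual^2)`.
#' Accessions are assigned to phenotyping batches (weather covariates) and
#' to randomized positions on the field grid, `n_reps` plots each.
#'
#' @param G genotype matrix from [simulate_genotypes()].
#' @param truth truth record from [simulate_genotypes()].
#' @param config a [sim_config()].
#' @return data.frame of plot records (`accession`, `row`, `column`,
#'   `batch`, `AveT`, `AveH`, one column per trait) with attribute
#'   `accession_truth`: per accession, its total genetic value
#'   (mu + causal + random intercept) for each trait.
#' @export
simulate_field_phenotypes <- function(G, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 2L))
  acc <- truth$accession
  n <- length(acc)
  n_plots <- n * config$n_reps
  if (config$field_rows * config$field_cols < n_plots)
    stop("field layout smaller than accessions x replicates")

  batch <- sample(rep_len(seq_along(config$batch_AveT), n))
  cells <- sample(config$field_rows * config$field_cols, n_plots)
  plot_row <- ((cells - 1L) %/% config$field_cols) + 1L
  plot_col <- ((cells - 1L) %% config$field_cols) + 1L
  idx <- rep(seq_len(n), each = config$n_reps)

  out <- data.frame(accession = acc[idx], row = plot_row, column = plot_col,
                    batch = batch[idx],
                    AveT = config$batch_AveT[batch[idx]],
                    AveH = config$batch_AveH[batch[idx]],
                    stringsAsFactors = FALSE)
  acc_truth <- data.frame(accession = acc, stringsAsFactors = FALSE)
  for (tr in config$traits) {
    sr <- config$sigma_residual[[tr]]
    u <- stats::rnorm(n, 0, config$sigma_accession[[tr]])
    reff <- stats::rnorm(config$field_rows, 0, config$row_effect_scale * sr)
    ceff <- stats::rnorm(config$field_cols, 0, config$col_effect_scale * sr)
    value_acc <- config$trait_means[[tr]] + truth[[paste0("g_", tr)]] + u
    out[[tr]] <- value_acc[idx] +
      reff[plot_row] + ceff[plot_col] +
      config$beta_AveT[[tr]] * out$AveT + config$beta_AveH[[tr]] * out$AveH +
      stats::rnorm(n_plots, 0, sr)
    acc_truth[[tr]] <- value_acc
  }
  attr(out, "accession_truth") <- acc_truth
  attr(out, "traits") <- config$traits
  out
}

#' Simulate leaf-impression measurements
#'
#' Per accession, `n_plants` plants are sampled on both leaf surfaces.
#' Stomatal counts per field of view are Poisson with mean
#' `density * fov_area`; the abaxial surface scales density by
#' `abaxial_density_factor` and each dimension by its abaxial factor.
#' Guard-cell dimensions are lognormal with an accession-level component
#' anti-correlated with density (target correlation
#' `density_size_cor`), reproducing the density-size trade-off.
#'
#' @param accession_density_means named vector of adaxial stomatal density
#'   means (mm^-2) per accession.
#' @param config a [sim_config()].
#' @return data.frame with columns `accession`, `plant_id`, `surface`,
#'   `fov_area` and list-columns `counts`, `SL`, `SCW`, `PL`, `GCW`,
#'   ready for [derive_anatomy()].
#' @export
simulate_impressions <- function(accession_density_means, config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(accession_density_means <= 0)) stop("densities must be positive")
  set.seed(child_seed(config$seed, 3L))
  ip <- config$impressions
  acc <- names(accession_density_means)
  if (is.null(acc)) acc <- sprintf("ACC%03d", seq_along(accession_density_means))
  dens <- as.numeric(accession_density_means)

  # accession-level size component anti-correlated with density
  z <- if (length(dens) > 1 && stats::sd(log(dens)) > 0)
    as.numeric(scale(log(dens))) else rep(0, length(dens))
  r <- ip$density_size_cor
  size_z <- r * z + sqrt(max(0, 1 - r^2)) * stats::rnorm(length(dens))

  rows <- list()
  for (i in seq_along(acc)) {
    sl_acc <- ip$SL_mean * exp(ip$acc_log_sd * size_z[i])
    scw_acc <- ip$SCW_mean * exp(ip$acc_log_sd * size_z[i])
    for (p in seq_len(ip$n_plants)) {
      for (surf in c("adaxial", "abaxial")) {
        dfac <- if (surf == "abaxial") ip$abaxial_density_factor else 1
        dimf <- if (surf == "abaxial") ip$abaxial_dim_factors else
          c(SL = 1, SCW = 1, PL = 1, GCW = 1)
        counts <- stats::rpois(ip$n_fields, dens[i] * dfac * ip$fov_area)
        ns <- sample(seq(ip$stomata_range[1], ip$stomata_range[2]), 1)
        SL <- sl_acc * dimf[["SL"]] * exp(stats::rnorm(ns, 0, ip$stoma_log_sd))
        SCW <- scw_acc * dimf[["SCW"]] * exp(stats::rnorm(ns, 0, ip$stoma_log_sd))
        pr <- pmin(0.9, pmax(0.2, ip$PL_ratio * dimf[["PL"]] / dimf[["SL"]] *
                               exp(stats::rnorm(ns, 0, 0.05))))
        gr <- pmin(0.9, pmax(0.1, ip$GCW_ratio * dimf[["GCW"]] / dimf[["SCW"]] *
                               exp(stats::rnorm(ns, 0, 0.05))))
        rows[[length(rows) + 1L]] <- data.frame(
          accession = acc[i],
          plant_id = paste0(acc[i], "_p", p),
          surface = surf, fov_area = ip$fov_area,
          counts = I(list(counts)), SL = I(list(SL)), SCW = I(list(SCW)),
          PL = I(list(SL * pr)), GCW = I(list(SCW * gr)),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# Non-rectangular hyperbola light-response of net assimilation.
nrh_an <- function(Q, phi, theta, Amax, Rd) {
  s <- phi * Q + Amax
  (s - sqrt(s^2 - 4 * theta * phi * Q * Amax)) / (2 * theta) - Rd
}

#' Simulate one BWB-generative light-response curve
#'
#' Produces steady-state records at the 11 PPFD levels of the measurement
#' schedule (acclimation level 1600 plus ten descending steps). An follows
#' a non-rectangular hyperbola — a standard stand-in for a measured C4
#' light response — and gsw follows the BWB relation for the accession's
#' haplotype class and treatment, with additive noise truncated at the
#' configured floor.
#'
#' @param config a [sim_config()].
#' @param accession accession id label.
#' @param treatment `"WW"` or `"WS"`.
#' @param replicate biological replicate number.
#' @param hap_class haplotype class index (1-8) selecting the BWB slope.
#' @return data.frame of gas-exchange records: `accession`, `treatment`,
#'   `replicate`, `ppfd`, `An`, `gsw`, `Ci`, `Cs`, `Hs`, `Tleaf`.
#' @export
simulate_light_response <- function(config, accession, treatment = c("WW", "WS"),
                                    replicate = 1L, hap_class = 1L) {
  stopifnot(inherits(config, "sim_config"))
  treatment <- match.arg(treatment)
  lc <- config$light_curve
  bw <- config$bwb
  if (hap_class < 1 || hap_class > length(bw$m_WW))
    stop("hap_class out of range")
  set.seed(child_seed(config$seed,
                      4L + hap_class * 97L + replicate * 11L +
                        (treatment == "WS") * 5L))
  Amax <- if (treatment == "WW") lc$Amax_WW else lc$Amax_WS
  m <- if (treatment == "WW") bw$m_WW[hap_class] else bw$m_WS[hap_class]
  An <- nrh_an(lc$ppfd, lc$phi, lc$theta, Amax, lc$Rd)
  gsw <- m * ball_index(An, lc$Hs, lc$Cs) + bw$g0 +
    stats::rnorm(length(An), 0, bw$sigma_gsw)
  gsw <- pmax(gsw, bw$gsw_floor)
  data.frame(accession = accession, treatment = treatment,
             replicate = as.integer(replicate), ppfd = lc$ppfd,
             An = An, gsw = gsw,
             Ci = lc$Cs * 0.6, Cs = lc$Cs, Hs = lc$Hs, Tleaf = 28,
             stringsAsFactors = FALSE)
}

#' Simulate the full growth-chamber gas-exchange experiment
#'
#' One representative accession per haplotype class, each measured in both
#' water regimes with `n_reps` biological replicates.
#'
#' @param config a [sim_config()].
#' @param accessions character vector naming one accession per class
#'   (default `HapAcc1..HapAcc8`).
#' @param n_reps biological replicates per accession x treatment.
#' @return data.frame of light-response records across all curves; attribute
#'   `hap_class` maps accession to class.
#' @export
simulate_gas_exchange <- function(config,
                                  accessions = paste0("HapAcc",
                                                      seq_along(config$bwb$m_WW)),
                                  n_reps = 3L) {
  stopifnot(length(accessions) == length(config$bwb$m_WW))
  out <- list()
  for (h in seq_along(accessions))
    for (trt in c("WW", "WS"))
      for (r in seq_len(n_reps))
        out[[length(out) + 1L]] <-
          simulate_light_response(config, accessions[h], trt, r, h)
  res <- do.call(rbind, out)
  attr(res, "hap_class") <- stats::setNames(seq_along(accessions), accessions)
  res
}
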