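# End-to-end orchestration: simulate -> anatomy -> field model -> scan ->
# haplotypes -> BWB -> multivariate stats, with per-stage outputs and a run
# manifest. Stages run in dependency order; a failing stage stops
# downstream stages while preserving upstream outputs.

#' Pipeline configuration
#'
#' @param sim a [sim_config()]; its seed drives every stage.
#' @param out_dir output directory (created if needed).
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "anatomy", "fieldmodel", "gwas", "haplotypes", "bwb",
#'   "stats")`.
#' @param alpha,maf_cutoff,k_pcs,window_bp scan parameters.
#' @param focal_markers marker ids for the haplotype stage (default: the
#'   simulated causal block).
#' @param k_clusters trait clusters for the stats stage.
#' @param genes optional gene table for candidate windows.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), out_dir = tempfile("wue_run_"),
                            stages = c("simulate", "anatomy", "fieldmodel",
                                       "gwas", "haplotypes", "bwb", "stats"),
                            alpha = 0.05, maf_cutoff = 0.03, k_pcs = 3,
                            window_bp = 75000, focal_markers = NULL,
                            k_clusters = 3, genes = NULL) {
  known <- c("simulate", "anatomy", "fieldmodel", "gwas", "haplotypes",
             "bwb", "stats")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(sim = sim, out_dir = out_dir, stages = stages,
                 alpha = alpha, maf_cutoff = maf_cutoff, k_pcs = k_pcs,
                 window_bp = window_bp, focal_markers = focal_markers,
                 k_clusters = k_clusters, genes = genes),
            class = "pipeline_config")
}

config_hash <- function(config) {
  strip <- config
  strip$genes <- NULL
  strip$out_dir <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(utils::str(strip, digits.d = 15)), f)
  unname(tools::md5sum(f))
}

write_csv_seeded <- function(df, path, seed, hash) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("# seed=", seed, " config=", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order on simulated inputs,
#' writing per-stage CSV/TSV outputs and a JSON manifest (`manifest.json`)
#' recording the seed, config hash, per-stage row counts, and the note that
#' the association stage is a PC-adjusted single-marker scan. Identical
#' configs and seeds give byte-identical outputs. The haplotype stage runs
#' from explicit `focal_markers` when given, without requiring the scan
#' stage.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (list; also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$sim$seed
  hash <- config_hash(config)
  manifest <- list(package = "stomataWUE",
                   version = as.character(utils::packageVersion("stomataWUE")),
                   seed = seed, config_hash = hash,
                   scan_method = paste("PC-adjusted single-marker OLS scan",
                                       "(no multi-stage mixed-model scan)"),
                   stages = list())
  on_stage <- function(name) name %in% config$stages
  note <- function(name, rows_in, rows_out, outputs = character(0)) {
    manifest$stages[[name]] <<- list(rows_in = rows_in, rows_out = rows_out,
                                     outputs = outputs)
  }
  state <- list()

  if (on_stage("simulate")) {
    g <- simulate_genotypes(config$sim)
    state$G <- g$G
    state$truth <- g$truth
    state$pheno <- simulate_field_phenotypes(g$G, g$truth, config$sim)
    dens <- stats::setNames(
      pmax(40, state$pheno$SD_total[!duplicated(state$pheno$accession)] / 2.255),
      state$pheno$accession[!duplicated(state$pheno$accession)])
    state$impr <- simulate_impressions(dens, config$sim)
    state$gasex <- simulate_gas_exchange(config$sim)
    p1 <- file.path(config$out_dir, "genotypes.csv")
    p2 <- file.path(config$out_dir, "phenotypes.csv")
    write_dosage_csv(state$G, p1, comment = paste0("seed=", seed, " config=", hash))
    write_csv_seeded(state$pheno, p2, seed, hash)
    note("simulate", 0, nrow(state$pheno), c(p1, p2))
  }

  if (on_stage("anatomy")) {
    if (is.null(state$impr)) stop("anatomy stage needs simulated impressions")
    state$anat <- derive_anatomy(state$impr)
    state$anat$accession <- sub("_p[0-9]+$", "", state$anat$plant_id)
    p <- file.path(config$out_dir, "anatomy_traits.csv")
    write_csv_seeded(state$anat, p, seed, hash)
    note("anatomy", nrow(state$impr), nrow(state$anat), p)
  }

  if (on_stage("fieldmodel")) {
    if (is.null(state$pheno)) stop("fieldmodel stage needs phenotypes")
    traits <- attr(state$pheno, "traits")
    preds <- NULL
    for (tr in traits) {
      fit <- fit_random_intercept_reml(state$pheno, tr)
      pv <- predict_accession_values(fit)
      if (is.null(preds))
        preds <- data.frame(accession = names(pv), stringsAsFactors = FALSE)
      preds[[tr]] <- pv[preds$accession]
    }
    state$preds <- preds
    p <- file.path(config$out_dir, "accession_predictions.csv")
    write_csv_seeded(preds, p, seed, hash)
    note("fieldmodel", nrow(state$pheno), nrow(preds), p)
  }

  if (on_stage("gwas")) {
    if (is.null(state$G) || is.null(state$preds))
      stop("gwas stage needs genotypes and accession predictions")
    Gf <- maf_filter(state$G, config$maf_cutoff)
    pcs <- genotype_pcs(Gf, k = config$k_pcs)
    outs <- character(0)
    state$scan <- list()
    for (tr in attr(state$pheno, "traits")) {
      y <- stats::setNames(state$preds[[tr]], state$preds$accession)
      res <- single_marker_scan(Gf, y, pcs, alpha = config$alpha, trait = tr)
      state$scan[[tr]] <- res
      p <- file.path(config$out_dir, paste0("gwas_", tr, ".tsv"))
      write_gwas_tsv(res, p)
      pq <- file.path(config$out_dir, paste0("qq_", tr, ".tsv"))
      utils::write.table(qq_table(res$table$p), pq, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      outs <- c(outs, p, pq)
      if (!is.null(config$genes)) {
        sig <- significant_markers(res)
        if (nrow(sig) > 0) {
          cand <- do.call(rbind, lapply(seq_len(nrow(sig)), function(i) {
            cw <- candidate_window(config$genes, sig$chrom[i], sig$pos[i],
                                   config$window_bp)
            if (nrow(cw) == 0) return(NULL)
            cbind(marker = sig$id[i], cw)
          }))
          if (!is.null(cand)) {
            pc <- file.path(config$out_dir, paste0("candidates_", tr, ".tsv"))
            utils::write.table(cand, pc, sep = "\t", row.names = FALSE,
                               quote = FALSE)
            outs <- c(outs, pc)
          }
        }
      }
    }
    note("gwas", n_markers(state$G), n_markers(Gf), outs)
  }

  if (on_stage("haplotypes")) {
    if (is.null(state$G)) stop("haplotypes stage needs genotypes")
    focal <- config$focal_markers
    if (is.null(focal)) focal <- attr(state$truth, "causal_ids")
    if (is.null(focal)) stop("no focal markers available for haplotype stage")
    ht <- build_haplotypes(state$G, focal)
    state$hap <- ht
    p <- file.path(config$out_dir, "haplotype_assignments.csv")
    write_csv_seeded(ht$assignments, p, seed, hash)
    outs <- p
    if (!is.null(state$preds)) {
      stats_rows <- lapply(attr(state$pheno, "traits"), function(tr) {
        y <- stats::setNames(state$preds[[tr]], state$preds$accession)
        gs <- haplotype_group_stats(ht, y)
        a <- ht$assignments
        a$value <- y[a$accession]
        keep <- ht$classes$class[ht$classes$n >= 2]
        aok <- a[a$class %in% keep & !is.na(a$value), ]
        lt <- anova_tukey_letters(aok$value, aok$class)
        gs$letter <- lt$letters[gs$class]
        cbind(trait = tr, gs)
      })
      ps <- file.path(config$out_dir, "haplotype_stats.csv")
      write_csv_seeded(do.call(rbind, stats_rows), ps, seed, hash)
      outs <- c(outs, ps)
    }
    note("haplotypes", nrow(state$G$dosages), nrow(ht$assignments), outs)
  }

  if (on_stage("bwb")) {
    if (is.null(state$gasex)) stop("bwb stage needs gas-exchange records")
    fits <- fit_bwb_all(state$gasex)
    cmp <- compare_slopes(fits)
    p1 <- file.path(config$out_dir, "bwb_fits.csv")
    p2 <- file.path(config$out_dir, "bwb_contrasts.csv")
    write_csv_seeded(fits, p1, seed, hash)
    write_csv_seeded(cmp$per_accession, p2, seed, hash)
    state$bwb <- list(fits = fits, contrast = cmp)
    note("bwb", nrow(state$gasex), nrow(fits), c(p1, p2))
  }

  if (on_stage("stats")) {
    if (is.null(state$preds)) stop("stats stage needs accession predictions")
    M <- as.matrix(state$preds[, -1, drop = FALSE])
    rownames(M) <- state$preds$accession
    cm <- correlation_matrix(M)
    pca <- pca_traits(M)
    cl <- cluster_traits(pca, k = min(config$k_clusters, ncol(M)))
    p1 <- file.path(config$out_dir, "trait_correlations.csv")
    p2 <- file.path(config$out_dir, "trait_pca_variance.csv")
    p3 <- file.path(config$out_dir, "trait_clusters.csv")
    write_csv_seeded(as.data.frame(cm$r), p1, seed, hash)
    write_csv_seeded(data.frame(pc = seq_along(pca$var_pct),
                                var_pct = pca$var_pct), p2, seed, hash)
    write_csv_seeded(data.frame(trait = names(cl), cluster = unname(cl)),
                     p3, seed, hash)
    note("stats", nrow(M), ncol(M), c(p1, p2, p3))
  }

  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  manifest$path <- mpath
  invisible(manifest)
}
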