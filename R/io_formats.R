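# Readers and writers for the external formats the pipeline touches:
# minimal VCF (GT only), a dosage-matrix CSV dialect, plot-level phenotype
# CSV, GFF3 gene annotation, and the GWAS results TSV.

#' Construct a genotype matrix
#'
#' Container for a panel of accessions genotyped at biallelic SNP markers.
#' Dosages count alternative alleles (0 = homozygous reference, 2 =
#' homozygous alternative, `NA` = missing). Inbred panels carry only 0/2,
#' but heterozygous dosage 1 is accepted.
#'
#' @param dosages integer matrix, accessions in rows, markers in columns.
#'   Row names are accession ids, column names marker ids.
#' @param markers data.frame with columns `id`, `chrom`, `pos` (1-based bp),
#'   `ref`, `alt`, one row per column of `dosages`, in the same order.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages` and `markers`.
#' @export
genotype_matrix <- function(dosages, markers) {
  dosages <- as.matrix(dosages)
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(markers)))
    stop("markers must have columns: ", paste(need, collapse = ", "))
  markers$pos <- as.integer(markers$pos)
  if (ncol(dosages) != nrow(markers))
    stop("dosage columns (", ncol(dosages), ") != marker rows (", nrow(markers), ")")
  if (anyDuplicated(markers$id))
    stop("duplicate marker ids: ", paste(unique(markers$id[duplicated(markers$id)]), collapse = ", "))
  if (is.null(rownames(dosages)))
    stop("dosages must carry accession ids as row names")
  if (anyDuplicated(rownames(dosages)))
    stop("duplicate accession ids")
  colnames(dosages) <- markers$id
  bad <- !(dosages %in% c(0L, 1L, 2L) | is.na(dosages))
  if (any(bad)) stop("dosage values must be 0, 1, 2 or NA")
  # positions strictly increasing within each chromosome
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  structure(list(dosages = dosages, markers = markers),
            class = "genotype_matrix")
}

#' @method print genotype_matrix
#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "accessions x",
      ncol(x$dosages), "markers on",
      length(unique(x$markers$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing dosage fraction: %.4f\n", miss))
  invisible(x)
}

#' Number of accessions / markers in a genotype matrix
#' @param G a `genotype_matrix`
#' @return integer count.
#' @export
n_accessions <- function(G) nrow(G$dosages)

#' @rdname n_accessions
#' @export
n_markers <- function(G) ncol(G$dosages)

#' Strip a leading "Chr"/"chr" prefix for chromosome-name matching
#'
#' Original labels are preserved in outputs; normalization is used only when
#' matching chromosome namespaces between files.
#'
#' @param x character vector of chromosome labels.
#' @return character vector with any leading `chr`/`Chr`/`CHR` and leading
#'   zeros removed (`"Chr01"` and `"1"` both normalize to `"1"`).
#' @export
normalize_chrom <- function(x) {
  out <- sub("^[Cc][Hh][Rr]", "", as.character(x))
  sub("^0+(?=.)", "", out, perl = TRUE)
}

#' Read a minimal VCF into a genotype matrix
#'
#' Accepts VCF v4.x with GT fields. Only biallelic SNP records are kept;
#' multi-allelic or indel records are skipped and counted. Unphased and
#' phased GT separators are both accepted; `./.` becomes `NA`.
#'
#' @param path path to an (uncompressed or gzipped) VCF file.
#' @return A `genotype_matrix`; attribute `skipped` holds the number of
#'   records dropped as non-biallelic-SNP.
#' @export
read_vcf_lite <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(fix) == 0) stop("no variant records in ", path)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  skipped <- sum(!keep)
  if (!any(keep)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_integer_)
    sum(al == "1")
  })
  ids <- fix[keep, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0("S", fix[keep, "CHROM"][noid], "_", fix[keep, "POS"][noid])
  if (anyDuplicated(ids)) stop("duplicate marker ids in ", path)
  markers <- data.frame(id = ids,
                        chrom = fix[keep, "CHROM"],
                        pos = as.integer(fix[keep, "POS"]),
                        ref = ref[keep], alt = alt[keep],
                        stringsAsFactors = FALSE)
  G <- genotype_matrix(t(dos), markers)
  attr(G, "skipped") <- skipped
  if (skipped > 0)
    message(skipped, " non-biallelic-SNP record(s) skipped")
  G
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits sites with GT-only FORMAT; dosage 0/1/2/NA become `0/0`, `0/1`,
#' `1/1`, `./.`. UTF-8, LF line endings.
#'
#' @param G a `genotype_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf_lite <- function(G, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con, sep = "\n")
  w("##fileformat=VCFv4.2")
  w("##source=stomataWUE")
  for (ch in unique(G$markers$chrom)) w("##contig=<ID=", ch, ">")
  w(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(G$dosages)), collapse = "\t"))
  gtmap <- c("0" = "0/0", "1" = "0/1", "2" = "1/1")
  for (j in seq_len(ncol(G$dosages))) {
    d <- G$dosages[, j]
    gt <- ifelse(is.na(d), "./.", gtmap[as.character(d)])
    m <- G$markers[j, ]
    w(paste(c(m$chrom, m$pos, m$id, m$ref, m$alt, ".", "PASS", ".", "GT", gt),
            collapse = "\t"))
  }
  invisible(path)
}

#' Read / write the dosage CSV dialect
#'
#' A plain-text alternative to VCF for synthetic fixtures: one row per
#' marker with columns `id, chrom, pos, ref, alt` followed by one dosage
#' column per accession. Lines starting with `#` are comments.
#'
#' @param path file path.
#' @return `read_dosage_csv`: a `genotype_matrix`.
#' @export
read_dosage_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE,
                        colClasses = c(id = "character", chrom = "character",
                                       ref = "character", alt = "character"))
  meta <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(meta %in% names(df)))
    stop("dosage CSV must start with columns: ", paste(meta, collapse = ", "))
  acc <- setdiff(names(df), meta)
  if (length(acc) == 0) stop("no accession columns in ", path)
  dos <- t(as.matrix(df[, acc, drop = FALSE]))
  mode(dos) <- "integer"
  rownames(dos) <- acc
  genotype_matrix(dos, df[, meta])
}

#' @rdname read_dosage_csv
#' @param G a `genotype_matrix`.
#' @param comment optional comment line(s) written at the top (each prefixed
#'   with `#`), used by the simulator to log its seed.
#' @return `write_dosage_csv`: `path`, invisibly.
#' @export
write_dosage_csv <- function(G, path, comment = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con, sep = "\n")
  df <- cbind(G$markers, as.data.frame(t(G$dosages), check.names = FALSE))
  lines <- c(paste(names(df), collapse = ","),
             apply(df, 1, function(r) paste(ifelse(is.na(r), "", trimws(r)), collapse = ",")))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a plot-level phenotype table
#'
#' Expects a CSV with mandatory design columns `accession`, `row`, `column`,
#' `AveT` (average daily temperature, deg C), `AveH` (average relative
#' humidity, %) and at least one numeric trait column. Any additional
#' numeric column is treated as a trait; empty trait cells are kept as `NA`
#' and flagged.
#'
#' @param path CSV path.
#' @return data.frame of plot records with attributes `traits` (detected
#'   trait column names) and `n_missing` (count of missing trait cells).
#' @export
read_phenotype_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  mandatory <- c("accession", "row", "column", "AveT", "AveH")
  absent <- setdiff(mandatory, names(df))
  if (length(absent) > 0)
    stop("phenotype CSV is missing mandatory column(s): ",
         paste(absent, collapse = ", "))
  traits <- setdiff(names(df), c(mandatory, "batch", "replicate", "plot"))
  traits <- traits[vapply(df[traits], is.numeric, logical(1))]
  if (length(traits) == 0) stop("no numeric trait columns detected")
  df$accession <- as.character(df$accession)
  attr(df, "traits") <- traits
  attr(df, "n_missing") <- sum(is.na(df[, traits]))
  df
}

#' Read gene records from a GFF3 file
#'
#' Keeps rows of type `gene`; 1-based inclusive coordinates are preserved
#' verbatim. The gene id is parsed from the `ID=` attribute; if absent, an
#' id is synthesized from the coordinates with a warning.
#'
#' @param path GFF3 path.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (a "gene table"). May have zero rows.
#' @export
read_gff3_genes <- function(path) {
  g <- ape::read.gff(path)
  g <- g[g$type == "gene", , drop = FALSE]
  if (nrow(g) == 0)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  if (any(g$end < g$start))
    stop("gene record with end < start in ", path)
  ids <- sub("^.*ID=([^;]+).*$", "\\1", g$attributes)
  noid <- !grepl("ID=", g$attributes)
  if (any(noid)) {
    ids[noid] <- paste0("gene_", g$seqid[noid], "_", g$start[noid])
    warning(sum(noid), " gene record(s) lacked an ID attribute; ",
            "ids synthesized from coordinates")
  }
  data.frame(gene_id = ids, chrom = as.character(g$seqid),
             start = as.integer(g$start), end = as.integer(g$end),
             strand = as.character(g$strand), stringsAsFactors = FALSE)
}

#' Write a GWAS result as a TSV
#'
#' One row per tested marker with columns `id`, `chrom`, `pos`, `maf`,
#' `beta`, `se`, `p`, `neg_log10_p`, `significant` in that fixed order.
#' Values round-trip through [read_gwas_tsv()] at full double precision.
#'
#' @param result a `gwas_result` from [single_marker_scan()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gwas_tsv <- function(result, path) {
  stopifnot(inherits(result, "gwas_result"))
  tab <- result$table
  out <- data.frame(id = tab$id, chrom = tab$chrom, pos = tab$pos,
                    maf = tab$maf, beta = tab$beta, se = tab$se, p = tab$p,
                    neg_log10_p = -log10(tab$p),
                    significant = tab$p < result$threshold)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("# alpha=", format(result$alpha),
                    " n_markers_tested=", result$n_markers_tested,
                    " threshold=", format(result$threshold, digits = 17),
                    " covariates=", result$covariates,
                    " method=PC-adjusted single-marker OLS scan"), con)
  writeLines(paste(names(out), collapse = "\t"), con)
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "pos"
  for (cn in names(out)[num]) out[[cn]] <- format(out[[cn]], digits = 17, trim = TRUE)
  writeLines(do.call(paste, c(out, sep = "\t")), con)
  invisible(path)
}

#' @rdname write_gwas_tsv
#' @return `read_gwas_tsv`: the per-marker table as a data.frame.
#' @export
read_gwas_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
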