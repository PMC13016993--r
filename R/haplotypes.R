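# Multi-locus haplotype classes at chosen focal SNPs: allele-string
# construction for homozygous accessions, class labeling, per-class trait
# statistics, and one-way ANOVA with Tukey HSD compact letters.

#' Build haplotype classes from focal markers
#'
#' Each accession homozygous at all chosen loci gets an allele string
#' (reference base for dosage 0, alternative base for dosage 2, in marker
#' order) and a class label `Hap1..HapK`. Heterozygous or missing accessions
#' are excluded with a logged count. Default class ordering is ascending
#' count of alternative alleles, ties broken by descending class frequency,
#' then alphabetically — so Hap1 is the all-reference configuration and HapK
#' the all-alternative one. An explicit `anchor` vector of allele strings
#' forces a fixed ordering instead.
#'
#' @param G a `genotype_matrix`.
#' @param marker_ids focal marker ids, in display order.
#' @param anchor optional character vector of allele strings fixing the
#'   class order; observed strings missing from it are appended under the
#'   default rule.
#' @return object of class `haplotype_table`: list with `marker_ids`,
#'   `markers` (their rows of the marker table), `assignments` (data.frame:
#'   accession, allele_string, alt_count, class), `classes` (data.frame:
#'   class, allele_string, alt_count, n), `n_excluded`.
#' @export
build_haplotypes <- function(G, marker_ids, anchor = NULL) {
  missing_ids <- setdiff(marker_ids, G$markers$id)
  if (length(missing_ids) > 0)
    stop("marker id(s) not in genotype matrix: ",
         paste(missing_ids, collapse = ", "))
  j <- match(marker_ids, G$markers$id)
  D <- G$dosages[, j, drop = FALSE]
  ok <- apply(D, 1, function(d) all(!is.na(d) & d %in% c(0L, 2L)))
  n_excluded <- sum(!ok)
  if (n_excluded > 0)
    message(n_excluded, " accession(s) heterozygous or missing at a focal ",
            "locus excluded from haplotype assignment")
  if (!any(ok)) stop("no accession is homozygous at all focal loci")
  D <- D[ok, , drop = FALSE]
  mk <- G$markers[j, , drop = FALSE]
  strings <- apply(D, 1, function(d)
    paste0(ifelse(d == 0L, mk$ref, mk$alt), collapse = ""))
  alt_count <- as.integer(rowSums(D) / 2L)

  tab <- table(strings)
  uniq <- data.frame(allele_string = names(tab), n = as.integer(tab),
                     stringsAsFactors = FALSE)
  uniq$alt_count <- vapply(uniq$allele_string, function(s) {
    sum(strsplit(s, "")[[1]] != mk$ref)
  }, integer(1))
  ord <- order(uniq$alt_count, -uniq$n, uniq$allele_string)
  uniq <- uniq[ord, , drop = FALSE]
  if (!is.null(anchor)) {
    anchored <- intersect(anchor, uniq$allele_string)
    rest <- setdiff(uniq$allele_string, anchored)
    uniq <- uniq[match(c(anchored, rest), uniq$allele_string), , drop = FALSE]
  }
  uniq$class <- paste0("Hap", seq_len(nrow(uniq)))

  assignments <- data.frame(accession = rownames(D),
                            allele_string = strings,
                            alt_count = alt_count,
                            class = uniq$class[match(strings, uniq$allele_string)],
                            stringsAsFactors = FALSE)
  structure(list(marker_ids = marker_ids, markers = mk,
                 assignments = assignments,
                 classes = uniq[, c("class", "allele_string", "alt_count", "n")],
                 n_excluded = n_excluded),
            class = "haplotype_table")
}

#' @method print haplotype_table
#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype_table:", nrow(x$classes), "classes over",
      length(x$marker_ids), "loci (", paste(x$marker_ids, collapse = ", "), ")\n")
  print(x$classes, row.names = FALSE)
  if (x$n_excluded > 0)
    cat("  ", x$n_excluded, "accession(s) excluded (het/missing)\n")
  invisible(x)
}

#' Per-class trait statistics
#'
#' @param table a `haplotype_table`.
#' @param trait_values named numeric vector of trait values by accession.
#' @return data.frame per class: `class`, `allele_string`, `n` (accessions
#'   with a trait value), `mean`, `sd` (n-1 denominator; `NA` with
#'   `sd_undefined` flag for singleton classes).
#' @export
haplotype_group_stats <- function(table, trait_values) {
  stopifnot(inherits(table, "haplotype_table"))
  if (is.null(names(trait_values)))
    stop("trait_values must be named by accession id")
  a <- table$assignments
  a$value <- trait_values[a$accession]
  a <- a[!is.na(a$value), , drop = FALSE]
  out <- lapply(seq_len(nrow(table$classes)), function(i) {
    cl <- table$classes$class[i]
    v <- a$value[a$class == cl]
    if (length(v) == 0) {
      warning("class ", cl, " has no trait values; omitted")
      return(NULL)
    }
    data.frame(class = cl, allele_string = table$classes$allele_string[i],
               n = length(v), mean = mean(v),
               sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
               sd_undefined = length(v) < 2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Compact letter display by maximal cliques of the "not significantly
# different" graph: groups share a letter iff their pairwise p >= alpha.
compact_letters <- function(group_names, pair_p, alpha = 0.05,
                            group_means = NULL) {
  k <- length(group_names)
  if (k == 1) return(stats::setNames("a", group_names))
  adj <- matrix(FALSE, k, k, dimnames = list(group_names, group_names))
  for (i in seq_len(nrow(pair_p)))
    adj[pair_p$group1[i], pair_p$group2[i]] <-
      adj[pair_p$group2[i], pair_p$group1[i]] <- pair_p$p[i] >= alpha
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  cl <- igraph::max_cliques(g)
  members <- lapply(cl, function(x) group_names[as.integer(x)])
  # order cliques by the best (largest-mean) member so 'a' marks the top group
  if (is.null(group_means)) group_means <- stats::setNames(rep(0, k), group_names)
  best <- vapply(members, function(m) max(group_means[m]), numeric(1))
  members <- members[order(-best)]
  letters_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- stats::setNames(rep("", k), group_names)
  for (i in seq_along(members))
    out[members[[i]]] <- paste0(out[members[[i]]], letters_pool[i])
  vapply(out, function(s) paste(sort(strsplit(s, "")[[1]]), collapse = ""),
         character(1))
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Pairwise comparisons use the studentized-range (Tukey HSD) test at
#' family level `alpha`; unequal group sizes get the Tukey-Kramer
#' adjustment, as computed by [stats::TukeyHSD()]. Letters come from the
#' maximal-clique compact letter display: two groups share a letter exactly
#' when their Tukey p-value is at least `alpha`.
#'
#' @param values numeric response vector.
#' @param groups group labels aligned to `values`.
#' @param alpha family-wise level (default 0.05).
#' @return list with `F`, `p`, `df` (between/within), `tukey` (data.frame:
#'   group1, group2, diff, p), `letters` (named by group, ordered by
#'   descending group mean), `group_means`.
#' @export
anova_tukey_letters <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("at least 2 groups are required")
  sizes <- table(groups)
  if (any(sizes < 2)) stop("every group needs at least 2 observations")
  dat <- data.frame(y = values, g = groups)
  av <- stats::aov(y ~ g, data = dat)
  tab <- summary(av)[[1]]
  tk <- stats::TukeyHSD(av, conf.level = 1 - alpha)$g
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  pair_p <- data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                       diff = tk[, "diff"], p = tk[, "p adj"],
                       stringsAsFactors = FALSE, row.names = NULL)
  gm <- tapply(values, groups, mean)
  letters <- compact_letters(levels(groups), pair_p, alpha, gm)
  list(F = tab["g", "F value"], p = tab["g", "Pr(>F)"],
       df = c(between = tab["g", "Df"], within = tab["Residuals", "Df"]),
       tukey = pair_p,
       letters = letters[order(-gm[names(letters)])],
       group_means = gm)
}
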