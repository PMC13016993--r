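# Gas-exchange derived quantities and Ball-Woodrow-Berry (BWB) model
# fitting. The BWB model is the linear relation
#   gsw = m * An * Hs / Cs + g0
# where An*Hs/Cs is the "ball index" (mol m^-2 s^-1 when An is in
# mol m^-2 s^-1 and Cs in mol mol^-1, or equivalently umol/umol), m is the
# dimensionless stomatal-sensitivity slope, and g0 the residual conductance
# as An approaches zero.

#' Intrinsic water-use efficiency
#'
#' @param An net CO2 assimilation, umol m^-2 s^-1.
#' @param gsw stomatal conductance to water vapor, mol m^-2 s^-1 (> 0).
#' @return iWUE = An / gsw, umol CO2 mol^-1 H2O.
#' @export
iwue <- function(An, gsw) {
  if (any(gsw <= 0)) stop("gsw must be positive")
  An / gsw
}

#' Ball index An * Hs / Cs
#'
#' @param An net CO2 assimilation, umol m^-2 s^-1.
#' @param Hs relative humidity at the leaf surface as a fraction in (0, 1].
#'   Values above 1 are rejected: percent was passed where a fraction is
#'   expected.
#' @param Cs CO2 mole fraction at the leaf surface, umol mol^-1.
#' @return ball index, mol m^-2 s^-1.
#' @export
ball_index <- function(An, Hs, Cs) {
  if (any(Hs > 1))
    stop("Hs must be a fraction in (0,1]; it looks like percent was passed ",
         "(divide by 100)")
  if (any(Hs <= 0)) stop("Hs must be in (0,1]")
  if (any(Cs <= 0)) stop("Cs must be positive")
  An * Hs / Cs
}

#' Maximum quantum yield of photosystem II
#'
#' @param F0 minimum (dark-adapted) fluorescence, arbitrary units.
#' @param Fm maximum fluorescence after a saturating flash.
#' @return Fv/Fm = (Fm - F0) / Fm, in (0, 1).
#' @export
fv_fm <- function(F0, Fm) {
  if (any(F0 <= 0)) stop("F0 must be positive")
  if (any(Fm <= F0)) stop("Fm must exceed F0")
  (Fm - F0) / Fm
}

#' Fit the Ball-Woodrow-Berry model to one light-response curve
#'
#' Ordinary least squares of gsw on the ball index over the records of one
#' accession x treatment x replicate. The intercept g0 is unconstrained; a
#' negative estimate is flagged, not clipped.
#'
#' @param records data.frame with columns `An`, `gsw`, `Hs`, `Cs` and
#'   (optionally) `accession`, `treatment`, `replicate` carried into the fit.
#' @return object of class `bwb_fit`: list with `m`, `g0`, `r2`, `n_points`,
#'   `accession`, `treatment`, `replicate`, and flags `g0_negative`, `low_n`
#'   (n < 5).
#' @export
fit_bwb <- function(records) {
  stopifnot(all(c("An", "gsw", "Hs", "Cs") %in% names(records)))
  n <- nrow(records)
  if (n < 3) stop("at least 3 records are required to fit the BWB model")
  bi <- ball_index(records$An, records$Hs, records$Cs)
  if (stats::sd(bi) == 0 || diff(range(bi)) < 1e-12)
    stop("degenerate fit: ball index has no spread")
  fit <- stats::lm(records$gsw ~ bi)
  # r2 computed directly; summary.lm warns on noise-free curves
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((records$gsw - mean(records$gsw))^2)
  first <- function(col) if (col %in% names(records)) records[[col]][1] else NA
  structure(list(m = unname(stats::coef(fit)[2]),
                 g0 = unname(stats::coef(fit)[1]),
                 r2 = r2, n_points = n,
                 accession = first("accession"),
                 treatment = first("treatment"),
                 replicate = first("replicate"),
                 g0_negative = unname(stats::coef(fit)[1]) < 0,
                 low_n = n < 5),
            class = "bwb_fit")
}

#' @method print bwb_fit
#' @export
print.bwb_fit <- function(x, ...) {
  cat(sprintf("BWB fit: m = %.4f, g0 = %.4f mol m-2 s-1, r2 = %.4f (n = %d)\n",
              x$m, x$g0, x$r2, x$n_points))
  if (x$g0_negative) cat("  note: g0 < 0 (unconstrained intercept)\n")
  invisible(x)
}

#' Fit BWB per replicate across a gas-exchange table
#'
#' @param records data.frame of light-response observations with columns
#'   `accession`, `treatment`, `replicate`, `An`, `gsw`, `Hs`, `Cs`.
#' @return data.frame, one row per accession x treatment x replicate, with
#'   `m`, `g0`, `r2`, `n_points` and `iwue_top` (An/gsw at the highest-PPFD
#'   record, used as the fit-level iWUE summary).
#' @export
fit_bwb_all <- function(records) {
  key <- interaction(records$accession, records$treatment, records$replicate,
                     drop = TRUE)
  out <- lapply(split(records, key), function(sub) {
    f <- fit_bwb(sub)
    top <- if ("ppfd" %in% names(sub)) which.max(sub$ppfd) else which.max(sub$An)
    data.frame(accession = f$accession, treatment = f$treatment,
               replicate = f$replicate, m = f$m, g0 = f$g0, r2 = f$r2,
               n_points = f$n_points,
               iwue_top = iwue(sub$An[top], sub$gsw[top]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$accession, res$treatment, res$replicate), ]
}

#' Pooled treatment-level regression points
#'
#' Builds the per-treatment point cloud used for the pooled ball-index
#' regression: one point per PPFD level x accession, with the 3 biological
#' replicates averaged first (so 11 PPFD levels x 8 accessions give 88
#' points per water regime).
#'
#' @param records light-response table as in [fit_bwb_all()].
#' @param average_replicates average replicate curves per accession x PPFD
#'   (default) or keep raw points.
#' @return data.frame with `treatment`, `accession`, `ppfd`, `An`, `gsw`,
#'   `Hs`, `Cs`, `ball_index`.
#' @export
bwb_pooled_points <- function(records, average_replicates = TRUE) {
  stopifnot(all(c("accession", "treatment", "ppfd", "An", "gsw", "Hs", "Cs")
                %in% names(records)))
  if (average_replicates) {
    agg <- stats::aggregate(records[, c("An", "gsw", "Hs", "Cs")],
                            by = list(treatment = records$treatment,
                                      accession = records$accession,
                                      ppfd = records$ppfd),
                            FUN = mean)
  } else {
    agg <- records[, c("treatment", "accession", "ppfd", "An", "gsw", "Hs", "Cs")]
  }
  agg$ball_index <- ball_index(agg$An, agg$Hs, agg$Cs)
  agg[order(agg$treatment, agg$accession, -agg$ppfd), ]
}

#' Compare BWB slopes between water regimes
#'
#' Per accession, a two-sample Student's t-test on replicate-level slopes
#' (well-watered vs water-stressed); overall, a two-way fixed-effects ANOVA
#' of m on accession x treatment; plus the Pearson correlation between m
#' and fit-level iWUE across all fits.
#'
#' @param fits data.frame from [fit_bwb_all()] covering both treatments.
#' @param alpha significance level for reporting (default 0.05).
#' @return list with elements `per_accession` (data.frame: accession, mean m
#'   per treatment, t, p, direction), `anova` (data.frame of the two-way
#'   ANOVA table), `interaction_p`, `treatment_p`, and `m_iwue_cor`
#'   (list: r, p).
#' @export
compare_slopes <- function(fits, alpha = 0.05) {
  stopifnot(all(c("accession", "treatment", "m") %in% names(fits)))
  trts <- sort(unique(fits$treatment))
  if (length(trts) != 2) stop("exactly two treatments are required")
  per <- lapply(split(fits, fits$accession), function(sub) {
    a <- sub$m[sub$treatment == trts[1]]
    b <- sub$m[sub$treatment == trts[2]]
    if (length(a) < 2 || length(b) < 2) {
      tt <- list(statistic = NA_real_, p.value = NA_real_)
    } else if (stats::sd(c(a, b)) < 1e-12) {
      tt <- list(statistic = 0, p.value = 1)  # identical samples
    } else {
      tt <- stats::t.test(a, b)
    }
    data.frame(accession = sub$accession[1],
               m_1 = mean(a), m_2 = mean(b),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  names(per)[2:3] <- paste0("m_", trts)
  rownames(per) <- NULL

  cc <- stats::complete.cases(fits[, c("accession", "treatment", "m")])
  if (!all(cc)) warning("ANOVA computed on available cells only")
  dat <- fits[cc, ]
  dat$accession <- factor(dat$accession)
  dat$treatment <- factor(dat$treatment)
  form <- if (nlevels(dat$accession) > 1) m ~ accession * treatment
          else m ~ treatment  # interaction undefined with one accession
  av <- stats::aov(form, data = dat)
  tab <- summary(av)[[1]]
  term <- trimws(rownames(tab))
  getp <- function(t) if (t %in% term) tab[term == t, "Pr(>F)"] else NA_real_
  res <- list(per_accession = per,
              anova = data.frame(term = term, tab, check.names = FALSE,
                                 row.names = NULL),
              interaction_p = getp("accession:treatment"),
              treatment_p = getp("treatment"))
  if ("iwue_top" %in% names(fits) && stats::sd(fits$iwue_top) > 0 &&
      stats::sd(fits$m) > 0) {
    ct <- stats::cor.test(fits$m, fits$iwue_top)
    res$m_iwue_cor <- list(r = unname(ct$estimate), p = ct$p.value)
  } else {
    res$m_iwue_cor <- list(r = NA_real_, p = NA_real_)
  }
  res
}
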