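# Plot-level random-intercept mixed model for field adjustment:
# trait ~ row + column + AveT + AveH + (1 | accession), fitted by REML.
# Accession predictions (fixed part at reference covariates + BLUP) feed
# the association scan.

#' Fit the field random-intercept model by REML
#'
#' Row and column enter as categorical fixed effects by default, absorbing
#' arbitrary spatial gradients; `categorical_rowcol = FALSE` keeps them
#' numeric. Aliased fixed-effect columns are dropped (with a message) rather
#' than erroring, as field layouts routinely alias. A fit whose accession
#' variance is estimated at the boundary (singular fit) is flagged, not
#' rejected.
#'
#' @param data plot-level data.frame with columns `accession`, `row`,
#'   `column`, the covariates, and the trait.
#' @param trait name of the trait column to model.
#' @param covariates weather covariates included as fixed effects
#'   (default `c("AveT", "AveH")`; may be empty).
#' @param use_rowcol include row/column fixed effects (default TRUE).
#' @param categorical_rowcol treat row/column as factors (default TRUE).
#' @return object of class `mixed_model_result`: list with
#'   `fixed_coefficients`, `sigma2_accession`, `sigma2_residual`, `blups`
#'   (named vector, shrunken accession intercepts), `predictions` (named
#'   vector, see [predict_accession_values()]), `logREML`, `converged`,
#'   `boundary`, `n_obs`, `n_accessions`, and the fitted `lme4` object in
#'   `fit`.
#' @export
fit_random_intercept_reml <- function(data, trait,
                                      covariates = c("AveT", "AveH"),
                                      use_rowcol = TRUE,
                                      categorical_rowcol = TRUE) {
  stopifnot(trait %in% names(data), "accession" %in% names(data))
  data <- data[!is.na(data[[trait]]), , drop = FALSE]
  if (length(unique(data$accession)) < 2)
    stop("at least 2 accessions are required")
  if (nrow(data) < 4) stop("too few plots to fit the model")
  dat <- data
  dat$.y <- dat[[trait]]
  terms <- character(0)
  if (use_rowcol && all(c("row", "column") %in% names(dat))) {
    if (categorical_rowcol) {
      dat$row <- factor(dat$row)
      dat$column <- factor(dat$column)
    }
    terms <- c(terms, "row", "column")
  }
  terms <- c(terms, intersect(covariates, names(dat)))
  rhs <- if (length(terms) > 0) paste(terms, collapse = " + ") else "1"
  form <- stats::as.formula(paste(".y ~", rhs, "+ (1 | accession)"))

  fit <- withCallingHandlers(
    lme4::lmer(form, data = dat, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE)),
    message = function(m) {
      if (grepl("rank deficient", conditionMessage(m)))
        message("aliased fixed-effect column(s) dropped: ",
                trimws(conditionMessage(m)))
      invokeRestart("muffleMessage")
    })

  vc <- as.data.frame(lme4::VarCorr(fit))
  s2a <- vc$vcov[vc$grp == "accession"]
  s2e <- vc$vcov[vc$grp == "Residual"]
  conv <- length(fit@optinfo$conv$lme4) == 0
  boundary <- lme4::isSingular(fit, tol = 1e-6)
  re <- lme4::ranef(fit)$accession
  blups <- stats::setNames(re[, "(Intercept)"], rownames(re))

  res <- structure(list(fixed_coefficients = lme4::fixef(fit),
                        sigma2_accession = s2a, sigma2_residual = s2e,
                        blups = blups,
                        logREML = as.numeric(stats::logLik(fit)),
                        converged = conv, boundary = boundary,
                        n_obs = nrow(dat),
                        n_accessions = length(blups),
                        trait = trait, fit = fit),
                   class = "mixed_model_result")
  res$predictions <- predict_accession_values(res)
  res
}

#' @method print mixed_model_result
#' @export
print.mixed_model_result <- function(x, ...) {
  cat("Random-intercept REML fit for", x$trait, "\n")
  cat(sprintf("  sigma2_accession = %.6g, sigma2_residual = %.6g\n",
              x$sigma2_accession, x$sigma2_residual))
  cat(sprintf("  %d plots, %d accessions; logREML = %.3f%s%s\n",
              x$n_obs, x$n_accessions, x$logREML,
              if (!x$converged) "; NOT CONVERGED" else "",
              if (x$boundary) "; variance at boundary" else ""))
  invisible(x)
}

#' Accession-level predicted values from a fitted field model
#'
#' Default mode `"reference"` evaluates the fixed part at reference
#' covariates — the fitted fixed-effect predictor averaged over all plots,
#' which puts AveT/AveH at their means and averages row/column effects
#' out — and adds each accession's BLUP. Mode `"observed"` instead averages
#' the fixed part over the accession's own plots, reproducing a
#' predict-then-average workflow on observed covariates.
#'
#' @param result a `mixed_model_result`.
#' @param accessions accessions to predict (default: all fitted ones).
#' @param mode `"reference"` (default) or `"observed"`.
#' @return named numeric vector of predicted accession values.
#' @export
predict_accession_values <- function(result, accessions = NULL,
                                     mode = c("reference", "observed")) {
  stopifnot(inherits(result, "mixed_model_result"))
  mode <- match.arg(mode)
  fit <- result$fit
  fixed_part <- stats::predict(fit, re.form = NA)  # X beta per plot
  fr <- stats::model.frame(fit)
  acc_of_plot <- as.character(fr$accession)
  all_acc <- names(result$blups)
  if (is.null(accessions)) accessions <- all_acc
  unknown <- setdiff(accessions, all_acc)
  if (length(unknown) > 0)
    stop("unknown accession(s): ", paste(unknown, collapse = ", "))
  base <- if (mode == "reference") {
    stats::setNames(rep(mean(fixed_part), length(accessions)), accessions)
  } else {
    vapply(accessions, function(a) mean(fixed_part[acc_of_plot == a]),
           numeric(1))
  }
  base + result$blups[accessions]
}

#' AIC comparison of weather-covariate model variants
#'
#' Refits the field model by maximum likelihood with and without the
#' weather covariates and compares by AIC (lower is better), the criterion
#' used for covariate selection.
#'
#' @param data,trait,use_rowcol,categorical_rowcol as in
#'   [fit_random_intercept_reml()].
#' @param covariates covariates whose inclusion is tested.
#' @return data.frame with one row per variant: `model`, `AIC`, `logLik`,
#'   `preferred` flag.
#' @export
compare_weather_models <- function(data, trait, covariates = c("AveT", "AveH"),
                                   use_rowcol = TRUE,
                                   categorical_rowcol = TRUE) {
  fit_ml <- function(covs) {
    r <- fit_random_intercept_reml(data, trait, covariates = covs,
                                   use_rowcol = use_rowcol,
                                   categorical_rowcol = categorical_rowcol)
    ml <- stats::update(r$fit, REML = FALSE)
    c(AIC = stats::AIC(ml), logLik = as.numeric(stats::logLik(ml)))
  }
  with_w <- fit_ml(covariates)
  without <- fit_ml(character(0))
  out <- data.frame(model = c(paste0("with ", paste(covariates, collapse = "+")),
                              "without weather covariates"),
                    AIC = c(with_w["AIC"], without["AIC"]),
                    logLik = c(with_w["logLik"], without["logLik"]))
  out$preferred <- out$AIC == min(out$AIC)
  out
}
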