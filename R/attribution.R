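# Factor-deleted counterfactual PAF engine: predict expected costs under
# observed exposures and again after recoding exposures to their
# reference ("no exposure") levels; the relative difference of the
# weighted totals is the population attributable fraction.

#' Standard counterfactual recoding rules
#'
#' Returns the recoding rule for a named risk: each single behaviour,
#' the combined behaviours (`behaviours`), or the socioeconomic equity
#' gap (`ses`, everyone recoded to post-secondary education, income
#' >= $80,000, owned home, low deprivation).
#'
#' @param risk One of `smoking`, `alcohol`, `diet`, `activity`,
#'   `behaviours`, `ses`.
#' @param heavy_only Logical; for alcohol, recode only heavy drinkers to
#'   moderate (leave non-drinkers untouched) instead of recoding every
#'   non-reference level.
#' @return Named character vector (variable -> reference level) of class
#'   `recoding_rule`.
#' @export
attribution_rule <- function(risk, heavy_only = FALSE) {
  beh <- behaviour_reference_levels()
  rule <- switch(risk,
    smoking = beh["smoking"],
    alcohol = beh["alcohol"],
    diet = beh["diet"],
    activity = beh["activity"],
    behaviours = beh,
    ses = ses_reference_levels(),
    stop("unknown risk '", risk, "'")
  )
  structure(rule, class = "recoding_rule",
            heavy_only = isTRUE(heavy_only) && "alcohol" %in% names(rule))
}

#' Recode a cohort to a counterfactual reference
#'
#' Sets every non-reference, non-missing level of each target variable to
#' its reference level (for smoking this turns current and former smokers
#' into non-smokers); all other columns are untouched.  Missing stays
#' missing: item non-response is not converted into exposure information.
#'
#' @param cohort Cohort data frame.
#' @param rule Named character vector, variable -> reference level (see
#'   [attribution_rule()]); an empty rule returns the cohort unchanged.
#' @return A recoded copy of the cohort.
#' @export
counterfactual_recode <- function(cohort, rule) {
  if (length(rule) == 0L) return(cohort)
  heavy_only <- isTRUE(attr(rule, "heavy_only"))
  for (v in names(rule)) {
    if (!v %in% names(cohort)) stop("unknown variable '", v, "' in recoding rule")
    x <- as.character(cohort[[v]])
    sel <- !is.na(x) & x != "missing" & x != rule[[v]]
    if (v == "alcohol" && heavy_only) sel <- sel & x == "heavy"
    x[sel] <- rule[[v]]
    if (is.factor(cohort[[v]])) {
      cohort[[v]] <- factor(x, levels = levels(cohort[[v]]))
    } else cohort[[v]] <- x
  }
  cohort
}

# weighted predicted totals under a model (or per-sex model list)
.predicted_total <- function(models, cohort, weights) {
  if (inherits(models, "cost_model")) models <- list(models)
  tot <- 0
  used <- rep(FALSE, nrow(cohort))
  for (m in models) {
    sel <- cohort$sex == m$sex
    if (!any(sel)) next
    used <- used | sel
    tot <- tot + sum(weights[sel] * predict_expected_cost(m, cohort[sel, , drop = FALSE]))
  }
  if (!all(used)) stop("no model provided for sex '",
                       paste(unique(cohort$sex[!used]), collapse = ", "), "'")
  tot
}

#' Population attributable fraction by factor deletion
#'
#' PAF = (sum(w * mu) - sum(w * mu0)) / sum(w * mu), where mu is the
#' model-predicted expected annual cost under observed exposures and mu0
#' under the counterfactual recoding.  When sex-specific models are
#' supplied (a list, or a `model_suite` plus `sector`/`step`), both
#' sexes' weighted predictions are pooled before the ratio, giving a
#' population-level PAF from sex-specific models.  The PAF may be
#' negative when the reference level is not cost-minimal.
#'
#' @param models A `cost_model`, a list of sex-specific `cost_model`s, or
#'   a `model_suite`.
#' @param cohort Cohort data frame (the weighted survey cycle).
#' @param rule Recoding rule (see [attribution_rule()]).
#' @param weights Survey weights (default column `weight`, else 1).
#' @param sector,step Used to select models when `models` is a
#'   `model_suite` (default step 3, the primary attribution model).
#' @return PAF as a dimensionless fraction.
#' @export
paf <- function(models, cohort, rule, weights = NULL, sector = NULL, step = 3) {
  if (inherits(models, "model_suite")) {
    if (is.null(sector)) stop("sector must be given with a model_suite")
    models <- list(suite_model(models, "male", sector, step),
                   suite_model(models, "female", sector, step))
  }
  if (is.null(weights))
    weights <- if ("weight" %in% names(cohort)) cohort$weight else rep(1, nrow(cohort))
  stopifnot(length(weights) == nrow(cohort))
  base <- .predicted_total(models, cohort, weights)
  if (base <= 0) stop("total predicted cost is zero; PAF undefined")
  cf <- .predicted_total(models, counterfactual_recode(cohort, rule), weights)
  (base - cf) / base
}

#' Combined-behaviour PAF
#'
#' Single PAF from simultaneously recoding smoking, alcohol, diet and
#' physical activity to their reference levels.
#'
#' @inheritParams paf
#' @return PAF fraction.
#' @export
combined_paf <- function(models, cohort, weights = NULL, sector = NULL, step = 3) {
  paf(models, cohort, attribution_rule("behaviours"), weights = weights,
      sector = sector, step = step)
}

#' Annual PAF series with between-cycle interpolation
#'
#' Cycle years keep their estimated PAF; each year between cycles gets
#' the arithmetic mean of the nearest preceding and succeeding cycle
#' estimates.  Years outside the covered span are an error (no
#' extrapolation).
#'
#' @param cycle_pafs Named numeric vector, names = cycle years.
#' @param years Integer years to cover (default the full cycle span).
#' @return Data frame (year, paf, provenance) where provenance is
#'   `cycle_estimate` or `interpolated`.
#' @export
annual_paf_series <- function(cycle_pafs,
                              years = seq(min(cyc), max(cyc))) {
  stopifnot(length(cycle_pafs) >= 1L, !is.null(names(cycle_pafs)))
  cyc <- as.integer(names(cycle_pafs))
  stopifnot(!anyNA(cyc))
  o <- order(cyc)
  cyc <- cyc[o]; est <- as.numeric(cycle_pafs)[o]
  years <- as.integer(years)
  if (any(years < min(cyc)) || any(years > max(cyc)))
    stop("years outside the covered cycle span [", min(cyc), ", ", max(cyc),
         "]; no extrapolation")
  paf <- numeric(length(years))
  prov <- character(length(years))
  for (i in seq_along(years)) {
    y <- years[i]
    if (y %in% cyc) {
      paf[i] <- est[match(y, cyc)]
      prov[i] <- "cycle_estimate"
    } else {
      paf[i] <- mean(c(est[max(which(cyc < y))], est[min(which(cyc > y))]))
      prov[i] <- "interpolated"
    }
  }
  data.frame(year = years, paf = paf, provenance = prov)
}

#' Per-cycle PAF table across risks and sectors
#'
#' Computes, for each survey cycle in the cohort, the factor-deleted PAF
#' for each requested risk and sector from the step-`step` sex-specific
#' models, then expands to an annual series per (risk, sector) with
#' between-cycle interpolation.
#'
#' @param suite A `model_suite`.
#' @param cohort Scored multi-cycle cohort with a `cycle_year` column.
#' @param risks Risk names understood by [attribution_rule()].
#' @param sectors Sector names.
#' @param step Ladder step used for prediction (default 3).
#' @param heavy_only Passed to [attribution_rule()] for alcohol.
#' @param years Years for the annual series (default full cycle span).
#' @return Data frame (risk, sector, year, paf, provenance).
#' @export
paf_series <- function(suite, cohort,
                       risks = c("smoking", "alcohol", "diet", "activity",
                                 "behaviours", "ses"),
                       sectors = SECTORS, step = 3, heavy_only = FALSE,
                       years = NULL) {
  stopifnot("cycle_year" %in% names(cohort))
  cycles <- sort(unique(cohort$cycle_year))
  if (is.null(years)) years <- seq(min(cycles), max(cycles))
  out <- list()
  for (r in risks) {
    rule <- attribution_rule(r, heavy_only = heavy_only)
    for (s in sectors) {
      est <- vapply(cycles, function(cy) {
        cyc <- cohort[cohort$cycle_year == cy, , drop = FALSE]
        paf(suite, cyc, rule, sector = s, step = step)
      }, numeric(1))
      ser <- annual_paf_series(stats::setNames(est, cycles), years)
      ser$risk <- r; ser$sector <- s
      out[[length(out) + 1L]] <- ser
    }
  }
  res <- do.call(rbind, out)
  res[, c("risk", "sector", "year", "paf", "provenance")]
}

#' Write a PAF series as tidy CSV
#'
#' @param series Data frame from [paf_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_paf_series <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}
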