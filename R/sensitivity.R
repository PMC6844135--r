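# Sensitivity analyses: ladder bounds on PAFs, top-5% high-cost-user
# exclusion with age-standardized cost ratios, and inverse probability of
# treatment weighted cost ratios.

#' Ladder-bound PAF estimates
#'
#' The primary attribution estimate (ladder step 3) bracketed by the
#' minimally adjusted health-behaviour model (step 1, upper bound) and
#' the over-adjusted proximal-mediator model (step 5, lower bound).
#' Attribution typically shrinks as more risk factors are adjusted for;
#' the ordering is recorded, not enforced.
#'
#' @param suite A `model_suite` with steps 1, 3 and 5 fitted.
#' @param cohort Cohort data frame.
#' @param rule Recoding rule (see [attribution_rule()]).
#' @param sector Sector name.
#' @param weights Optional survey weights (default cohort `weight`).
#' @return List of class `bounded_estimate`: `primary`, `upper`, `lower`,
#'   and `ordered` (whether upper >= primary >= lower held).
#' @export
bound_estimates <- function(suite, cohort, rule, sector, weights = NULL) {
  est <- vapply(c(1, 3, 5), function(st)
    paf(suite, cohort, rule, weights = weights, sector = sector, step = st),
    numeric(1))
  structure(list(primary = est[2], upper = est[1], lower = est[3],
                 ordered = est[1] >= est[2] && est[2] >= est[3]),
            class = "bounded_estimate")
}

#' @export
print.bounded_estimate <- function(x, ...) {
  cat(sprintf("PAF %.4f (ladder bounds: upper %.4f, lower %.4f)%s\n",
              x$primary, x$upper, x$lower,
              if (x$ordered) "" else "  [bounds not ordered]"))
  invisible(x)
}

#' Exclude the top fraction of health care users
#'
#' Removes the ceiling(fraction x n) persons with the highest total cost
#' across all sectors combined over follow-up.  Ties at the cut are
#' broken by stable person-id order (smallest ids removed first) with a
#' warning.
#'
#' @param cohort Cohort data frame with `cost_*` columns and `person_id`.
#' @param fraction Fraction to remove, in (0, 1); default 0.05.
#' @return The remaining cohort, with an `exclusion` attribute listing
#'   removed ids, the count and the cost cutoff.
#' @export
exclude_top_users <- function(cohort, fraction = 0.05) {
  if (!(is.numeric(fraction) && length(fraction) == 1L &&
        fraction > 0 && fraction < 1))
    stop("fraction must lie strictly between 0 and 1")
  cost_cols <- grep("^cost_", names(cohort), value = TRUE)
  if (!length(cost_cols)) stop("cohort has no cost columns")
  total <- rowSums(cohort[, cost_cols, drop = FALSE])
  k <- ceiling(fraction * nrow(cohort))
  ord <- order(-total, cohort$person_id)
  removed <- ord[seq_len(k)]
  cutoff <- total[ord[k]]
  if (k < nrow(cohort) && total[ord[k + 1L]] == cutoff)
    warning("ties at the exclusion cutoff broken by person_id order")
  out <- cohort[-removed, , drop = FALSE]
  attr(out, "exclusion") <- list(
    n_removed = k, fraction = fraction,
    removed_ids = cohort$person_id[removed], cost_cutoff = cutoff)
  out
}

#' Survey-weighted standard age distribution
#'
#' The survey-weighted age-group distribution of a cohort, used as the
#' default standard population for age standardization.
#'
#' @param cohort Cohort data frame with `age_group` and `weight`.
#' @return Named numeric vector of weights summing to 1.
#' @export
standard_population <- function(cohort) {
  w <- tapply(cohort$weight, cohort$age_group, sum)
  w <- w / sum(w)
  w[!is.na(w)]
}

#' Age-standardized cost ratio between two exposure levels
#'
#' Within each age group, the survey-weighted mean annualized total cost
#' is computed for the exposed and reference strata; the ratio of the
#' standard-population-weighted averages is returned.  Age groups where
#' either stratum is empty are dropped from both sums symmetrically,
#' with a warning.
#'
#' @param cohort Cohort with `age_group`, `weight`, `person_years` and
#'   `cost_*` columns.
#' @param variable Exposure column name.
#' @param exposure_level,reference_level Category labels to compare.
#' @param std Standard population (named weights by age group); default
#'   the survey-weighted age distribution of `cohort`.
#' @param sector Optional sector; default uses total cost over all
#'   sectors.
#' @return The age-standardized cost ratio (exposed / reference).
#' @export
age_standardized_cost_ratio <- function(cohort, variable, exposure_level,
                                        reference_level, std = NULL,
                                        sector = NULL) {
  cost <- if (is.null(sector)) {
    rowSums(cohort[, grep("^cost_", names(cohort), value = TRUE), drop = FALSE])
  } else cohort[[paste0("cost_", sector)]]
  rate <- cost / cohort$person_years
  lev <- as.character(cohort[[variable]])
  if (is.null(std)) std <- standard_population(cohort)
  stratum_mean <- function(level, age) {
    sel <- lev == level & cohort$age_group == age
    if (!any(sel)) return(NA_real_)
    stats::weighted.mean(rate[sel], cohort$weight[sel])
  }
  ages <- names(std)
  me <- vapply(ages, stratum_mean, numeric(1), level = exposure_level)
  mr <- vapply(ages, stratum_mean, numeric(1), level = reference_level)
  ok <- !is.na(me) & !is.na(mr)
  if (!any(ok)) stop("no age group contains both exposure levels")
  if (!all(ok))
    warning("dropping age group(s) with an empty stratum: ",
            paste(ages[!ok], collapse = ", "))
  w <- std[ok] / sum(std[ok])
  sum(w * me[ok]) / sum(w * mr[ok])
}

#' Inverse-probability-of-treatment-weighted cost ratios
#'
#' Fits a multinomial logistic propensity model for the treatment
#' variable given the covariates, weights each person by the stabilized
#' inverse probability of the level actually held (marginal level
#' probability over fitted probability), truncates weights at a
#' percentile, and returns the IPW-weighted mean annualized cost of each
#' level relative to the reference level.
#'
#' @param cohort Cohort data frame.
#' @param treatment Treatment column name (categorical).
#' @param covariates Character vector of covariate column names.
#' @param reference_level Reference category (default the package
#'   reference for the variable, else the first level).
#' @param truncate_at Percentile for weight truncation (default 0.99).
#' @param sector Optional sector for the cost outcome; default total.
#' @return Named vector of cost ratios (reference level = 1), with the
#'   stabilized weights as attribute `weights` and the number truncated
#'   as `n_truncated`.
#' @export
ipw_cost_ratio <- function(cohort, treatment, covariates,
                           reference_level = NULL, truncate_at = 0.99,
                           sector = NULL) {
  lev <- as.character(cohort[[treatment]])
  tab <- table(lev)
  if (length(tab) < 2L || any(tab == 0L)) stop("empty treatment level")
  if (is.null(reference_level))
    reference_level <- if (treatment %in% names(.REFERENCE_LEVELS))
      .REFERENCE_LEVELS[[treatment]] else names(tab)[1L]
  absent <- setdiff(covariates, names(cohort))
  if (length(absent))
    stop("missing covariate column(s): ", paste(absent, collapse = ", "))
  dat <- cohort[, covariates, drop = FALSE]
  dat[] <- lapply(dat, function(x) if (is.numeric(x)) x else factor(as.character(x)))
  dat$.treatment <- factor(lev, levels = c(reference_level,
                                           setdiff(names(tab), reference_level)))
  fml <- stats::reformulate(covariates, response = ".treatment")
  fit <- nnet::multinom(fml, data = dat, trace = FALSE, maxit = 200)
  pr <- stats::predict(fit, newdata = dat, type = "probs")
  if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)  # binary case
  colnames(pr) <- levels(dat$.treatment)
  p_obs <- pr[cbind(seq_len(nrow(pr)), match(lev, colnames(pr)))]
  if (any(p_obs < 1e-8))
    warning(sum(p_obs < 1e-8), " near-zero propensities (non-overlap)")
  marg <- as.numeric(tab[lev]) / length(lev)
  sw <- marg / pmax(p_obs, 1e-8)
  cap <- stats::quantile(sw, truncate_at)
  n_trunc <- sum(sw > cap)
  sw <- pmin(sw, cap)
  cost <- if (is.null(sector)) {
    rowSums(cohort[, grep("^cost_", names(cohort), value = TRUE), drop = FALSE])
  } else cohort[[paste0("cost_", sector)]]
  rate <- cost / cohort$person_years
  means <- vapply(names(tab), function(l)
    stats::weighted.mean(rate[lev == l], sw[lev == l]), numeric(1))
  out <- means / means[[reference_level]]
  attr(out, "weights") <- sw
  attr(out, "n_truncated") <- n_trunc
  out
}
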