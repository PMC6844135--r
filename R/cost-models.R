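# Sex- and sector-specific negative binomial cost models over a stepped
# covariate ladder.  Outcome: total sector cost (whole 2014 dollars) over
# individual follow-up; offset: log person-years, so coefficients act on
# annual cost rates.

SECTORS <- c("hospital", "drugs", "community")
LADDER_STEPS <- 1:5

#' Covariate ladder of the stepped modelling approach
#'
#' Five nested covariate sets: (1) health behaviour model — age plus the
#' four behaviours; (2) basic sociodemographic model — adds immigrant
#' status, education and marital status; (3) primary attribution model —
#' adds household income, home ownership, urban residence, neighbourhood
#' deprivation, ethnicity, self-perceived stress and flu vaccination;
#' (4) distal mediator model — adds health-status indicators (BMI,
#' hypertension, diabetes, heart disease, cancer, stroke, dementia);
#' (5) proximal mediator model — adds fragility.  Step 3 is the primary
#' attribution model; steps 1 and 5 serve as upper/lower sensitivity
#' bounds.
#'
#' @param step Integer 1-5.
#' @return Character vector of covariate column names (cumulative).
#' @export
ladder_covariates <- function(step) {
  stopifnot(length(step) == 1L, step %in% LADDER_STEPS)
  groups <- list(
    c("age_group", "smoking", "alcohol", "diet", "activity"),
    c("immigrant", "education", "marital"),
    c("income", "home_owned", "urban", "deprivation", "ethnicity",
      "stress", "flu_shot"),
    c("bmi", "hypertension", "diabetes", "heart_disease", "cancer",
      "stroke", "dementia"),
    c("fragility")
  )
  unlist(groups[seq_len(step)], use.names = FALSE)
}

# reference level per modelled variable; variables not listed use their
# first observed level
.REFERENCE_LEVELS <- c(
  smoking = "non", alcohol = "moderate", diet = "adequate",
  activity = "active", education = "postsecondary", income = "ge80k",
  home_owned = "yes", deprivation = "low", immigrant = "no",
  marital = "married", urban = "yes", ethnicity = "white", stress = "low",
  flu_shot = "no", bmi = "normal", hypertension = "no", diabetes = "no",
  heart_disease = "no", cancer = "no", stroke = "no", dementia = "no",
  fragility = "none"
)

#' Build the model design for one ladder step
#'
#' Checks that every covariate of the step exists in the cohort, converts
#' each to a factor with its reference level first (keeping `missing` as
#' an explicit level), and flags zero-variance covariates, which are
#' excluded from the design with a message rather than breaking the fit.
#'
#' @param cohort Cohort data frame with categorized columns.
#' @param step Ladder step 1-5.
#' @return List with `formula`, `variables`, `dropped` (degenerate
#'   variables), and `data` (the cohort with factors applied).
#' @export
build_design <- function(cohort, step) {
  vars <- ladder_covariates(step)
  absent <- setdiff(vars, names(cohort))
  if (length(absent))
    stop("cohort is missing covariate column(s): ", paste(absent, collapse = ", "))
  dropped <- character(0)
  for (v in vars) {
    x <- as.character(cohort[[v]])
    lev <- unique(x[!is.na(x)])
    if (length(lev) < 2L) {
      dropped <- c(dropped, v)
      next
    }
    ref <- if (v %in% names(.REFERENCE_LEVELS)) .REFERENCE_LEVELS[[v]] else lev[1L]
    if (!ref %in% lev) ref <- lev[1L]
    cohort[[v]] <- factor(x, levels = c(ref, sort(setdiff(lev, ref))))
  }
  if (length(dropped))
    message("excluding zero-variance covariate(s): ", paste(dropped, collapse = ", "))
  vars <- setdiff(vars, dropped)
  fml <- stats::reformulate(c(vars, "offset(log(person_years))"),
                            response = "cost_outcome")
  list(formula = fml, variables = vars, dropped = dropped, data = cohort)
}

#' Fit one negative binomial cost model
#'
#' Maximum likelihood negative binomial GLM (log link) for total sector
#' cost over follow-up with a log person-years offset, for one sex and
#' one ladder step.  Costs are rounded to whole dollars so the count
#' likelihood is well defined.  By default the fit is unweighted; survey
#' weights enter at the PAF prediction stage.  Set `weighted = TRUE` for
#' a pseudo-likelihood fit weighted by `weight`.
#'
#' @param cohort Cohort data frame (both sexes; filtered internally).
#' @param sex `male` or `female`.
#' @param sector One of `hospital`, `drugs`, `community`.
#' @param step Ladder step 1-5.
#' @param weighted Logical, survey-weighted pseudo-likelihood fit.
#' @return Object of class `cost_model`: coefficients, `theta`
#'   (dispersion), design metadata and the fitted `glm.nb` object.
#' @export
fit_cost_model <- function(cohort, sex, sector, step, weighted = FALSE) {
  stopifnot(sector %in% SECTORS, sex %in% c("male", "female"))
  dat <- cohort[cohort$sex == sex, , drop = FALSE]
  if (nrow(dat) == 0L) stop("no rows for sex '", sex, "'")
  cost_col <- paste0("cost_", sector)
  if (!cost_col %in% names(dat)) stop("missing cost column ", cost_col)
  if (any(dat[[cost_col]] < 0, na.rm = TRUE))
    stop("sector costs must be non-negative")
  if (any(dat$person_years <= 0, na.rm = TRUE))
    stop("person_years must be positive")
  dat$cost_outcome <- round(dat[[cost_col]])
  if (all(dat$cost_outcome == 0))
    stop("all-zero cost outcome for sector '", sector, "'")
  design <- build_design(dat, step)
  warnings_seen <- character(0)
  nb_fit <- function() {
    if (weighted) {
      design$data$.w <- dat$weight / mean(dat$weight)
      MASS::glm.nb(design$formula, data = design$data, weights = .w,
                   maxit = 100)
    } else {
      MASS::glm.nb(design$formula, data = design$data, maxit = 100)
    }
  }
  fit <- withCallingHandlers(
    tryCatch(nb_fit(), error = function(e) {
      # theta diverges when the data carry no overdispersion (e.g. exact
      # constant-rate outcomes); the NB log-likelihood then approaches its
      # Poisson limit, which is the fit we report
      message("dispersion estimate diverged (", conditionMessage(e),
              "); using the Poisson limit")
      f <- if (weighted) {
        design$data$.w <- dat$weight / mean(dat$weight)
        stats::glm(design$formula, data = design$data, weights = .w,
                   family = stats::poisson())
      } else {
        stats::glm(design$formula, data = design$data,
                   family = stats::poisson())
      }
      f$theta <- Inf
      f
    }),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (!isTRUE(fit$converged))
    stop("negative binomial fit did not converge (sex=", sex,
         ", sector=", sector, ", step=", step, ") after ", fit$iter,
         " iterations; warnings: ",
         paste(unique(warnings_seen), collapse = "; "), call. = FALSE)
  structure(list(
    sex = sex, sector = sector, step = step,
    coefficients = stats::coef(fit),
    se = sqrt(diag(stats::vcov(fit))),
    theta = fit$theta,
    variables = design$variables,
    dropped = design$dropped,
    xlevels = fit$xlevels,
    offset_convention = "log person-years",
    weighted = weighted,
    fit = fit
  ), class = "cost_model")
}

#' @export
print.cost_model <- function(x, ...) {
  cat("Negative binomial cost model (", x$sex, ", ", x$sector,
      ", ladder step ", x$step, ")\n", sep = "")
  cat("  dispersion theta:", format(x$theta, digits = 4), "\n")
  cat("  coefficients:", length(x$coefficients), "  covariates:",
      paste(x$variables, collapse = ", "), "\n")
  invisible(x)
}

#' Exponentiated coefficients (cost ratios)
#'
#' @param model A `cost_model`.
#' @return Named vector of cost ratios versus the reference levels.
#' @export
cost_ratios <- function(model) exp(model$coefficients)

#' Per-person expected annual cost under a fitted model
#'
#' Evaluates exp(linear predictor) per person-year: the offset
#' contribution is removed so predictions are annualized regardless of
#' each person's follow-up.  Unseen factor levels raise an error naming
#' the level.
#'
#' @param model A `cost_model`.
#' @param cohort Cohort data frame carrying the model covariates.
#' @return Numeric vector of expected annual costs.
#' @export
predict_expected_cost <- function(model, cohort) {
  for (v in model$variables) {
    if (!v %in% names(cohort)) stop("cohort is missing covariate ", v)
    bad <- setdiff(unique(as.character(cohort[[v]])), model$xlevels[[v]])
    bad <- bad[!is.na(bad)]
    if (length(bad))
      stop("unseen level(s) in '", v, "': ", paste(bad, collapse = ", "))
    cohort[[v]] <- factor(as.character(cohort[[v]]), levels = model$xlevels[[v]])
  }
  nd <- cohort
  nd$person_years <- 1  # offset 0 -> annualized prediction
  as.numeric(stats::predict(model$fit, newdata = nd, type = "response"))
}

#' Fit the full model suite
#'
#' Fits every (sex, sector, ladder step) combination: with all five steps
#' and three sectors this is 15 models per sex, 30 in total.
#'
#' @param cohort Cohort data frame with both sexes and all sector cost
#'   columns.
#' @param steps Ladder steps to fit (default all five).
#' @param sectors Sectors to fit (default all three).
#' @param weighted Logical, survey-weighted fits.
#' @return Object of class `model_suite`: a list keyed
#'   `sex.sector.step`.
#' @export
fit_model_suite <- function(cohort, steps = LADDER_STEPS, sectors = SECTORS,
                            weighted = FALSE) {
  for (sx in c("male", "female"))
    if (!any(cohort$sex == sx)) stop("cohort has no rows for sex '", sx, "'")
  suite <- list()
  for (sx in c("male", "female")) for (se in sectors) for (st in steps) {
    key <- paste(sx, se, st, sep = ".")
    suite[[key]] <- tryCatch(
      fit_cost_model(cohort, sx, se, st, weighted = weighted),
      error = function(e) stop("fit failed for (", key, "): ",
                               conditionMessage(e), call. = FALSE))
  }
  structure(suite, class = "model_suite")
}

#' @export
print.model_suite <- function(x, ...) {
  cat("Model suite:", length(x), "negative binomial cost models\n")
  for (sx in c("male", "female"))
    cat(" ", sx, ":", sum(startsWith(names(x), paste0(sx, "."))), "models\n")
  invisible(x)
}

#' Select one model from a suite
#'
#' @param suite A `model_suite`.
#' @param sex,sector,step Model key components.
#' @return The `cost_model`; errors if absent.
#' @export
suite_model <- function(suite, sex, sector, step) {
  key <- paste(sex, sector, step, sep = ".")
  m <- suite[[key]]
  if (is.null(m)) stop("model suite has no entry for ", key)
  m
}

#' Serialize a model suite to JSON
#'
#' Writes coefficients, dispersion, covariate lists and factor levels for
#' every model; enough to audit or re-apply the fits.
#'
#' @param suite A `model_suite`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_suite <- function(suite, path) {
  payload <- lapply(suite, function(m) list(
    sex = m$sex, sector = m$sector, step = m$step,
    coefficients = as.list(m$coefficients), se = as.list(m$se),
    theta = m$theta, variables = m$variables, dropped = m$dropped,
    xlevels = m$xlevels, offset = m$offset_convention, weighted = m$weighted))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
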