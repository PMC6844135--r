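# Schema-validated readers/writers and the end-to-end pipeline driver.
# Two cohort roles: "linked" cohorts carry per-sector costs and are used
# for model fitting; "unlinked" cycles carry no costs and are used for
# weighted PAF prediction.

.MANDATORY_COLUMNS <- list(
  linked   = c("person_id", "cycle_year", "sex", "age_group", "weight",
               "person_years", "cost_hospital", "cost_drugs", "cost_community"),
  unlinked = c("person_id", "cycle_year", "sex", "age_group", "weight")
)

#' Read a cohort CSV
#'
#' Reads and validates a person-level cohort table.  Mandatory columns
#' depend on the role: linked cohorts (used for fitting) must carry
#' person-years and per-sector costs; unlinked cycles (used for PAF
#' prediction) need only identification, weights and covariates.
#' Categorical columns present in the file are validated against the
#' package vocabularies ([exposure_levels()]); an unknown token is an
#' error naming the row and column.  Extra columns are carried through
#' untouched.
#'
#' @param path CSV path.
#' @param role `linked` or `unlinked`.
#' @return Validated cohort data frame.
#' @export
read_cohort <- function(path, role = c("linked", "unlinked")) {
  role <- match.arg(role)
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(cohort, role)
}

#' Validate a cohort data frame
#'
#' @param cohort Cohort data frame.
#' @param role `linked` or `unlinked`.
#' @return The cohort, invisibly returned after checks.
#' @export
validate_cohort <- function(cohort, role = c("linked", "unlinked")) {
  role <- match.arg(role)
  need <- .MANDATORY_COLUMNS[[role]]
  absent <- setdiff(need, names(cohort))
  if (length(absent))
    stop("cohort (role=", role, ") is missing mandatory column(s): ",
         paste(absent, collapse = ", "))
  if ("person_years" %in% names(cohort)) {
    bad <- which(!is.na(cohort$person_years) & cohort$person_years <= 0)
    if (length(bad))
      stop("non-positive person_years at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  for (col in grep("^cost_", names(cohort), value = TRUE)) {
    bad <- which(!is.na(cohort[[col]]) & cohort[[col]] < 0)
    if (length(bad))
      stop("negative ", col, " at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  vocab <- exposure_levels()
  for (v in intersect(names(vocab), names(cohort))) {
    x <- as.character(cohort[[v]])
    bad <- which(!is.na(x) & !x %in% vocab[[v]])
    if (length(bad))
      stop("unknown category '", x[bad[1L]], "' in column '", v,
           "' at row ", bad[1L])
  }
  if (!all(is.na(cohort$sex) | cohort$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  message("cohort (", role, "): ", nrow(cohort), " rows, ",
          ncol(cohort), " columns")
  cohort
}

#' Write a cohort CSV
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read an annual expenditure table CSV
#'
#' Expects columns `fiscal_year`, `sector`, `amount` (nominal dollars)
#' with all four sectors (hospital, drugs, community, other) present for
#' every year.
#'
#' @param path CSV path.
#' @return Validated expenditure data frame.
#' @export
read_expenditure_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fiscal_year", "sector", "amount")
  if (!all(need %in% names(x)))
    stop("expenditure table must have columns: ", paste(need, collapse = ", "))
  if (any(x$amount < 0)) stop("expenditures must be non-negative")
  sectors <- c(SECTORS, "other")
  for (y in unique(x$fiscal_year)) {
    miss <- setdiff(sectors, x$sector[x$fiscal_year == y])
    if (length(miss))
      stop("year ", y, " is missing sector(s): ", paste(miss, collapse = ", "))
  }
  x
}

#' Read a CPI series CSV
#'
#' Expects columns `year`, `cpi` with positive index values and the base
#' year 2014 at ratio 1.
#'
#' @param path CSV path.
#' @return Validated CPI data frame.
#' @export
read_cpi_series <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("year", "cpi") %in% names(x)))
    stop("CPI series must have columns year, cpi")
  if (any(x$cpi <= 0)) stop("CPI values must be positive")
  base <- x$cpi[x$year == 2014]
  if (length(base) != 1L || abs(base - 1) > 1e-8)
    stop("CPI series must have base year 2014 with index 1")
  x
}

#' Read and validate a run configuration (YAML or JSON)
#'
#' Recognized keys: `cohort_linked`, `cohort_unlinked`, `expenditures`,
#' `cpi` (paths), `steps`, `primary_step`, `risks`, `heavy_only_alcohol`,
#' `weighted_fit`, `seed`, `output_dir`, `sensitivity` (logical).
#' Unknown keys are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or a named list.
#' @return Validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path
  else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- c("cohort_linked", "cohort_unlinked", "expenditures", "cpi",
             "steps", "primary_step", "risks", "heavy_only_alcohol",
             "weighted_fit", "seed", "output_dir", "sensitivity")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(steps = LADDER_STEPS, primary_step = 3,
                   risks = c("smoking", "alcohol", "diet", "activity",
                             "behaviours", "ses"),
                   heavy_only_alcohol = FALSE, weighted_fit = FALSE,
                   seed = 1L, output_dir = ".", sensitivity = FALSE)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (!cfg$primary_step %in% cfg$steps)
    stop("primary_step must be among the fitted steps")
  structure(cfg, class = c("run_config", "list"))
}

#' Run the end-to-end attribution pipeline
#'
#' Scores raw responses, fits the model suite on the linked cohort,
#' computes per-cycle PAFs on the unlinked cycles with between-cycle
#' interpolation, converts them to attributable dollars against the
#' expenditure table (2014 dollars), computes avoided costs versus the
#' first-year baseline, optionally runs the ladder-bound sensitivity
#' analysis, and writes tidy CSV outputs plus a machine-readable run
#' manifest (seed, package version, config hash).  If the config names
#' no expenditure table, the burden stage is skipped with a notice and
#' PAFs are still produced.
#'
#' @param config A `run_config`, or a path accepted by
#'   [read_run_config()].
#' @param linked,unlinked Optional in-memory cohorts overriding the
#'   config paths.
#' @return List with `suite`, `pafs`, `burden` (or NULL), `avoided` (or
#'   NULL), `manifest`; outputs written under `config$output_dir`.
#' @export
run_pipeline <- function(config, linked = NULL, unlinked = NULL) {
  config <- read_run_config(config)
  set.seed(config$seed)
  if (is.null(linked)) linked <- read_cohort(config$cohort_linked, "linked")
  if (is.null(unlinked)) {
    unlinked <- if (!is.null(config$cohort_unlinked))
      read_cohort(config$cohort_unlinked, "unlinked") else linked
  }
  linked <- score_cohort(linked)
  unlinked <- score_cohort(unlinked)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  suite <- fit_model_suite(linked, steps = config$steps,
                           weighted = config$weighted_fit)
  pafs <- paf_series(suite, unlinked, risks = config$risks,
                     step = config$primary_step,
                     heavy_only = config$heavy_only_alcohol)
  write_paf_series(pafs, file.path(config$output_dir, "paf_series.csv"))
  write_model_suite(suite, file.path(config$output_dir, "model_suite.json"))
  burden <- NULL; avoided <- NULL
  if (!is.null(config$expenditures)) {
    expend <- read_expenditure_table(config$expenditures)
    cpi <- read_cpi_series(config$cpi)
    expend14 <- inflate_expenditures(expend, cpi)
    burden <- attribute_expenditure(pafs, expend14)
    utils::write.csv(burden, file.path(config$output_dir, "burden.csv"),
                     row.names = FALSE)
    budgets <- tapply(expend14$amount, expend14$fiscal_year, sum)
    avoided <- lapply(stats::setNames(nm = setdiff(config$risks, "ses")),
                      function(r) {
      ser <- pafs[pafs$risk == r, , drop = FALSE]
      # budget-share-weighted total PAF across sectors per year
      tot <- vapply(sort(unique(ser$year)), function(y) {
        ex <- expend14[expend14$fiscal_year == y, ]
        ps <- ser[ser$year == y, ]
        p <- ps$paf[match(ifelse(ex$sector == "other", "community", ex$sector),
                          ps$sector)]
        sum(p * ex$amount) / sum(ex$amount)
      }, numeric(1))
      names(tot) <- sort(unique(ser$year))
      avoided_costs(tot[[1L]], tot, budgets[names(tot)])
    })
    summ <- summarize_burden(burden, avoided)
    jsonlite::write_json(summ, file.path(config$output_dir, "burden_summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else {
    message("no expenditure table configured; burden stage skipped")
  }
  sensitivity <- NULL
  if (isTRUE(config$sensitivity) &&
      all(c(1, 5) %in% config$steps)) {
    sensitivity <- lapply(stats::setNames(nm = SECTORS), function(s)
      unclass(bound_estimates(suite, unlinked, attribution_rule("behaviours"), s)))
    jsonlite::write_json(sensitivity,
                         file.path(config$output_dir, "sensitivity_bounds.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(
    package = "costpaf",
    version = as.character(utils::packageVersion("costpaf")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    config = unclass(config),
    n_models = length(suite),
    timestamp_free = TRUE  # no wall-clock in the manifest: outputs are a pure
  )                        # function of (inputs, config, seed)
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(suite = suite, pafs = pafs, burden = burden, avoided = avoided,
       sensitivity = sensitivity, manifest = manifest)
}
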