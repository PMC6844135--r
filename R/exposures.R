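# Exposure scoring: raw survey responses -> analytic risk categories.
# Category vocabularies are fixed package-wide; "missing" is always an
# explicit level so that models never drop rows for item non-response.

#' Category vocabularies for behavioural and socioeconomic exposures
#'
#' Named list of the category labels used throughout the package, one
#' character vector per exposure variable.  The first element of each
#' behaviour vector is the highest-risk level and the reference (lowest
#' risk) level is the one used for counterfactual recoding; see
#' [behaviour_reference_levels()].
#'
#' @return Named list of character vectors.
#' @export
exposure_levels <- function() {
  list(
    smoking     = c("heavy", "light", "former_heavy", "former_light", "non", "missing"),
    alcohol     = c("heavy", "moderate", "non", "missing"),
    diet        = c("poor", "fair", "adequate", "missing"),
    activity    = c("inactive", "moderate", "active", "missing"),
    education   = c("lt_highschool", "highschool", "postsecondary", "missing"),
    income      = c("lt30k", "30to80k", "ge80k", "missing"),
    home_owned  = c("yes", "no", "missing"),
    deprivation = c("low", "moderate", "high", "missing")
  )
}

#' Counterfactual reference levels
#'
#' The lowest-risk (behaviours) and lowest-cost (socioeconomic) category
#' of each exposure, used as the "no exposure" assignment in
#' factor-deleted PAF computation.
#'
#' @return Named character vector, variable -> reference level.
#' @export
behaviour_reference_levels <- function() {
  c(smoking = "non", alcohol = "moderate", diet = "adequate", activity = "active")
}

#' @rdname behaviour_reference_levels
#' @export
ses_reference_levels <- function() {
  c(education = "postsecondary", income = "ge80k", home_owned = "yes",
    deprivation = "low")
}

#' Categorize smoking behaviour
#'
#' Combines smoking status, daily cigarette amount and lifetime
#' consumption into five categories.  Current daily smokers of 20 or more
#' cigarettes per day are heavy smokers; current daily smokers below 20,
#' and current occasional smokers with at least 100 lifetime cigarettes,
#' are light smokers.  Former daily smokers split at the same 20/day
#' threshold on their former daily amount; former occasional smokers with
#' >= 100 lifetime cigarettes are former light smokers.  Never smokers and
#' occasional smokers with fewer than 100 lifetime cigarettes are
#' non-smokers.
#'
#' @param smoking_status One of `current_daily`, `current_occasional`,
#'   `former_daily`, `former_occasional`, `never`, or `NA`.
#' @param cigs_per_day Cigarettes per day (current amount for current
#'   daily smokers, former amount for former daily smokers).
#' @param lifetime_cigs_ge_100 Logical, at least 100 cigarettes ever.
#' @return Character vector with levels
#'   `heavy`, `light`, `former_heavy`, `former_light`, `non`, `missing`.
#' @export
categorize_smoking <- function(smoking_status, cigs_per_day = NA_real_,
                               lifetime_cigs_ge_100 = NA) {
  n <- length(smoking_status)
  cigs_per_day <- rep_len(cigs_per_day, n)
  lifetime_cigs_ge_100 <- rep_len(lifetime_cigs_ge_100, n)
  if (any(!is.na(cigs_per_day) & cigs_per_day < 0))
    stop("cigs_per_day must be non-negative")
  out <- rep("missing", n)
  st <- as.character(smoking_status)
  daily <- !is.na(st) & st == "current_daily"
  out[daily & !is.na(cigs_per_day) & cigs_per_day >= 20] <- "heavy"
  out[daily & !is.na(cigs_per_day) & cigs_per_day < 20]  <- "light"
  occ <- !is.na(st) & st == "current_occasional"
  out[occ & !is.na(lifetime_cigs_ge_100) & lifetime_cigs_ge_100]  <- "light"
  out[occ & !is.na(lifetime_cigs_ge_100) & !lifetime_cigs_ge_100] <- "non"
  fdaily <- !is.na(st) & st == "former_daily"
  out[fdaily & !is.na(cigs_per_day) & cigs_per_day >= 20] <- "former_heavy"
  out[fdaily & !is.na(cigs_per_day) & cigs_per_day < 20]  <- "former_light"
  focc <- !is.na(st) & st == "former_occasional"
  out[focc & !is.na(lifetime_cigs_ge_100) & lifetime_cigs_ge_100]  <- "former_light"
  out[focc & !is.na(lifetime_cigs_ge_100) & !lifetime_cigs_ge_100] <- "non"
  out[!is.na(st) & st == "never"] <- "non"
  out
}

#' Categorize alcohol consumption
#'
#' Heavy drinking is bingeing (five or more drinks on a day in the
#' previous week, or weekly bingeing in the previous month) or more than
#' 21 (men) / 14 (women) drinks per week.  Drinking at or below the
#' sex-specific threshold with no bingeing is moderate; no alcohol in the
#' last 12 months is non-drinking.
#'
#' @param drinks_per_week Average drinks per week.
#' @param binge_any_day_prev_week Logical, >= 5 drinks on a day in the
#'   previous week.
#' @param weekly_binge_prev_month Logical, weekly bingeing in the
#'   previous month.
#' @param any_alcohol_12mo Logical, any alcohol in the last 12 months.
#' @param sex `male` or `female` (sets the weekly-drinks threshold).
#' @return Character vector with levels `heavy`, `moderate`, `non`,
#'   `missing`.
#' @export
categorize_alcohol <- function(drinks_per_week, binge_any_day_prev_week,
                               weekly_binge_prev_month, any_alcohol_12mo, sex) {
  n <- max(length(drinks_per_week), length(any_alcohol_12mo), length(sex))
  drinks_per_week <- rep_len(drinks_per_week, n)
  binge_any_day_prev_week <- rep_len(binge_any_day_prev_week, n)
  weekly_binge_prev_month <- rep_len(weekly_binge_prev_month, n)
  any_alcohol_12mo <- rep_len(any_alcohol_12mo, n)
  sex <- as.character(rep_len(sex, n))
  if (!all(is.na(sex) | sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  if (any(!is.na(drinks_per_week) & drinks_per_week < 0))
    stop("drinks_per_week must be non-negative")
  thr <- ifelse(sex == "male", 21, 14)
  # either binge indicator true counts as bingeing; NA in one indicator
  # does not mask a TRUE in the other
  binge <- (!is.na(binge_any_day_prev_week) & binge_any_day_prev_week) |
    (!is.na(weekly_binge_prev_month) & weekly_binge_prev_month)
  out <- rep("missing", n)
  non <- !is.na(any_alcohol_12mo) & !any_alcohol_12mo
  out[non] <- "non"
  heavy <- binge | (!is.na(drinks_per_week) & !is.na(thr) & drinks_per_week > thr)
  out[heavy & !non] <- "heavy"
  moderate <- !heavy & !non &
    !is.na(any_alcohol_12mo) & any_alcohol_12mo &
    !is.na(drinks_per_week) & !is.na(thr) & drinks_per_week <= thr &
    !is.na(binge_any_day_prev_week) & !is.na(weekly_binge_prev_month)
  out[moderate] <- "moderate"
  out
}

#' Leisure-time activity volume in MET-hours per day
#'
#' Sums, over reported activities, sessions-per-week / 7 times hours per
#' session times the activity's MET value (the low-intensity MET of each
#' activity, following the convention that respondents overestimate
#' intensity).
#'
#' @param activities Data frame with columns `sessions_per_week`,
#'   `hours_per_session`, `met_value` (one row per activity); an empty
#'   data frame gives 0.
#' @return Scalar MET-hours per day.
#' @export
compute_met_hours <- function(activities) {
  if (is.null(activities) || nrow(activities) == 0L) return(0)
  stopifnot(all(c("sessions_per_week", "hours_per_session", "met_value")
                %in% names(activities)))
  with(activities, {
    if (any(sessions_per_week < 0, na.rm = TRUE) ||
        any(hours_per_session < 0, na.rm = TRUE))
      stop("activity frequency and duration must be non-negative")
    if (any(met_value <= 0, na.rm = TRUE)) stop("met_value must be positive")
    sum(sessions_per_week / 7 * hours_per_session * met_value)
  })
}

#' Categorize physical activity
#'
#' Inactive below 1.5 MET-hours/day, moderately active in [1.5, 3),
#' active at or above 3.
#'
#' @param met_hours_per_day Numeric vector, MET-hours per day.
#' @return Character vector with levels `inactive`, `moderate`, `active`,
#'   `missing`.
#' @export
categorize_activity <- function(met_hours_per_day) {
  if (any(met_hours_per_day < 0, na.rm = TRUE))
    stop("met_hours_per_day must be non-negative")
  out <- rep("missing", length(met_hours_per_day))
  ok <- !is.na(met_hours_per_day)
  out[ok & met_hours_per_day < 1.5] <- "inactive"
  out[ok & met_hours_per_day >= 1.5 & met_hours_per_day < 3] <- "moderate"
  out[ok & met_hours_per_day >= 3] <- "active"
  out
}

#' Fruit-and-vegetable diet index
#'
#' Individuals start with 2 points and earn one additional point per
#' average daily serving of fruit and vegetables, to a maximum of 8
#' additional points (maximum score 10).  Two points are deducted for
#' each of: daily fruit-juice servings exceeding one, no carrot
#' consumption, and daily potato servings exceeding 1 (males) or 0.7
#' (females).  Negative totals are recoded to zero.
#'
#' @param fv_servings Average daily fruit + vegetable servings.
#' @param juice_servings Daily fruit-juice servings.
#' @param carrot_consumed Logical, carrots consumed.
#' @param potato_servings Daily potato servings.
#' @param sex `male` or `female` (sets the potato threshold).
#' @return Numeric vector of index points in [0, 10]; `NA` when
#'   `fv_servings` is missing.
#' @export
diet_score <- function(fv_servings, juice_servings, carrot_consumed,
                       potato_servings, sex) {
  n <- max(length(fv_servings), length(sex))
  fv_servings <- rep_len(fv_servings, n)
  juice_servings <- rep_len(juice_servings, n)
  carrot_consumed <- rep_len(carrot_consumed, n)
  potato_servings <- rep_len(potato_servings, n)
  sex <- as.character(rep_len(sex, n))
  if (any(c(fv_servings, juice_servings, potato_servings) < 0, na.rm = TRUE))
    stop("servings must be non-negative")
  potato_thr <- ifelse(sex == "male", 1, 0.7)
  score <- 2 + pmin(8, fv_servings) -
    2 * (!is.na(juice_servings) & juice_servings > 1) -
    2 * (!is.na(carrot_consumed) & !carrot_consumed) -
    2 * (!is.na(potato_servings) & potato_servings > potato_thr)
  score <- pmax(0, pmin(10, score))
  score[is.na(fv_servings)] <- NA_real_
  score
}

#' Categorize the diet index
#'
#' Poor below 2.5 points, fair in [2.5, 5), adequate in [5, 10].
#'
#' @param score Diet index points in [0, 10].
#' @return Character vector with levels `poor`, `fair`, `adequate`,
#'   `missing`.
#' @export
categorize_diet <- function(score) {
  if (any(score < 0 | score > 10, na.rm = TRUE))
    stop("diet score must lie in [0, 10]")
  out <- rep("missing", length(score))
  ok <- !is.na(score)
  out[ok & score < 2.5] <- "poor"
  out[ok & score >= 2.5 & score < 5] <- "fair"
  out[ok & score >= 5] <- "adequate"
  out
}

#' Categorize neighbourhood deprivation
#'
#' The material and social deprivation quintiles of a dissemination area
#' are cross-tabulated into 25 cells: both quintiles in {1, 2} is low
#' deprivation (4 cells), both in {4, 5} is high (4 cells), anything else
#' moderate (17 cells).
#'
#' @param material_q Material deprivation quintile, 1 (least deprived) to 5.
#' @param social_q Social deprivation quintile, 1 to 5.
#' @return Character vector with levels `low`, `moderate`, `high`,
#'   `missing`.
#' @export
categorize_deprivation <- function(material_q, social_q) {
  n <- max(length(material_q), length(social_q))
  material_q <- rep_len(material_q, n)
  social_q <- rep_len(social_q, n)
  bad <- function(q) !is.na(q) & (q < 1 | q > 5 | q != round(q))
  if (any(bad(material_q)) || any(bad(social_q)))
    stop("deprivation quintiles must be integers in 1..5")
  out <- rep("missing", n)
  ok <- !is.na(material_q) & !is.na(social_q)
  out[ok & material_q <= 2 & social_q <= 2] <- "low"
  out[ok & material_q >= 4 & social_q >= 4] <- "high"
  out[ok & out == "missing"] <- "moderate"
  out
}

#' Score a cohort's raw responses into exposure categories
#'
#' Appends (or overwrites) the categorized exposure columns `smoking`,
#' `alcohol`, `diet_score_value`, `diet`, `met_hours_per_day`, `activity`
#' and `deprivation` computed from the raw response columns of a cohort
#' table.  Raw columns it looks for: `smoking_status`, `cigs_per_day`,
#' `lifetime_cigs_ge_100`; `drinks_per_week`, `binge_any_day_prev_week`,
#' `weekly_binge_prev_month`, `any_alcohol_12mo`; `fv_servings`,
#' `juice_servings`, `carrot_consumed`, `potato_servings`;
#' `act_sessions_per_week`, `act_hours_per_session`, `act_met_value`
#' (single dominant activity per respondent); `material_q`, `social_q`.
#' Raw column groups that are absent are skipped, so a cohort that
#' already carries categorized columns passes through unchanged.
#'
#' @param cohort Cohort data frame (see [read_cohort()]).
#' @return The cohort with categorized columns appended.
#' @export
score_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  if (all(c("smoking_status") %in% names(cohort))) {
    cohort$smoking <- categorize_smoking(
      cohort$smoking_status, cohort$cigs_per_day, cohort$lifetime_cigs_ge_100)
  }
  if (all(c("drinks_per_week", "any_alcohol_12mo") %in% names(cohort))) {
    cohort$alcohol <- categorize_alcohol(
      cohort$drinks_per_week, cohort$binge_any_day_prev_week,
      cohort$weekly_binge_prev_month, cohort$any_alcohol_12mo, cohort$sex)
  }
  if (all(c("fv_servings") %in% names(cohort))) {
    cohort$diet_score_value <- diet_score(
      cohort$fv_servings, cohort$juice_servings, cohort$carrot_consumed,
      cohort$potato_servings, cohort$sex)
    cohort$diet <- categorize_diet(cohort$diet_score_value)
  }
  if (all(c("act_sessions_per_week", "act_hours_per_session", "act_met_value")
          %in% names(cohort))) {
    cohort$met_hours_per_day <-
      ifelse(is.na(cohort$act_sessions_per_week), NA_real_,
             cohort$act_sessions_per_week / 7 *
               cohort$act_hours_per_session * cohort$act_met_value)
    cohort$activity <- categorize_activity(cohort$met_hours_per_day)
  }
  if (all(c("material_q", "social_q") %in% names(cohort))) {
    cohort$deprivation <- categorize_deprivation(cohort$material_q, cohort$social_q)
  }
  cohort
}
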