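# Synthetic multi-cycle survey cohort generator with known generating
# parameters, plus exact ground-truth PAF computation by enumeration of
# the discrete covariate distribution.

AGE_GROUPS <- c("25-29", "30-34", "35-39", "40-44", "45-49", "50-54",
                "55-59", "60-64", "65-69", "70-74", "75-79", "80-84",
                "85-89", "90+")

# behaviour level "riskiness" used by the confounding tilt
.RISK_TILT <- list(
  smoking  = c(heavy = 1, light = 0.5, former_heavy = 0.5, former_light = 0.25, non = 0),
  alcohol  = c(heavy = 1, moderate = 0, non = 0.3),
  diet     = c(poor = 1, fair = 0.5, adequate = 0),
  activity = c(inactive = 1, moderate = 0.5, active = 0)
)

.EDU_SCORE <- c(lt_highschool = 1, highschool = 0.5, postsecondary = 0)

#' Default synthetic-cohort generator configuration
#'
#' Describes a multi-cycle cross-sectional survey resembling a provincial
#' health survey sampled biennially from 2003 to 2013: 14 five-year age
#' groups from 25-29 to 90+, four health behaviours with an explicit
#' missing level, socioeconomic indicators (education, household income,
#' home ownership, area deprivation from crossed material/social
#' quintiles), additional sociodemographic and health-status covariates
#' used by the outer steps of the model ladder, survey weights, 1-4 year
#' follow-up, and per-sector annualized costs drawn from a log-link
#' negative binomial model with known coefficients.  Heavy-smoking
#' prevalence declines across cycles by default, mirroring the secular
#' decline in current smoking.
#'
#' @param n_per_cycle Respondents per survey cycle.
#' @param cycle_years Cycle anchor years (first fiscal year of each field
#'   period).
#' @param confounding Non-negative scalar; log-odds tilt making risky
#'   behaviour levels more likely at lower education. 0 = behaviours
#'   independent of socioeconomic position.
#' @param missing_rate Per-behaviour item non-response rate.
#' @param smoking_drift Logical; if `TRUE` heavy/light smoking prevalence
#'   declines linearly across cycles.
#' @param oversample Optional list `list(variable =, factor =)` giving
#'   sampling-rate multipliers by category level; design weights absorb
#'   the tilt so weighted estimates still target the population.
#' @param weighted_fit Logical; fit models with survey weights
#'   (pseudo-likelihood) rather than unweighted.
#' @return A list of class `costpaf_config`.
#' @export
default_generator_config <- function(n_per_cycle = 2000,
                                     cycle_years = c(2003, 2005, 2007, 2009, 2011, 2013),
                                     confounding = 0,
                                     missing_rate = 0.01,
                                     smoking_drift = TRUE,
                                     oversample = NULL,
                                     weighted_fit = FALSE) {
  n_cyc <- length(cycle_years)
  smoking_base <- c(heavy = 0.08, light = 0.15, former_heavy = 0.15,
                    former_light = 0.17, non = 0.45)
  smoking_by_cycle <- matrix(rep(smoking_base, each = n_cyc), nrow = n_cyc,
                             dimnames = list(as.character(cycle_years),
                                             names(smoking_base)))
  if (smoking_drift && n_cyc > 1) {
    f <- seq(0, 1, length.out = n_cyc)
    smoking_by_cycle[, "heavy"] <- 0.11 - 0.05 * f
    smoking_by_cycle[, "light"] <- 0.16 - 0.03 * f
    smoking_by_cycle[, "non"] <- 1 - rowSums(smoking_by_cycle[, c("heavy", "light",
                                                                  "former_heavy",
                                                                  "former_light"),
                                                              drop = FALSE])
  }
  config <- list(
    n_per_cycle = n_per_cycle,
    cycle_years = cycle_years,
    p_male = 0.456,
    age_groups = AGE_GROUPS,
    age_probs = c(7.35, 8.75, 9.7, 9.95, 8.55, 9.5, 10.15, 9.0, 7.95, 7.15,
                  5.9, 3.95, 1.65, 0.45) / 100,
    behaviours = list(
      smoking  = list(levels = names(smoking_base), probs_by_cycle = smoking_by_cycle),
      alcohol  = list(levels = c("heavy", "moderate", "non"),
                      probs = c(0.08, 0.71, 0.21)),
      diet     = list(levels = c("poor", "fair", "adequate"),
                      probs = c(0.12, 0.36, 0.52)),
      activity = list(levels = c("inactive", "moderate", "active"),
                      probs = c(0.50, 0.25, 0.25))
    ),
    ses = list(
      education = c(lt_highschool = 0.20, highschool = 0.24, postsecondary = 0.56),
      income    = c(lt30k = 0.21, `30to80k` = 0.44, ge80k = 0.35),
      home_owned = c(yes = 0.78, no = 0.22)
    ),
    extra_covariates = list(
      immigrant = c(yes = 0.22, no = 0.78),
      marital = c(married = 0.63, other = 0.37),
      urban = c(yes = 0.78, no = 0.22),
      ethnicity = c(white = 0.89, nonwhite = 0.11),
      stress = c(high = 0.21, low = 0.79),
      flu_shot = c(yes = 0.65, no = 0.35),
      bmi = c(normal = 0.42, underweight = 0.02, overweight = 0.34, obese = 0.22),
      hypertension = c(no = 0.76, yes = 0.24),
      diabetes = c(no = 0.92, yes = 0.08),
      heart_disease = c(no = 0.91, yes = 0.09),
      cancer = c(no = 0.97, yes = 0.03),
      stroke = c(no = 0.98, yes = 0.02),
      dementia = c(no = 0.995, yes = 0.005),
      fragility = c(none = 0.69, limited = 0.21, help_basic = 0.10)
    ),
    confounding = confounding,
    missing_rate = missing_rate,
    oversample = oversample,
    weighted_fit = weighted_fit,
    # log cost ratios of the generating model, by sector; unlisted levels
    # (including "missing") carry coefficient 0
    effects = list(
      hospital = list(
        intercept = log(1200), theta = 0.6, age = 0.055, sex_male = 0.05,
        smoking  = c(heavy = 0.40, light = 0.20, former_heavy = 0.25, former_light = 0.10),
        alcohol  = c(heavy = 0.15, non = 0.05),
        diet     = c(poor = 0.20, fair = 0.08),
        activity = c(inactive = 0.30, moderate = 0.10),
        education = c(lt_highschool = 0.15, highschool = 0.07),
        income   = c(lt30k = 0.15, `30to80k` = 0.06),
        home_owned = c(no = 0.05),
        deprivation = c(high = 0.10, moderate = 0.04)
      ),
      drugs = list(
        intercept = log(400), theta = 0.8, age = 0.08, sex_male = -0.05,
        smoking  = c(heavy = 0.30, light = 0.15, former_heavy = 0.20, former_light = 0.08),
        alcohol  = c(heavy = 0.05, non = 0.05),
        diet     = c(poor = 0.15, fair = 0.06),
        activity = c(inactive = 0.20, moderate = 0.08),
        education = c(lt_highschool = 0.12, highschool = 0.05),
        income   = c(lt30k = 0.12, `30to80k` = 0.05),
        home_owned = c(no = 0.04),
        deprivation = c(high = 0.08, moderate = 0.03)
      ),
      community = list(
        intercept = log(800), theta = 1.2, age = 0.04, sex_male = -0.10,
        smoking  = c(heavy = 0.25, light = 0.12, former_heavy = 0.15, former_light = 0.06),
        alcohol  = c(heavy = 0.10, non = 0.04),
        diet     = c(poor = 0.12, fair = 0.05),
        activity = c(inactive = 0.20, moderate = 0.07),
        education = c(lt_highschool = 0.10, highschool = 0.05),
        income   = c(lt30k = 0.10, `30to80k` = 0.04),
        home_owned = c(no = 0.04),
        deprivation = c(high = 0.07, moderate = 0.03)
      )
    ),
    followup_probs = c(`1` = 0.04, `2` = 0.05, `3` = 0.08, `4` = 0.83),
    weight_meanlog = log(100), weight_sdlog = 0.5,
    population_size = 1e6,
    other_share = 0.2,
    cpi_growth = 0.018,
    cpi_base_year = 2014
  )
  class(config) <- c("costpaf_config", "list")
  validate_generator_config(config)
  config
}

#' Validate a generator configuration
#'
#' @param config A `costpaf_config` list.
#' @return The config, invisibly; stops on invalid prevalences or
#'   dispersion.
#' @export
validate_generator_config <- function(config) {
  stopifnot(length(config$age_probs) == length(config$age_groups))
  chk <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("invalid prevalence vector for ", what,
           " (must be non-negative and sum to 1)")
  }
  chk(config$age_probs, "age groups")
  for (b in names(config$behaviours)) {
    spec <- config$behaviours[[b]]
    if (!is.null(spec$probs_by_cycle)) {
      apply(spec$probs_by_cycle, 1, chk, what = b)
    } else chk(spec$probs, b)
  }
  for (v in names(config$ses)) chk(config$ses[[v]], v)
  for (s in names(config$effects)) {
    if (config$effects[[s]]$theta <= 0)
      stop("negative binomial dispersion must be positive for sector ", s)
  }
  if (!all(names(config$followup_probs) %in% as.character(1:4)))
    stop("follow-up must be between 1 and 4 years")
  chk(config$followup_probs, "follow-up")
  invisible(config)
}

# behaviour level probabilities for one cycle, one education level
.behaviour_probs <- function(config, behaviour, cycle_year, education) {
  spec <- config$behaviours[[behaviour]]
  p <- if (!is.null(spec$probs_by_cycle)) {
    spec$probs_by_cycle[as.character(cycle_year), ]
  } else stats::setNames(spec$probs, spec$levels)
  conf <- config$confounding
  if (conf != 0) {
    tilt <- .RISK_TILT[[behaviour]][names(p)]
    es <- .EDU_SCORE[[education]] - sum(.EDU_SCORE * config$ses$education)
    p <- p * exp(conf * es * tilt)
    p <- p / sum(p)
  }
  m <- config$missing_rate
  c(p * (1 - m), missing = m)
}

# linear predictor of the generating model on category columns
.generator_eta <- function(df, eff) {
  eta <- rep(eff$intercept, nrow(df)) + eff$age * (df$age_idx - 1) +
    ifelse(df$sex == "male", eff$sex_male, 0)
  for (v in c("smoking", "alcohol", "diet", "activity",
              "education", "income", "home_owned", "deprivation")) {
    co <- eff[[v]]
    if (is.null(co) || !v %in% names(df)) next
    idx <- match(as.character(df[[v]]), names(co))
    eta <- eta + ifelse(is.na(idx), 0, co[idx])
  }
  eta
}

.sample_level <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# raw survey responses consistent with the sampled category (round-trip
# property: scoring the raw fields reproduces the category)
.raw_from_smoking <- function(cat) {
  n <- length(cat)
  status <- rep(NA_character_, n); cigs <- rep(NA_real_, n)
  life <- rep(NA, n)
  status[cat == "heavy"] <- "current_daily"
  cigs[cat == "heavy"] <- sample(20:40, sum(cat == "heavy"), replace = TRUE)
  status[cat == "light"] <- "current_daily"
  cigs[cat == "light"] <- sample(1:19, sum(cat == "light"), replace = TRUE)
  status[cat == "former_heavy"] <- "former_daily"
  cigs[cat == "former_heavy"] <- sample(20:40, sum(cat == "former_heavy"), replace = TRUE)
  status[cat == "former_light"] <- "former_daily"
  cigs[cat == "former_light"] <- sample(1:19, sum(cat == "former_light"), replace = TRUE)
  status[cat == "non"] <- "never"
  life <- cat %in% c("heavy", "light", "former_heavy", "former_light")
  life[cat == "missing"] <- NA
  data.frame(smoking_status = status, cigs_per_day = cigs,
             lifetime_cigs_ge_100 = life)
}

.raw_from_alcohol <- function(cat, sex) {
  n <- length(cat)
  thr <- ifelse(sex == "male", 21, 14)
  drinks <- rep(NA_real_, n); binge <- rep(NA, n); wbinge <- rep(NA, n)
  any12 <- rep(NA, n)
  hv <- cat == "heavy"
  via_binge <- hv & stats::runif(n) < 0.5
  drinks[hv] <- ifelse(via_binge[hv],
                       round(stats::runif(sum(hv)) * thr[hv]),
                       thr[hv] + sample(1:15, sum(hv), replace = TRUE))
  binge[hv] <- via_binge[hv]; wbinge[hv] <- FALSE; any12[hv] <- TRUE
  md <- cat == "moderate"
  drinks[md] <- round(stats::runif(sum(md)) * (thr[md] - 1))
  binge[md] <- FALSE; wbinge[md] <- FALSE; any12[md] <- TRUE
  nn <- cat == "non"
  drinks[nn] <- 0; binge[nn] <- FALSE; wbinge[nn] <- FALSE; any12[nn] <- FALSE
  data.frame(drinks_per_week = drinks, binge_any_day_prev_week = binge,
             weekly_binge_prev_month = wbinge, any_alcohol_12mo = any12)
}

.raw_from_diet <- function(cat) {
  n <- length(cat)
  fv <- rep(NA_real_, n); juice <- rep(NA_real_, n)
  carrot <- rep(NA, n); potato <- rep(NA_real_, n)
  ad <- cat == "adequate"
  fv[ad] <- stats::runif(sum(ad), 3, 8); juice[ad] <- 0.5
  carrot[ad] <- TRUE; potato[ad] <- 0.2
  fa <- cat == "fair"
  fv[fa] <- stats::runif(sum(fa), 0.5, 2.99); juice[fa] <- 0.5
  carrot[fa] <- TRUE; potato[fa] <- 0.2
  po <- cat == "poor"
  fv[po] <- stats::runif(sum(po), 0, 2); juice[po] <- 2
  carrot[po] <- FALSE; potato[po] <- 2
  data.frame(fv_servings = fv, juice_servings = juice,
             carrot_consumed = carrot, potato_servings = potato)
}

.raw_from_activity <- function(cat) {
  n <- length(cat)
  target <- rep(NA_real_, n)
  target[cat == "inactive"] <- stats::runif(sum(cat == "inactive"), 0, 1.49)
  target[cat == "moderate"] <- stats::runif(sum(cat == "moderate"), 1.5, 2.99)
  target[cat == "active"]   <- stats::runif(sum(cat == "active"), 3, 8)
  data.frame(act_sessions_per_week = ifelse(is.na(target), NA_real_, 7),
             act_hours_per_session = target / 3,
             act_met_value = ifelse(is.na(target), NA_real_, 3))
}

#' Generate a synthetic multi-cycle survey cohort
#'
#' Draws, per cycle: sex, age group, socioeconomic indicators, area
#' deprivation quintiles, health behaviours conditional on education (per
#' the confounding setting), raw survey responses consistent with the
#' sampled categories, additional ladder covariates, survey weights,
#' follow-up years, and per-sector total costs over follow-up from the
#' configured negative binomial model (whole dollars).
#'
#' @param config A `costpaf_config` (see [default_generator_config()]).
#' @param seed Integer seed; output is reproducible given the seed.
#' @return A cohort data frame with raw, categorized, weight, follow-up
#'   and cost columns; the config is attached as attribute `config`.
#' @export
generate_cohort <- function(config = default_generator_config(), seed = 1) {
  validate_generator_config(config)
  set.seed(seed)
  cycles <- lapply(config$cycle_years, function(cy) {
    n <- config$n_per_cycle
    sex <- ifelse(stats::runif(n) < config$p_male, "male", "female")
    age_idx <- sample(seq_along(config$age_groups), n, replace = TRUE,
                      prob = config$age_probs)
    education <- .sample_level(n, config$ses$education)
    income <- .sample_level(n, config$ses$income)
    home_owned <- .sample_level(n, config$ses$home_owned)
    material_q <- sample(1:5, n, replace = TRUE)
    social_q <- sample(1:5, n, replace = TRUE)
    beh <- list()
    for (b in names(config$behaviours)) {
      cat <- character(n)
      for (ed in names(config$ses$education)) {
        sel <- education == ed
        if (!any(sel)) next
        p <- .behaviour_probs(config, b, cy, ed)
        cat[sel] <- .sample_level(sum(sel), p)
      }
      beh[[b]] <- cat
    }
    weight <- stats::rlnorm(n, config$weight_meanlog, config$weight_sdlog)
    if (!is.null(config$oversample)) {
      os <- config$oversample
      lev <- beh[[os$variable]]
      fac <- os$factor[lev]
      fac[is.na(fac)] <- 1
      keep <- stats::runif(n) < fac / max(os$factor)
      # rejection sampling tilts the sample; weights absorb the inverse tilt
      weight <- weight / fac
      idx <- which(keep)
      sex <- sex[idx]; age_idx <- age_idx[idx]; education <- education[idx]
      income <- income[idx]; home_owned <- home_owned[idx]
      material_q <- material_q[idx]; social_q <- social_q[idx]
      beh <- lapply(beh, `[`, idx); weight <- weight[idx]
      n <- length(idx)
    }
    df <- data.frame(
      cycle_year = cy, sex = sex, age_idx = age_idx,
      age_group = config$age_groups[age_idx],
      weight = weight,
      person_years = as.integer(.sample_level(n, config$followup_probs)),
      education = education, income = income, home_owned = home_owned,
      material_q = material_q, social_q = social_q,
      smoking = beh$smoking, alcohol = beh$alcohol,
      diet = beh$diet, activity = beh$activity
    )
    df$deprivation <- categorize_deprivation(material_q, social_q)
    for (v in names(config$extra_covariates))
      df[[v]] <- .sample_level(n, config$extra_covariates[[v]])
    df <- cbind(df, .raw_from_smoking(df$smoking),
                .raw_from_alcohol(df$alcohol, df$sex),
                .raw_from_diet(df$diet), .raw_from_activity(df$activity))
    for (s in names(config$effects)) {
      eff <- config$effects[[s]]
      mu <- df$person_years * exp(.generator_eta(df, eff))
      df[[paste0("cost_", s)]] <- stats::rnbinom(n, size = eff$theta, mu = mu)
    }
    df
  })
  out <- do.call(rbind, cycles)
  out$person_id <- seq_len(nrow(out))
  out <- out[, c("person_id", setdiff(names(out), "person_id"))]
  attr(out, "config") <- config
  out
}

# enumerate the discrete covariate distribution for one cycle:
# data frame of cells + probability column
.enumerate_cells <- function(config, cycle_year) {
  m <- config$missing_rate
  beh_levels <- lapply(config$behaviours, function(s) c(s$levels, "missing"))
  grid <- expand.grid(
    sex = c("male", "female"),
    age_idx = seq_along(config$age_groups),
    education = names(config$ses$education),
    income = names(config$ses$income),
    home_owned = names(config$ses$home_owned),
    deprivation = c("low", "moderate", "high"),
    smoking = beh_levels$smoking, alcohol = beh_levels$alcohol,
    diet = beh_levels$diet, activity = beh_levels$activity,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  p_sex <- c(male = config$p_male, female = 1 - config$p_male)
  p_depr <- c(low = 0.16, moderate = 0.68, high = 0.16)  # crossed uniform quintiles
  prob <- p_sex[grid$sex] * config$age_probs[grid$age_idx] *
    config$ses$education[grid$education] * config$ses$income[grid$income] *
    config$ses$home_owned[grid$home_owned] * p_depr[grid$deprivation]
  for (b in names(config$behaviours)) {
    pb <- vapply(names(config$ses$education), function(ed)
      .behaviour_probs(config, b, cycle_year, ed), numeric(length(beh_levels[[b]])))
    rownames(pb) <- beh_levels[[b]]
    prob <- prob * pb[cbind(grid[[b]], grid$education)]
  }
  grid$prob <- unname(prob)
  grid
}

#' Ground-truth PAFs of the generating model
#'
#' Computes, by exact enumeration over the discrete covariate
#' distribution (no sampling error), the population attributable fraction
#' of the generating negative binomial model for each single behaviour,
#' the combined behaviours, and the socioeconomic equity gap, per sector
#' and cycle year.
#'
#' @param config A `costpaf_config`.
#' @param risks Character vector of risk names; any of `smoking`,
#'   `alcohol`, `diet`, `activity`, `behaviours` (combined), `ses`.
#' @param sectors Sector names (default all configured).
#' @param cycle_years Cycle years (default all configured).
#' @return Data frame (risk, sector, cycle_year, paf) plus the true cost
#'   ratios as attribute `effects`.
#' @export
true_paf <- function(config = default_generator_config(),
                     risks = c("smoking", "alcohol", "diet", "activity",
                               "behaviours", "ses"),
                     sectors = names(config$effects),
                     cycle_years = config$cycle_years) {
  validate_generator_config(config)
  rules <- lapply(risks, attribution_rule)
  names(rules) <- risks
  out <- list()
  for (cy in cycle_years) {
    cells <- .enumerate_cells(config, cy)
    for (s in sectors) {
      eff <- config$effects[[s]]
      mu <- exp(.generator_eta(cells, eff))
      base <- sum(cells$prob * mu)
      for (r in risks) {
        cf <- counterfactual_recode(cells, rules[[r]])
        mu0 <- exp(.generator_eta(cf, eff))
        out[[length(out) + 1L]] <- data.frame(
          risk = r, sector = s, cycle_year = cy,
          paf = (base - sum(cells$prob * mu0)) / base)
      }
    }
  }
  res <- do.call(rbind, out)
  attr(res, "effects") <- config$effects
  res
}

#' Monte Carlo cross-check of the ground-truth PAF
#'
#' Estimates the generating-model PAF for one (risk, sector, cycle) by
#' simulating draws from the covariate distribution, with a standard
#' error, as an internal cross-check of the exact enumeration.
#'
#' @inheritParams true_paf
#' @param risk Single risk name.
#' @param sector Single sector name.
#' @param cycle_year Single cycle year.
#' @param n_draws Number of Monte Carlo draws.
#' @param seed Seed for the draws.
#' @return List with `paf` and `se`.
#' @export
true_paf_mc <- function(config, risk, sector, cycle_year, n_draws = 1e5,
                        seed = 1) {
  set.seed(seed)
  cells <- .enumerate_cells(config, cycle_year)
  idx <- sample.int(nrow(cells), n_draws, replace = TRUE, prob = cells$prob)
  draw <- cells[idx, ]
  eff <- config$effects[[sector]]
  mu <- exp(.generator_eta(draw, eff))
  mu0 <- exp(.generator_eta(counterfactual_recode(draw, attribution_rule(risk)), eff))
  d <- mu - mu0
  paf <- sum(d) / sum(mu)
  # delta-method SE of a ratio of means
  v <- stats::var(d - paf * mu) / n_draws
  list(paf = paf, se = sqrt(v) / mean(mu))
}

#' Generate annual expenditure and CPI tables matching a cohort config
#'
#' Builds an annual sector expenditure table (nominal dollars) whose
#' hospital/drugs/community budgets equal the generating model's expected
#' per-person annual cost (enumerated exactly, interpolated between
#' cycles) scaled to the configured population size and deflated to each
#' fiscal year's price level, plus an `other` sector holding a fixed
#' share of the total, and the matching CPI series with base year 2014.
#'
#' @param config A `costpaf_config`.
#' @return List with `expenditures` (fiscal_year, sector, amount) and
#'   `cpi` (year, cpi).
#' @export
generate_expenditure_tables <- function(config = default_generator_config()) {
  validate_generator_config(config)
  years <- seq(min(config$cycle_years), max(config$cycle_years))
  cpi <- cpi_series(c(years, config$cpi_base_year), growth = config$cpi_growth,
                    base_year = config$cpi_base_year)
  # expected annual per-person cost per sector at each cycle, then linear
  # interpolation across calendar years
  percap <- vapply(names(config$effects), function(s) {
    vapply(config$cycle_years, function(cy) {
      cells <- .enumerate_cells(config, cy)
      sum(cells$prob * exp(.generator_eta(cells, config$effects[[s]])))
    }, numeric(1))
  }, numeric(length(config$cycle_years)))
  percap <- matrix(percap, nrow = length(config$cycle_years),
                   dimnames = list(NULL, names(config$effects)))
  rows <- list()
  for (s in names(config$effects)) {
    annual <- if (length(config$cycle_years) == 1L) {
      rep(percap[1L, s], length(years))
    } else stats::approx(config$cycle_years, percap[, s], xout = years)$y
    real2014 <- annual * config$population_size
    nominal <- real2014 * cpi$cpi[match(years, cpi$year)]
    rows[[s]] <- data.frame(fiscal_year = years, sector = s, amount = nominal)
  }
  core <- do.call(rbind, rows)
  tot_core <- tapply(core$amount, core$fiscal_year, sum)
  other <- data.frame(fiscal_year = years, sector = "other",
                      amount = as.numeric(tot_core[as.character(years)]) *
                        config$other_share / (1 - config$other_share))
  exp_table <- rbind(core, other)
  rownames(exp_table) <- NULL
  list(expenditures = exp_table, cpi = cpi)
}
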