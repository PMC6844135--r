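# Shared fixtures and independent oracles, all built in code.

# Independent scalar brute-force oracle for the diet index, written
# straight from the scoring description (start at 2, +1/serving up to 8,
# -2 deductions, floor at 0, cap at 10); deliberately not vectorized and
# structurally unlike diet_score().
oracle_diet_score <- function(fv, juice, carrot, potato, sex) {
  pts <- 2
  extra <- fv
  if (extra > 8) extra <- 8
  pts <- pts + extra
  if (juice > 1) pts <- pts - 2
  if (!carrot) pts <- pts - 2
  thr <- if (sex == "male") 1 else 0.7
  if (potato > thr) pts <- pts - 2
  if (pts < 0) pts <- 0
  if (pts > 10) pts <- 10
  pts
}

# Per-person loop oracle for the factor-deleted PAF: predict each person,
# recode one person at a time, accumulate both totals.
oracle_paf <- function(models, cohort, rule, weights) {
  if (inherits(models, "cost_model")) models <- list(models)
  num <- 0; den <- 0
  for (i in seq_len(nrow(cohort))) {
    row <- cohort[i, , drop = FALSE]
    m <- NULL
    for (mm in models) if (mm$sex == row$sex) m <- mm
    mu <- predict_expected_cost(m, row)
    mu0 <- predict_expected_cost(m, counterfactual_recode(row, rule))
    den <- den + weights[i] * mu
    num <- num + weights[i] * (mu - mu0)
  }
  num / den
}

# Deterministic toy cohort with an exactly known cost model: Poisson GLM
# on exact expected counts recovers the generating coefficients exactly,
# giving a cost_model whose predictions are closed-form.
toy_exposure_model <- function(p_exposed = 0.5, rho = 2, base = 100,
                               n = 400, sex = "male") {
  n_exp <- round(n * p_exposed)
  cohort <- data.frame(
    person_id = seq_len(n), sex = sex,
    smoking = rep(c("heavy", "non"), c(n_exp, n - n_exp)),
    person_years = 1,
    weight = 1
  )
  cohort$cost_hospital <- ifelse(cohort$smoking == "heavy", base * rho, base)
  fit <- stats::glm(cost_hospital ~ smoking + offset(log(person_years)),
                    data = transform(cohort,
                                     smoking = factor(smoking, c("non", "heavy"))),
                    family = stats::poisson())
  model <- structure(list(
    sex = sex, sector = "hospital", step = 3,
    coefficients = stats::coef(fit), se = sqrt(diag(stats::vcov(fit))),
    theta = Inf, variables = "smoking", dropped = character(0),
    xlevels = list(smoking = c("non", "heavy")),
    offset_convention = "log person-years", weighted = FALSE, fit = fit
  ), class = "cost_model")
  list(cohort = cohort, model = model)
}

# Small generator configs used across tests; prevalences and effects are
# the package defaults (the study conditions), only the sample size and
# switches vary by scenario.
quick_config <- function(n = 1500, ...) {
  default_generator_config(n_per_cycle = n, ...)
}
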