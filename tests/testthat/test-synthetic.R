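test_that("config validation rejects bad prevalences and dispersion", {
  cfg <- quick_config(n = 100)
  expect_silent(validate_generator_config(cfg))
  bad <- cfg; bad$ses$education <- c(lt_highschool = 0.5, highschool = 0.5,
                                     postsecondary = 0.5)
  expect_error(validate_generator_config(bad), "prevalence")
  bad2 <- cfg; bad2$effects$hospital$theta <- -1
  expect_error(validate_generator_config(bad2), "dispersion")
})

test_that("generation is deterministic given the seed", {
  cfg <- quick_config(n = 300)
  a <- generate_cohort(cfg, seed = 99)
  b <- generate_cohort(cfg, seed = 99)
  attr(a, "config") <- NULL; attr(b, "config") <- NULL
  expect_identical(a, b)
  c2 <- generate_cohort(cfg, seed = 100)
  expect_false(identical(a$cost_hospital, c2$cost_hospital))
  # byte-identical CSV on re-run
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(a, f1); write_cohort(b, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("raw responses round-trip through the exposure scorers", {
  co <- generate_cohort(quick_config(n = 2000), seed = 17)
  raw <- co[, setdiff(names(co), c("smoking", "alcohol", "diet", "activity"))]
  scored <- score_cohort(raw)
  agree <- mean(scored$smoking == co$smoking & scored$alcohol == co$alcohol &
                  scored$diet == co$diet & scored$activity == co$activity)
  expect_gte(agree, 0.999)
})

test_that("zero-effect config reproduces the baseline mean cost rate", {
  cfg <- quick_config(n = 4000, missing_rate = 0)
  for (s in names(cfg$effects)) {
    e <- cfg$effects[[s]]
    e[setdiff(names(e), c("intercept", "theta"))] <- NULL
    e$age <- 0; e$sex_male <- 0
    cfg$effects[[s]] <- e
  }
  cfg$cycle_years <- 2003
  co <- generate_cohort(cfg, seed = 53)
  rate <- sum(co$cost_hospital) / sum(co$person_years)
  mu <- exp(cfg$effects$hospital$intercept)
  se <- sqrt(mu + mu^2 / cfg$effects$hospital$theta) / sqrt(nrow(co))
  expect_lt(abs(rate - mu), 2 * se * 2)  # py in 1..4 inflates the SE a little
})

test_that("declining smoking prevalence drifts across cycles", {
  co <- generate_cohort(quick_config(n = 3000), seed = 59)
  p03 <- mean(co$smoking[co$cycle_year == 2003] == "heavy")
  p13 <- mean(co$smoking[co$cycle_year == 2013] == "heavy")
  expect_gt(p03, p13)
})

test_that("enumerated truth matches the closed form in homogeneous cases", {
  cfg <- quick_config(n = 100, missing_rate = 0)
  # single binary exposure: only heavy smoking has an effect, prevalence
  # p at every education level, log cost ratio log(2)
  cfg$confounding <- 0
  cfg$behaviours$smoking <- list(levels = c("heavy", "non"), probs = c(0.5, 0.5))
  for (s in names(cfg$effects)) {
    e <- cfg$effects[[s]]
    e[setdiff(names(e), c("intercept", "theta"))] <- NULL
    e$age <- 0; e$sex_male <- 0
    e$smoking <- c(heavy = log(2))
    cfg$effects[[s]] <- e
  }
  tp <- true_paf(cfg, risks = "smoking", sectors = "hospital",
                 cycle_years = 2003)
  expect_equal(tp$paf, 0.5 * (2 - 1) / (1 + 0.5 * (2 - 1)), tolerance = 1e-12)
  # all cost ratios 1 -> PAF 0 for every risk
  cfg0 <- cfg
  cfg0$effects$hospital$smoking <- NULL
  tp0 <- true_paf(cfg0, sectors = "hospital", cycle_years = 2003)
  expect_true(all(abs(tp0$paf) < 1e-12))
})

test_that("enumeration agrees with its Monte Carlo cross-check", {
  cfg <- quick_config(n = 100)
  exact <- true_paf(cfg, risks = "smoking", sectors = "hospital",
                    cycle_years = 2003)$paf
  mc <- true_paf_mc(cfg, "smoking", "hospital", 2003, n_draws = 2e5, seed = 61)
  expect_lt(abs(exact - mc$paf), 3 * mc$se)
})

test_that("expenditure tables are consistent with the generating model", {
  cfg <- quick_config(n = 100)
  tabs <- generate_expenditure_tables(cfg)
  years <- seq(min(cfg$cycle_years), max(cfg$cycle_years))
  expect_setequal(unique(tabs$expenditures$fiscal_year), years)
  expect_setequal(unique(tabs$expenditures$sector),
                  c("hospital", "drugs", "community", "other"))
  # the 'other' share of the total equals the configured fraction exactly
  y <- years[1]
  ex <- tabs$expenditures[tabs$expenditures$fiscal_year == y, ]
  expect_equal(ex$amount[ex$sector == "other"] / sum(ex$amount),
               cfg$other_share, tolerance = 1e-12)
  # budgets scale linearly with the configured population size
  cfg2 <- cfg; cfg2$population_size <- cfg$population_size * 2
  tabs2 <- generate_expenditure_tables(cfg2)
  expect_equal(tabs2$expenditures$amount, 2 * tabs$expenditures$amount)
  # CPI is monotone with base year 2014 at 1
  expect_equal(tabs$cpi$cpi[tabs$cpi$year == 2014], 1)
  expect_true(all(diff(tabs$cpi$cpi[order(tabs$cpi$year)]) > 0))
  # degenerate single-year config gives a single year of budgets
  cfg1 <- quick_config(n = 100, cycle_years = 2005)
  t1 <- generate_expenditure_tables(cfg1)
  expect_equal(unique(t1$expenditures$fiscal_year), 2005)
})

test_that("informative weights pull the weighted PAF toward the truth", {
  # heavy smokers oversampled 4x: the unweighted sample over-represents
  # the exposed, the design weights undo it
  os <- list(variable = "smoking",
             factor = c(heavy = 6, light = 3, former_heavy = 1,
                        former_light = 1, non = 1, missing = 1))
  cfg <- quick_config(n = 30000, cycle_years = 2003, missing_rate = 0,
                      oversample = os)
  truth <- true_paf(cfg, risks = "smoking", sectors = "hospital",
                    cycle_years = 2003)$paf
  co <- generate_cohort(cfg, seed = 67)
  mM <- fit_cost_model(co, "male", "hospital", 3)
  mF <- fit_cost_model(co, "female", "hospital", 3)
  rule <- attribution_rule("smoking")
  weighted <- paf(list(mM, mF), co, rule)
  unweighted <- paf(list(mM, mF), co, rule, weights = rep(1, nrow(co)))
  expect_lt(abs(weighted - truth), abs(unweighted - truth))
})
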