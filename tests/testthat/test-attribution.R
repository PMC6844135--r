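test_that("counterfactual recoding maps non-reference levels to reference", {
  co <- data.frame(smoking = c("heavy", "former_light", "non", "missing"),
                   alcohol = c("heavy", "non", "moderate", "missing"),
                   diet = "poor", stringsAsFactors = FALSE)
  rec <- counterfactual_recode(co, attribution_rule("smoking"))
  expect_equal(rec$smoking, c("non", "non", "non", "missing"))
  expect_equal(rec$alcohol, co$alcohol)  # untouched
  expect_identical(counterfactual_recode(co, character(0)), co)
  # alcohol recodes both heavy and non to moderate by default
  rec2 <- counterfactual_recode(co, attribution_rule("alcohol"))
  expect_equal(rec2$alcohol, c("moderate", "moderate", "moderate", "missing"))
  # heavy-only switch leaves non-drinkers untouched
  rec3 <- counterfactual_recode(co, attribution_rule("alcohol", heavy_only = TRUE))
  expect_equal(rec3$alcohol, c("moderate", "non", "moderate", "missing"))
  expect_error(counterfactual_recode(co, c(unknown = "x")), "unknown variable")
})

test_that("ses rule recodes all four socioeconomic variables", {
  co <- generate_cohort(quick_config(n = 200), seed = 4)
  rec <- counterfactual_recode(co, attribution_rule("ses"))
  expect_true(all(rec$education %in% c("postsecondary", "missing")))
  expect_true(all(rec$income %in% c("ge80k", "missing")))
  expect_true(all(rec$home_owned %in% c("yes", "missing")))
  expect_true(all(rec$deprivation %in% c("low", "missing")))
})

test_that("homogeneous binary-exposure PAF matches the closed form", {
  for (p in c(0.2, 0.5, 0.8)) for (rho in c(1.5, 2, 4)) {
    toy <- toy_exposure_model(p_exposed = p, rho = rho)
    got <- paf(toy$model, toy$cohort, attribution_rule("smoking"))
    expect_equal(got, p * (rho - 1) / (1 + p * (rho - 1)), tolerance = 1e-10)
  }
  # cost ratio 1 -> PAF 0
  toy1 <- toy_exposure_model(rho = 1)
  expect_equal(paf(toy1$model, toy1$cohort, attribution_rule("smoking")), 0,
               tolerance = 1e-10)
})

test_that("vectorized PAF equals the per-person brute-force oracle", {
  co <- generate_cohort(quick_config(n = 150), seed = 8)
  mM <- fit_cost_model(co, "male", "hospital", 1)
  mF <- fit_cost_model(co, "female", "hospital", 1)
  for (r in c("smoking", "alcohol", "behaviours")) {
    rule <- attribution_rule(r)
    got <- paf(list(mM, mF), co, rule)
    want <- oracle_paf(list(mM, mF), co, rule, co$weight)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("PAF is invariant to weight and cost-scale rescaling", {
  toy <- toy_exposure_model(p_exposed = 0.3, rho = 3)
  rule <- attribution_rule("smoking")
  base <- paf(toy$model, toy$cohort, rule)
  expect_equal(paf(toy$model, toy$cohort, rule,
                   weights = rep(7.3, nrow(toy$cohort))), base,
               tolerance = 1e-12)
  scaled <- toy$model
  scaled$fit$coefficients["(Intercept)"] <-
    scaled$fit$coefficients["(Intercept)"] + log(10)
  expect_equal(paf(scaled, toy$cohort, rule), base, tolerance = 1e-12)
})

test_that("PAF strictly increases with exposure prevalence when rho > 1", {
  pafs <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(p) {
    toy <- toy_exposure_model(p_exposed = p, rho = 2)
    paf(toy$model, toy$cohort, attribution_rule("smoking"))
  }, numeric(1))
  expect_true(all(diff(pafs) > 0))
})

test_that("combined PAF reduces to the single-risk PAF when only one risk varies", {
  co <- generate_cohort(quick_config(n = 400), seed = 6)
  co$alcohol <- "moderate"; co$diet <- "adequate"; co$activity <- "active"
  m <- fit_cost_model(co, "male", "hospital", 1)
  dat <- co[co$sex == "male", ]
  expect_equal(combined_paf(m, dat),
               paf(m, dat, attribution_rule("smoking")), tolerance = 1e-12)
  # all-reference cohort attributes nothing
  m0 <- toy_exposure_model()$model
  allref <- data.frame(sex = "male", smoking = "non", alcohol = "moderate",
                       diet = "adequate", activity = "active",
                       person_years = 1, weight = 1)
  expect_equal(combined_paf(m0, allref), 0)
})

test_that("model-3 PAF converges to the enumerated generating-model truth", {
  truth <- true_paf(quick_config(n = 100, cycle_years = 2003,
                                 missing_rate = 0),
                    risks = "behaviours", sectors = "hospital",
                    cycle_years = 2003)$paf
  one_err <- function(npc, seed) {
    cfg_n <- quick_config(n = npc, cycle_years = 2003, missing_rate = 0)
    co <- generate_cohort(cfg_n, seed = seed)
    mM <- fit_cost_model(co, "male", "hospital", 3)
    mF <- fit_cost_model(co, "female", "hospital", 3)
    abs(combined_paf(list(mM, mF), co) - truth)
  }
  # mean absolute error over replicates, since a single small-n draw can
  # land near the truth by luck
  err_small <- vapply(31:33, one_err, numeric(1), npc = 2000)
  err_large <- vapply(31:33, one_err, numeric(1), npc = 20000)
  expect_lt(mean(err_large), mean(err_small))  # error shrinks with n
  expect_lt(mean(err_large), 0.015)            # and is small at n = 20,000
})

test_that("annual series keeps cycle estimates and interpolates gaps", {
  s <- annual_paf_series(c(`2004` = 0.20, `2006` = 0.30), 2004:2006)
  expect_equal(s$paf, c(0.20, 0.25, 0.30))
  expect_equal(s$provenance, c("cycle_estimate", "interpolated",
                               "cycle_estimate"))
  expect_equal(annual_paf_series(c(`2004` = 0.20), 2004)$paf, 0.20)
  # wide gaps use the nearest cycles on each side
  s2 <- annual_paf_series(c(`2004` = 0.2, `2008` = 0.3), 2004:2008)
  expect_equal(s2$paf[s2$year == 2006], 0.25)
  expect_equal(s2$paf[s2$year == 2005], 0.25)
  expect_error(annual_paf_series(c(`2004` = 0.2), 2003), "span")
})

test_that("paf_series produces a tidy interpolated table per risk and sector", {
  co <- generate_cohort(quick_config(n = 250,
                                     cycle_years = c(2003, 2005, 2007)),
                        seed = 13)
  suite <- suppressMessages(fit_model_suite(co, steps = 3))
  ser <- paf_series(suite, co, risks = c("smoking", "behaviours"),
                    sectors = "hospital", step = 3)
  expect_setequal(names(ser), c("risk", "sector", "year", "paf", "provenance"))
  expect_equal(nrow(ser), 2 * 1 * 5)  # 2 risks x 1 sector x years 2003..2007
  expect_true(all(ser$provenance[ser$year %in% c(2004, 2006)] == "interpolated"))
  smk <- ser[ser$risk == "smoking", ]
  expect_equal(smk$paf[smk$year == 2004],
               mean(smk$paf[smk$year %in% c(2003, 2005)]))
})
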