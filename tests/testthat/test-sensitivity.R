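test_that("top-user exclusion removes ceil(f*n) highest-cost persons", {
  co <- generate_cohort(quick_config(n = 17), seed = 19)  # 102 rows
  n <- nrow(co)
  out <- exclude_top_users(co, 0.05)
  info <- attr(out, "exclusion")
  expect_equal(info$n_removed, ceiling(0.05 * n))
  expect_equal(nrow(out), n - info$n_removed)
  total <- rowSums(co[, grep("^cost_", names(co))])
  removed <- co$person_id %in% info$removed_ids
  # order-statistic property: everyone kept costs no more than anyone removed
  expect_lte(max(total[!removed]), min(total[removed]))
  expect_error(exclude_top_users(co, 0), "between 0 and 1")
  expect_error(exclude_top_users(co, 1), "between 0 and 1")
})

test_that("ties at the exclusion cutoff break by person id with a warning", {
  co <- data.frame(person_id = 1:100, cost_hospital = 5)
  expect_warning(out <- exclude_top_users(co, 0.05), "ties")
  expect_equal(sort(attr(out, "exclusion")$removed_ids), 1:5)
  # re-application removes ceil(f * n') further persons, not none
  expect_warning(out2 <- exclude_top_users(out, 0.05), "ties")
  expect_equal(attr(out2, "exclusion")$n_removed, ceiling(0.05 * nrow(out)))
})

test_that("age-standardized ratio reduces to constant ratios and identity", {
  co <- generate_cohort(quick_config(n = 800), seed = 23)
  # construct exposed costs exactly double the reference in every age group
  co$cost_hospital <- ifelse(co$smoking == "heavy", 200, 100) * co$person_years
  co$cost_drugs <- 0; co$cost_community <- 0
  r <- age_standardized_cost_ratio(co, "smoking", "heavy", "non")
  expect_equal(r, 2.0, tolerance = 1e-12)
  expect_equal(age_standardized_cost_ratio(co, "smoking", "non", "non"), 1.0)
  # single age group reduces to the crude weighted ratio
  co1 <- co; co1$age_group <- "25-29"
  rate <- co1$cost_hospital / co1$person_years
  crude <- stats::weighted.mean(rate[co1$smoking == "heavy"],
                                co1$weight[co1$smoking == "heavy"]) /
    stats::weighted.mean(rate[co1$smoking == "non"],
                         co1$weight[co1$smoking == "non"])
  expect_equal(age_standardized_cost_ratio(co1, "smoking", "heavy", "non"),
               crude, tolerance = 1e-12)
})

test_that("age-standardized ratio recovers the generating cost ratio", {
  cfg <- quick_config(n = 2000, missing_rate = 0)
  cfg$effects$drugs$age <- 0; cfg$effects$community$age <- 0
  cfg$effects$hospital$age <- 0  # no age interaction with cost
  co <- generate_cohort(cfg, seed = 29)
  co <- co[co$sex == "male", ]
  co$cost_drugs <- 0; co$cost_community <- 0
  r <- age_standardized_cost_ratio(co, "smoking", "heavy", "non",
                                   sector = "hospital")
  expect_equal(r, exp(0.40), tolerance = 0.12)
})

test_that("IPW weighted means match a hand-computed toy table", {
  toy <- data.frame(
    person_id = 1:6,
    sex = c("male", "male", "male", "female", "female", "female"),
    smoking = c("heavy", "heavy", "non", "heavy", "non", "non"),
    person_years = 1, weight = 1,
    cost_hospital = c(300, 260, 120, 280, 100, 110))
  r <- ipw_cost_ratio(toy, "smoking", "sex", reference_level = "non",
                      truncate_at = 1)
  # propensities by sex: P(heavy|male)=2/3, P(heavy|female)=1/3
  marg <- c(heavy = 0.5, non = 0.5)
  p_obs <- c(2/3, 2/3, 1/3, 1/3, 2/3, 2/3)
  sw <- marg[toy$smoking] / p_obs
  want_heavy <- stats::weighted.mean(toy$cost_hospital[toy$smoking == "heavy"],
                                     sw[toy$smoking == "heavy"])
  want_non <- stats::weighted.mean(toy$cost_hospital[toy$smoking == "non"],
                                   sw[toy$smoking == "non"])
  expect_equal(unname(r["heavy"]), want_heavy / want_non, tolerance = 1e-6)
  expect_equal(unname(r["non"]), 1)
  expect_error(ipw_cost_ratio(toy[toy$smoking == "non", ], "smoking", "sex"),
               "empty treatment level")
})

test_that("under randomization IPW ratios match crude ratios", {
  cfg <- quick_config(n = 3000, missing_rate = 0, confounding = 0)
  co <- generate_cohort(cfg, seed = 37)
  co <- co[co$sex == "male", ]
  r_ipw <- ipw_cost_ratio(co, "smoking", c("education", "income"),
                          sector = "hospital")
  rate <- co$cost_hospital / co$person_years
  crude <- vapply(names(r_ipw), function(l)
    mean(rate[co$smoking == l]), numeric(1))
  crude <- crude / crude[["non"]]
  expect_equal(unname(r_ipw["heavy"]), unname(crude["heavy"]),
               tolerance = 0.05)
})

test_that("ladder bounds: equal without confounding, ordered with it", {
  # no confounding: behaviours independent of SES, so the three ladder
  # steps target the same estimand
  cfg0 <- quick_config(n = 2500, missing_rate = 0, confounding = 0)
  co0 <- generate_cohort(cfg0, seed = 41)
  suite0 <- suppressMessages(fit_model_suite(co0, sectors = "hospital"))
  b0 <- bound_estimates(suite0, co0, attribution_rule("smoking"), "hospital")
  expect_lt(abs(b0$upper - b0$primary), 0.03)
  expect_lt(abs(b0$primary - b0$lower), 0.03)
  # positive SES confounding inflates the under-adjusted step-1 estimate
  cfg1 <- quick_config(n = 2500, missing_rate = 0, confounding = 1.5)
  co1 <- generate_cohort(cfg1, seed = 43)
  suite1 <- suppressMessages(fit_model_suite(co1, sectors = "hospital",
                                             steps = c(1, 3, 5)))
  b1 <- bound_estimates(suite1, co1, attribution_rule("smoking"), "hospital")
  expect_gt(b1$upper, b1$primary)
  # empty rule attributes nothing at any step
  b_empty <- bound_estimates(suite0, co0, character(0), "hospital")
  expect_equal(c(b_empty$primary, b_empty$upper, b_empty$lower), rep(0, 3))
})
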