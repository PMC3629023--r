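test_that("generation is reproducible given a seed", {
  cfg <- synthetic_cohort_config(n_deliveries = 800, seed = 123)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$cohort, g2$cohort)
  expect_identical(g1$denominators, g2$denominators)
})

test_that("configuration is validated", {
  expect_error(synthetic_cohort_config(p_case = 1.2), "probabilities")
  expect_error(synthetic_cohort_config(transfusion_distribution = c(.5, .4)),
               "probability vector")
  expect_error(
    synthetic_cohort_config(criterion_prevalence = c(bogus = 0.1)),
    "unknown criteria")
  expect_error(
    synthetic_cohort_config(missingness_rates = c(not_a_field = 0.5)),
    "unknown fields")
})

test_that("cases fire through the real predicates, never by label", {
  g <- generate_cohort(synthetic_cohort_config(n_deliveries = 3000, seed = 2))
  coh <- g$cohort
  intended <- !is.na(coh$pregnancy_timing)
  cl <- classify_cohort(coh, "Haydom")
  # every intended case is classified positive from its field values alone,
  # and nothing else is
  expect_equal(unname(cl$label != "non_case"), unname(intended))
  # deaths only among cases
  expect_true(all(intended[coh$outcome == "dead"]))
  # a shock case really carries the shock physiology
  shock_rows <- which(cl$met[, "shock"])
  if (length(shock_rows) > 0) {
    expect_true(all(coh$sbp_min_sustained_mmHg[shock_rows] < 90))
    expect_true(all(coh$fluids_given_L[shock_rows] > 2))
  }
})

test_that("positive count tracks the configured case rate", {
  cfg <- synthetic_cohort_config(n_deliveries = 9471, p_case = 0.026,
                                 seed = 41)
  g <- generate_cohort(cfg)
  cl <- classify_cohort(g$cohort, "Haydom")
  n_pos <- sum(cl$label != "non_case")
  expected <- 9471 * 0.026
  se <- sqrt(9471 * 0.026 * (1 - 0.026))
  expect_lt(abs(n_pos - expected), 3 * se)
})

test_that("scalar probability parameters are recovered within 3 SE", {
  # pooled over 20 seeds at reduced n for runtime; the SE bands scale with
  # the pooled trial counts
  n_del <- 1500
  seeds <- 1:20
  tot <- list(cases = 0, deliveries = 0, live = 0, deaths = 0,
              sole = 0, one_unit = 0, temp_present = 0, temp_eligible = 0)
  cfg0 <- synthetic_cohort_config()
  for (s in seeds) {
    cfg <- synthetic_cohort_config(
      n_deliveries = n_del, seed = s,
      sole_transfusion_fraction = 0.7,
      # no criterion reads temperature here, so masking is unconditional
      criterion_prevalence = c(shock = 0.3, icu_admission = 0.4,
                               hysterectomy = 0.2),
      missingness_rates = c(temp_extreme_C = 0.5))
    g <- generate_cohort(cfg)
    coh <- g$cohort
    case <- !is.na(coh$pregnancy_timing)
    tot$cases <- tot$cases + sum(case)
    tot$deliveries <- tot$deliveries + n_del
    tot$live <- tot$live + g$denominators$n_live_births
    tot$deaths <- tot$deaths + sum(coh$outcome == "dead")
    u1 <- case & coh$blood_units_transfused == 1
    cl <- classify_cohort(coh, "Haydom")
    other <- rowSums(cl$met[, setdiff(colnames(cl$met), "transfusion"),
                            drop = FALSE]) > 0
    tot$one_unit <- tot$one_unit + sum(u1)
    tot$sole <- tot$sole + sum(u1 & !other)
    tot$temp_eligible <- tot$temp_eligible + sum(case)
    tot$temp_present <- tot$temp_present + sum(case & !is.na(coh$temp_extreme_C))
  }
  within_3se <- function(k, n, p) {
    abs(k / n - p) < 3 * sqrt(p * (1 - p) / n) + 1e-12
  }
  expect_true(within_3se(tot$cases, tot$deliveries, cfg0$p_case))
  expect_true(within_3se(tot$live, tot$deliveries, cfg0$live_birth_rate))
  expect_true(within_3se(tot$deaths, tot$cases, cfg0$p_death_given_case))
  expect_true(within_3se(tot$sole, tot$one_unit, 0.7))
  expect_true(within_3se(tot$temp_present, tot$temp_eligible, 0.5))
})

test_that("latent severity induces positive criterion co-occurrence", {
  cfg <- synthetic_cohort_config(n_deliveries = 20000, p_case = 0.1,
                                 severity_loading = 0.8, seed = 9)
  g <- generate_cohort(cfg)
  cl <- classify_cohort(g$cohort, "Haydom")
  case <- !is.na(g$cohort$pregnancy_timing)
  met <- cl$met[case, ]
  # deaths concentrate in cases with more met criteria
  dead <- g$cohort$outcome[case] == "dead"
  expect_gt(mean(rowSums(met)[dead]), mean(rowSums(met)[!dead]))
  # two common criteria co-occur more than independence predicts
  a <- met[, "icu_admission"]; b <- met[, "shock"]
  expect_gt(mean(a & b), mean(a) * mean(b))
})
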