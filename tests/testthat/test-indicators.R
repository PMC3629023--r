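test_that("SMO ratio and CFR reproduce the reference cohort values", {
  fx <- haydom_fx()
  cl <- classify_cohort(fx$cohort, "Haydom")
  ind <- compute_indicators(cl, fx$denominators, fx$cohort)
  expect_equal(ind$n_SMO, 248)
  expect_equal(round_half_up(ind$smo_ratio_per_1000_livebirths), 27.1)
  expect_equal(round_half_up(ind$cfr_percent), 12.9)
  expect_true(all(ind$per_criterion_counts <= ind$n_SMO))
})

test_that("degenerate cohorts are handled explicitly", {
  cl <- classify_cohort(empty_cohort(0), "Haydom")
  ind <- compute_indicators(cl, denominators(100, 95))
  expect_equal(ind$smo_ratio_per_1000_livebirths, 0)
  expect_true(is.na(ind$cfr_percent))
})

test_that("criterion frequencies count positives per criterion met", {
  fx <- haydom_fx()
  cl <- classify_cohort(fx$cohort, "Haydom")
  freq <- criterion_frequency_table(cl)
  published <- c(
    acute_cyanosis = 0, gasping = 15, resp_rate_extreme = 10, shock = 51,
    oliguria = 4, clot_failure = 3, unconsciousness = 16,
    cardiac_arrest = 26, stroke = 4, uncontrollable_fit = 3,
    jaundice_preeclampsia = 3, spo2_low = 17, thrombocytopenia = 12,
    icu_admission = 91, hysterectomy = 16, transfusion = 184,
    intubation = 15, cpr = 19, eclampsia = 15, sepsis = 30,
    uterine_rupture = 20)
  expect_equal(freq[names(published)], published, ignore_attr = TRUE)

  # a single near miss meeting one criterion
  rec <- empty_cohort(1)
  rec$stroke <- TRUE
  f1 <- criterion_frequency_table(classify_cohort(rec, "WHO"))
  expect_equal(sum(f1), 1)
  expect_equal(f1[["stroke"]], 1)

  # whenever every positive meets >= 1 criterion, totals cover the positives
  coh <- random_cohort(120, seed = 3)
  cl2 <- classify_cohort(coh, "Haydom")
  pos_with_crit <- sum(rowSums(cl2$met) > 0 & cl2$label != "non_case")
  expect_gte(sum(criterion_frequency_table(cl2)), pos_with_crit)
})

test_that("completeness reports exact fractions", {
  coh <- empty_cohort(248)
  coh$urine_output_mL_24h[1:25] <- 400
  comp <- completeness_report(coh)
  expect_equal(comp[["urine_output_mL_24h"]], 25 / 248)
  expect_equal(round_half_up(100 * comp[["urine_output_mL_24h"]]), 10.1)

  full <- random_cohort(10, fill = 1, seed = 1)
  expect_true(all(completeness_report(full) == 1))
})

test_that("threshold sweep at the profile threshold is the identity", {
  fx <- haydom_fx()
  sw <- transfusion_threshold_sweep(fx$cohort, "Haydom", fx$denominators,
                                    thresholds = 1L)
  cl <- classify_cohort(fx$cohort, "Haydom")
  expect_equal(sw$n_positives, sum(rowSums(cl$met) > 0))
  expect_equal(sw$n_positives, 248)
})

test_that("sweep positives shrink and specificity grows with the threshold", {
  fx <- haydom_fx()
  sw <- transfusion_threshold_sweep(fx$cohort, "Haydom", fx$denominators,
                                    thresholds = 1:6)
  expect_true(all(diff(sw$n_positives) <= 0))
  expect_true(all(diff(sw$specificity) >= -1e-12))

  # same property on random cohorts
  for (s in 1:5) {
    coh <- random_cohort(150, fill = 0.25, seed = 100 + s)
    d <- denominators(500, 480)
    sws <- transfusion_threshold_sweep(coh, "Haydom", d, thresholds = 1:5)
    expect_true(all(diff(sws$n_positives) <= 0), info = paste("seed", s))
    expect_true(all(diff(sws$specificity) >= -1e-12), info = paste("seed", s))
  }
})

test_that("indicators are invariant under record order permutation", {
  fx <- haydom_fx()
  set.seed(8)
  perm <- sample(nrow(fx$cohort))
  shuffled <- as_mnm_cohort(as.data.frame(fx$cohort)[perm, ])
  i1 <- compute_indicators(classify_cohort(fx$cohort, "Haydom"),
                           fx$denominators)
  i2 <- compute_indicators(classify_cohort(shuffled, "Haydom"),
                           fx$denominators)
  expect_equal(i1$smo_ratio_per_1000_livebirths,
               i2$smo_ratio_per_1000_livebirths)
  expect_equal(i1$cfr_percent, i2$cfr_percent)
  expect_equal(i1$per_criterion_counts, i2$per_criterion_counts)
})
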