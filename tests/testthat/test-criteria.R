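test_that("registry contains the full criterion set with correct categories", {
  reg <- builtin_registry()
  cats <- vapply(reg, `[[`, character(1), "category")
  expect_equal(sum(cats == "clinical"), 11)
  expect_equal(sum(cats == "laboratory"), 8)
  expect_equal(sum(cats == "management"), 7)  # 6 WHO + ICU admission
  expect_equal(sum(cats == "disease"), 3)
  expect_equal(reg[["shock"]]$category, "clinical")

  who <- audit_profile("WHO")
  expect_length(who$included_criteria, 25)
  expect_true(all(who$included_criteria %in% names(reg)))
  expect_false("icu_admission" %in% who$included_criteria)

  hay <- audit_profile("Haydom")
  expect_length(hay$included_criteria, 21)
  expect_setequal(setdiff(hay$included_criteria, who$included_criteria),
                  c("icu_admission", "eclampsia", "sepsis", "uterine_rupture"))
  expect_equal(
    hay$parameter_overrides$transfusion$transfusion_threshold_units, 1)

  expect_length(audit_profile("WHO-clinical")$included_criteria, 11)
})

test_that("criterion predicates match their clinical definitions", {
  reg <- builtin_registry()
  rec <- empty_cohort(1)
  rec$sbp_min_sustained_mmHg <- 80
  rec$pulse_max_concurrent_bpm <- 130
  rec$fluids_given_L <- 2.5
  ev <- evaluate_criterion(rec, reg$shock)
  expect_true(ev$met && ev$evaluable)

  # pulse below 120: the hypotension alone is not shock
  rec$pulse_max_concurrent_bpm <- 110
  expect_false(evaluate_criterion(rec, reg$shock)$met)

  # transfusion threshold: 4 units miss the 5-unit default, meet 1-unit
  rec <- empty_cohort(1)
  rec$blood_units_transfused <- 4L
  expect_false(evaluate_criterion(rec, reg$transfusion)$met)
  expect_true(evaluate_criterion(
    rec, reg$transfusion, list(transfusion_threshold_units = 1))$met)
  expect_error(
    evaluate_criterion(rec, reg$transfusion, list(bogus = 1)),
    "unknown parameter")

  # sepsis: infection sign + 3 of 4 systemic signs
  rec <- empty_cohort(1)
  rec$clinical_infection_sign <- TRUE
  rec$temp_extreme_C <- 39
  rec$resp_rate_extreme_per_min <- 24
  rec$pulse_max_concurrent_bpm <- 95
  rec$wbc_10e9_per_L <- 8
  expect_true(evaluate_criterion(rec, reg$sepsis)$met)
  rec$temp_extreme_C <- 37   # only 2 of 4 now
  expect_false(evaluate_criterion(rec, reg$sepsis)$met)

  # unconsciousness: duration OR low GCS
  rec <- empty_cohort(1)
  rec$gcs_min <- 8L
  expect_true(evaluate_criterion(rec, reg$unconsciousness)$met)
  rec <- empty_cohort(1)
  rec$unconscious_hours <- 13
  expect_true(evaluate_criterion(rec, reg$unconsciousness)$met)
})

test_that("missing data never fires a criterion: met implies evaluable", {
  reg <- builtin_registry()
  blank <- empty_cohort(1)
  for (def in reg) {
    if (def$id == "transfusion") next  # units default to 0, evaluable by design
    ev <- evaluate_criterion(blank, def)
    expect_false(ev$met, info = def$id)
    expect_false(ev$evaluable, info = def$id)
  }
  # property over random part-populated cohorts
  coh <- random_cohort(150, fill = 0.3, seed = 99)
  cl <- classify_cohort(coh, "Haydom")
  expect_true(all(!cl$met | cl$evaluable))
})

test_that("classification follows the audit label definitions", {
  reg <- builtin_registry()
  rec <- empty_cohort(1)
  rec$cardiac_arrest <- TRUE
  expect_equal(classify_case(rec, "WHO"),
               list(label = "MNM", met_criteria = "cardiac_arrest"))

  # a death with no met criterion is still a maternal death
  rec <- empty_cohort(1)
  rec$outcome <- "dead"
  out <- classify_case(rec, "WHO")
  expect_equal(out$label, "MD")
  expect_length(out$met_criteria, 0)

  # one unit transfused, nothing else: Haydom positive, WHO negative
  rec <- empty_cohort(1)
  rec$blood_units_transfused <- 1L
  expect_equal(classify_case(rec, "Haydom")$label, "MNM")
  expect_equal(classify_case(rec, "WHO")$label, "non_case")

  expect_equal(unname(classify_cohort(empty_cohort(0), "Haydom")$counts),
               c(0L, 0L, 0L))
})

test_that("cohort label counts partition the cohort", {
  coh <- random_cohort(200, seed = 5)
  for (pr in c("WHO", "Haydom")) {
    cl <- classify_cohort(coh, pr)
    expect_equal(sum(cl$counts), nrow(coh))
    expect_equal(as.character(cl$label[coh$outcome == "dead"]),
                 rep("MD", sum(coh$outcome == "dead")))
  }
})

test_that("subset profiles and stricter thresholds are monotone", {
  coh <- random_cohort(300, fill = 0.35, seed = 17)
  hay <- audit_profile("Haydom")
  clin <- audit_profile("WHO-clinical")
  # WHO-clinical criteria are a subset of Haydom's with identical parameters
  pos_sub <- rowSums(classify_cohort(coh, clin)$met) > 0
  pos_sup <- rowSums(classify_cohort(coh, hay)$met) > 0
  expect_true(all(pos_sup[pos_sub]))

  # raising the transfusion threshold never adds positives
  prev <- rep(TRUE, nrow(coh))
  for (t in 1:6) {
    pr <- hay
    pr$parameter_overrides$transfusion$transfusion_threshold_units <- t
    pos <- rowSums(classify_cohort(coh, pr)$met) > 0
    expect_true(all(prev[pos]), info = paste("threshold", t))
    prev <- pos
  }
})

test_that("profiles round-trip through JSON and validate", {
  hay <- audit_profile("Haydom")
  tmp <- withr::local_tempfile(fileext = ".json")
  write_profile(hay, tmp)
  expect_equal(unclass(read_profile(tmp)), unclass(hay))

  bad <- hay
  bad$included_criteria <- c(bad$included_criteria, "nonexistent")
  expect_error(write_profile(bad), "unknown criteria")
  bad <- hay
  bad$parameter_overrides$transfusion$transfusion_threshold_units <- 0
  expect_error(write_profile(bad, tmp), "must be >= 1")
})
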