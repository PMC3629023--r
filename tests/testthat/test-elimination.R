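test_that("the reconstructed WHO matrix replays the published elimination", {
  m <- fixture_who_matrix()
  expect_equal(dim(m), c(92, 17))
  expect_equal(colSums(m)[["shock"]], 51)
  expect_equal(colSums(m)[["cardiac_arrest"]], 26)

  tr <- stepwise_elimination(m)
  s1 <- tr$steps[[1]]
  expect_equal(s1$selected_criterion, "shock")
  expect_equal(s1$cases_removed, 51)
  expect_equal(s1$remaining_after, 41)
  s2 <- tr$steps[[2]]
  expect_equal(s2$selected_criterion, "unconsciousness")
  expect_equal(s2$cases_removed, 13)
  expect_equal(s2$frequency_snapshot[["unconsciousness"]], 13)

  # the tie at step 3 (cardiac arrest vs hysterectomy, both 8) resolves in
  # favour of the criterion more frequent in the full cohort
  expect_equal(tr$steps[[3]]$selected_criterion, "cardiac_arrest")
  expect_equal(tr$steps[[3]]$frequency_snapshot[["hysterectomy"]], 8)

  # every non-dash cell of the published grid is reproduced
  marg <- fixture_who_marginals()
  replay <- step_marginals(tr)
  expect_identical(replay$selected, marg$selected)
  expect_equal(replay$counts[rownames(marg$counts), ],
               marg$counts, ignore_attr = TRUE)
})

test_that("independent and passive partitions match the published refinement", {
  tr <- stepwise_elimination(fixture_who_matrix())
  contrib <- independent_contribution(tr)
  expect_equal(
    contrib$independent$criterion,
    c("shock", "unconsciousness", "cardiac_arrest", "hysterectomy",
      "thrombocytopenia", "intubation", "spo2_low", "resp_rate_extreme",
      "oliguria", "clot_failure", "jaundice_preeclampsia", "transfusion"))
  expect_equal(contrib$independent$count,
               c(51, 13, 8, 8, 4, 2, 1, 1, 1, 1, 1, 1))
  expect_setequal(contrib$passive,
                  c("cpr", "gasping", "stroke", "uncontrollable_fit"))
  expect_equal(contrib$unused, "acute_cyanosis")
  # conservation: every case removed exactly once
  expect_equal(sum(contrib$independent$count), 92)
})

test_that("trivial matrices eliminate as expected", {
  # each case meets exactly one distinct criterion: selection order follows
  # the counts, every criterion independent with its own count
  m <- matrix(FALSE, 6, 3, dimnames = list(NULL, c("a", "b", "c")))
  m[1:3, "b"] <- TRUE; m[4:5, "a"] <- TRUE; m[6, "c"] <- TRUE
  tr <- stepwise_elimination(as_incidence_matrix(m))
  expect_equal(tr$independent$criterion, c("b", "a", "c"))
  expect_equal(tr$independent$count, c(3, 2, 1))
  expect_length(tr$passive, 0)

  # single criterion cohort
  m1 <- matrix(TRUE, 4, 1, dimnames = list(NULL, "only"))
  tr1 <- stepwise_elimination(as_incidence_matrix(m1))
  expect_equal(tr1$independent$criterion, "only")
  expect_equal(tr1$independent$count, 4)

  expect_error(as_incidence_matrix(matrix(FALSE, 2, 2)), "all-zero")
})

test_that("elimination agrees with an independent replay oracle", {
  for (s in 1:20) {
    m <- random_incidence(50, 10, p = 0.15, seed = 300 + s)
    tr <- stepwise_elimination(m)
    orc <- oracle_elimination(m)
    expect_equal(tr$independent$criterion, orc$selected,
                 info = paste("seed", 300 + s))
    expect_equal(tr$independent$count, orc$counts)
    expect_equal(vapply(tr$steps, `[[`, numeric(1), "remaining_after"),
                 orc$remaining_after)
    expect_equal(sum(tr$independent$count), 50)
  }
})

test_that("marginals round-trip: reconstruct then eliminate reproduces them", {
  for (s in 1:12) {
    m <- random_incidence(40, 8, p = 0.2, seed = 500 + s)
    marg <- step_marginals(stepwise_elimination(m))
    m2 <- reconstruct_from_marginals(marg)
    marg2 <- step_marginals(stepwise_elimination(m2))
    expect_identical(marg2$selected, marg$selected)
    expect_equal(marg2$counts, marg$counts, ignore_attr = TRUE)
  }
})

test_that("the trace is insensitive to within-step co-occurrence shuffles", {
  # permute case rows (co-occurrence unchanged) and, separately, rebuild from
  # marginals (co-occurrence re-assigned): identical traces either way
  m <- random_incidence(60, 9, p = 0.18, seed = 77)
  tr <- stepwise_elimination(m)
  set.seed(78)
  mp <- as_incidence_matrix(unclass(m)[sample(nrow(m)), ])
  trp <- stepwise_elimination(mp)
  expect_equal(trp$independent, tr$independent)
  mr <- reconstruct_from_marginals(step_marginals(tr))
  expect_equal(stepwise_elimination(mr)$independent, tr$independent)
})

test_that("inconsistent marginals are rejected by name", {
  marg <- fixture_who_marginals()
  bad <- marg
  bad$counts["cpr", 2] <- 25L  # count increases after a removal step
  expect_error(reconstruct_from_marginals(bad), "cpr")
  bad2 <- marg
  bad2$counts["oliguria", 7] <- 4L  # rises back after the intubation step
  expect_error(reconstruct_from_marginals(bad2), "oliguria")
})

test_that("one-step marginals reconstruct to an all-true column", {
  marg <- list(counts = matrix(c(5L, 0L), 1, 2,
                               dimnames = list("only", NULL)),
               selected = "only")
  m <- reconstruct_from_marginals(marg)
  expect_equal(dim(m), c(5, 1))
  expect_true(all(m))
})

test_that("the exported elimination table mirrors the published layout", {
  tab <- elimination_table(stepwise_elimination(fixture_who_matrix()))
  expect_equal(tab$full_cohort[tab$criterion == "shock"], "51 (55.4%)")
  expect_equal(tab[tab$criterion == "shock", 3], "EXCL")
  expect_equal(tab$full_cohort[tab$criterion == "cardiac_arrest"],
               "26 (28.3%)")
  expect_equal(tab[tab$criterion == "acute_cyanosis", 2], "-")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_elimination_tsv(stepwise_elimination(fixture_who_matrix()), tmp)
  expect_true(file.exists(tmp))
})
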