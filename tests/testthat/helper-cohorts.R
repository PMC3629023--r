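# Shared test fixtures, all built in code.

# A randomly populated cohort for round-trip and invariance properties:
# every optional field gets a value with probability `fill`, with draws that
# respect the record invariants.
random_cohort <- function(n, fill = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  coh <- empty_cohort(n, case_id = sprintf("r%04d", seq_len(n)))
  coh$outcome <- sample(c("alive", "dead"), n, replace = TRUE, prob = c(.9, .1))
  coh$blood_units_transfused <- sample(0:6, n, replace = TRUE,
                                       prob = c(.6, .2, .1, .05, .03, .01, .01))
  sc <- cohort_schema()
  for (i in seq_len(nrow(sc))) {
    nm <- sc$name[i]
    if (nm %in% c("case_id", "outcome", "blood_units_transfused")) next
    on <- runif(n) < fill
    if (!any(on)) next
    coh[[nm]][on] <- switch(sc$type[i],
      character = sample(c("pregnant", "intrapartum", "postpartum_42d"),
                         sum(on), replace = TRUE),
      logical = runif(sum(on)) < 0.5,
      integer = if (nm == "gcs_min") sample(3:15, sum(on), replace = TRUE)
                else sample(0:500, sum(on), replace = TRUE),
      numeric = {
        x <- round(runif(sum(on), 0, 300), 3)
        if (nm == "spo2_min_pct") x <- round(runif(sum(on), 0, 100), 1)
        if (nm == "ph_arterial") x <- round(runif(sum(on), 6.8, 7.6), 2)
        x
      })
  }
  as_mnm_cohort(as.data.frame(coh))
}

# Random valid incidence matrix: every case carries >= 1 criterion.
random_incidence <- function(n_cases, n_crit, p = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(runif(n_cases * n_crit) < p, n_cases, n_crit,
              dimnames = list(sprintf("c%03d", seq_len(n_cases)),
                              sprintf("crit_%02d", seq_len(n_crit))))
  empty <- rowSums(m) == 0
  m[cbind(which(empty), sample(n_crit, sum(empty), replace = TRUE))] <- TRUE
  as_incidence_matrix(m)
}

# Independent re-implementation of the greedy elimination, used as oracle:
# a direct transcription of the procedure with no shared code.
oracle_elimination <- function(m) {
  m <- unclass(m)
  full <- colSums(m)
  alive <- rep(TRUE, nrow(m))
  taken <- rep(FALSE, ncol(m))
  sel <- character(); cnt <- integer(); after <- integer()
  while (sum(alive) > 0) {
    f <- colSums(m[alive, , drop = FALSE])
    f[taken] <- -Inf
    best <- which(f == max(f))
    if (length(best) > 1) {
      best <- best[order(-full[best], best)]
    }
    j <- best[1]
    sel <- c(sel, colnames(m)[j])
    cnt <- c(cnt, sum(alive & m[, j]))
    alive <- alive & !m[, j]
    after <- c(after, sum(alive))
    taken[j] <- TRUE
  }
  list(selected = sel, counts = cnt, remaining_after = after)
}

haydom_fx <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- fixture_haydom_cohort()
    cache
  }
})
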