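# Synthetic cohort generator.
#
# Emulates the statistical structure the audit analysis assumes: a hospital
# delivery cohort in which a small fraction of women become criteria-positive
# cases, criterion co-occurrence is driven by a latent severity scalar, blood
# transfusion has a heavy 1-unit component with many sole-criterion
# recipients, deaths concentrate in the most severe cases, and routine
# measurements are incompletely documented.
#
# Each configured probability is an exact marginal: criterion indicators and
# death are generated through a Gaussian copula on the shared severity score
# (u_i = Phi(rho * z + sqrt(1 - rho^2) * e_i) is Uniform(0,1) whatever rho),
# so empirical rates are unbiased estimators of the configured parameters —
# the basis of the parameter-recovery properties in the test suite.
#
# Missingness models incomplete routine documentation. It never erases the
# evidence fields of a case's met criteria: a case is in the audit because
# the criterion was observed, so the published per-criterion counts are
# observed counts while the completeness percentages describe routine
# measurement documentation.

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the magnitudes of the reference audit: 9,471
#' deliveries, 9,136/9,471 live-birth rate, 248/9,471 case rate, 32/248
#' deaths among cases, per-criterion prevalences from the published Haydom
#' frequency column, the published transfusion-unit distribution (with the
#' documented 3-4 unit filler), 77/108 sole one-unit recipients, and
#' missingness rates matching the published completeness percentages
#' (e.g. oxygen saturation documented in 4.8% of cases, urinary output
#' in 10%).
#'
#' @param n_deliveries number of delivered women.
#' @param live_birth_rate probability a delivery yields a live birth.
#' @param p_case probability a delivery becomes a criteria-positive case.
#' @param p_death_given_case probability a case dies.
#' @param severity_loading correlation loading (0..1) of criterion and death
#'   indicators on the latent severity scalar; 0 = independence.
#' @param criterion_prevalence named vector of per-criterion marginal
#'   prevalences among cases (transfusion is governed separately by
#'   `transfusion_distribution`).
#' @param transfusion_distribution probability vector over 0..K units,
#'   must sum to 1.
#' @param sole_transfusion_fraction probability that a one-unit recipient
#'   has no other met criterion.
#' @param missingness_rates named vector: probability each routine field is
#'   left unrecorded (fields backing a case's met criteria are never masked).
#' @param seed integer RNG seed, or NULL to use the current RNG state.
#' @return A validated `synthetic_cohort_config` list.
#' @export
synthetic_cohort_config <- function(
    n_deliveries = 9471,
    live_birth_rate = 9136 / 9471,
    p_case = 248 / 9471,
    p_death_given_case = 32 / 248,
    severity_loading = 0.6,
    criterion_prevalence = c(
      acute_cyanosis = 0, gasping = 15 / 248, resp_rate_extreme = 10 / 248,
      shock = 51 / 248, oliguria = 4 / 248, clot_failure = 3 / 248,
      unconsciousness = 16 / 248, cardiac_arrest = 26 / 248,
      stroke = 4 / 248, uncontrollable_fit = 3 / 248,
      jaundice_preeclampsia = 3 / 248, spo2_low = 17 / 248,
      thrombocytopenia = 12 / 248, icu_admission = 91 / 248,
      hysterectomy = 16 / 248, intubation = 15 / 248, cpr = 19 / 248,
      eclampsia = 15 / 248, sepsis = 30 / 248, uterine_rupture = 20 / 248),
    transfusion_distribution = c(64, 108, 54, 12, 8, 1, 1) / 248,
    sole_transfusion_fraction = 77 / 108,
    missingness_rates = c(
      hypertension = 0.26, pulse_max_concurrent_bpm = 0.32,
      resp_rate_extreme_per_min = 0.32, temp_extreme_C = 0.35,
      wbc_10e9_per_L = 0.10, platelets_per_mL = 0.10,
      urine_output_mL_24h = 0.90, spo2_min_pct = 0.952),
    seed = NULL) {
  cfg <- list(n_deliveries = as.integer(n_deliveries),
              live_birth_rate = live_birth_rate, p_case = p_case,
              p_death_given_case = p_death_given_case,
              severity_loading = severity_loading,
              criterion_prevalence = criterion_prevalence,
              transfusion_distribution = transfusion_distribution,
              sole_transfusion_fraction = sole_transfusion_fraction,
              missingness_rates = missingness_rates, seed = seed)
  probs <- c(live_birth_rate, p_case, p_death_given_case,
             sole_transfusion_fraction, criterion_prevalence,
             missingness_rates, severity_loading)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    stop_mnm("all probabilities must lie in [0, 1]",
             class = "mnm_config_error")
  }
  if (abs(sum(transfusion_distribution) - 1) > 1e-8 ||
      any(transfusion_distribution < 0)) {
    stop_mnm("transfusion_distribution must be a probability vector",
             class = "mnm_config_error")
  }
  if (n_deliveries < 1) stop_mnm("n_deliveries must be positive",
                                 class = "mnm_config_error")
  reg <- builtin_registry()
  unknown <- setdiff(names(criterion_prevalence), names(reg))
  if (length(unknown) > 0) {
    stop_mnm("unknown criteria in criterion_prevalence: %s",
             paste(unknown, collapse = ", "), class = "mnm_config_error")
  }
  bad <- setdiff(names(missingness_rates), cohort_schema()$name)
  if (length(bad) > 0) {
    stop_mnm("unknown fields in missingness_rates: %s",
             paste(bad, collapse = ", "), class = "mnm_config_error")
  }
  structure(cfg, class = "synthetic_cohort_config")
}

# Correlated Bernoulli via Gaussian copula: marginal is exactly `prob`,
# and higher z (severity) makes the event more likely when loading > 0.
copula_bernoulli <- function(z, prob, loading) {
  u <- stats::pnorm(loading * z + sqrt(1 - loading^2) * stats::rnorm(length(z)))
  u < prob
}

# Routine admission measurements with unremarkable values; only filled where
# no criterion has set the field already.
routine_defaults <- c(
  hypertension = FALSE, pulse_max_concurrent_bpm = 80,
  resp_rate_extreme_per_min = 16, temp_extreme_C = 37,
  wbc_10e9_per_L = 8, platelets_per_mL = 250000,
  urine_output_mL_24h = 1500, spo2_min_pct = 98)

#' Generate a synthetic delivery cohort
#'
#' Every delivered woman gets a record; non-case women have all optional
#' fields missing, zero transfused units and outcome `alive`. Cases receive
#' measurement values that make their intended criteria fire through the
#' real predicates (a shock case gets SBP 80 sustained, pulse 130, fluids
#' 2.5 L — never a label injection), then routine admission measurements,
#' then missingness.
#'
#' @param config a [synthetic_cohort_config()].
#' @return List with `cohort` (an `mnm_cohort`, cases first), `denominators`
#'   and the `config` used. Reproducible: a fixed `seed` yields a
#'   byte-identical cohort.
#' @export
generate_cohort <- function(config = synthetic_cohort_config()) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_deliveries
  n_live <- stats::rbinom(1, n, config$live_birth_rate)
  is_case <- stats::runif(n) < config$p_case
  n_case <- sum(is_case)

  prev <- config$criterion_prevalence
  units_support <- seq_along(config$transfusion_distribution) - 1L
  draw_met <- function(z) {
    m <- vapply(prev, function(p) {
      copula_bernoulli(z, p, config$severity_loading)
    }, logical(length(z)))
    matrix(m, nrow = length(z), dimnames = list(NULL, names(prev)))
  }

  z <- stats::rnorm(n_case)
  met <- draw_met(z)
  units <- sample(units_support, n_case, replace = TRUE,
                  prob = config$transfusion_distribution)
  # Sole-transfusion mechanism: each one-unit recipient is sole (no other
  # criterion) with exactly `sole_transfusion_fraction` probability; the
  # complement is conditioned on carrying >= 1 other criterion, so the
  # fraction is an exact marginal. Zero-unit cases must carry >= 1 criterion
  # to be cases at all; both conditionings use rejection sampling of the
  # severity score and criteria.
  sole <- units == 1L & stats::runif(n_case) < config$sole_transfusion_fraction
  need_criteria <- units == 0L | (units == 1L & !sole)
  repeat {
    bad <- which(need_criteria & rowSums(met) == 0)
    if (length(bad) == 0) break
    z[bad] <- stats::rnorm(length(bad))
    met[bad, ] <- draw_met(z[bad])
  }
  met[sole, ] <- FALSE
  dead <- if (n_case > 0) {
    copula_bernoulli(z, config$p_death_given_case, config$severity_loading)
  } else {
    logical(0)
  }
  d <- list(z = z, met = met, units = units)

  coh <- empty_cohort(n, case_id = sprintf("sim_%05d", seq_len(n)))
  case_rows <- which(is_case)
  for (id in names(prev)) {
    coh <- set_criterion_fields(coh, case_rows[d$met[, id]], id)
  }
  coh$blood_units_transfused[case_rows] <- as.integer(d$units)
  coh$outcome[case_rows[dead]] <- "dead"
  coh$pregnancy_timing[case_rows] <- "postpartum_42d"

  # Routine admission measurements on cases, where criteria left them unset.
  for (f in names(routine_defaults)) {
    fill <- case_rows[is.na(coh[[f]][case_rows])]
    coh[[f]][fill] <- routine_defaults[[f]]
  }

  # Missingness: mask routine fields, but never the evidence of a met
  # criterion.
  protected <- matrix(FALSE, n, ncol(coh), dimnames = list(NULL, names(coh)))
  for (id in names(prev)) {
    rows <- case_rows[d$met[, id]]
    protected[rows, criterion_evidence_fields(id)] <- TRUE
  }
  for (f in names(config$missingness_rates)) {
    mask <- stats::runif(n) < config$missingness_rates[[f]]
    mask <- mask & !protected[, f]
    coh[[f]][mask] <- NA
  }

  list(cohort = as_mnm_cohort(as.data.frame(coh)),
       denominators = denominators(n, max(n_live, 1L)),
       config = config)
}
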