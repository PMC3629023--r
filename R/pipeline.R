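# One-call orchestration of the full audit: classification, indicators,
# validity, elimination and the transfusion-threshold sweep, written as a
# deterministic report bundle.

#' Run the complete near-miss audit pipeline
#'
#' Classifies the cohort under a profile and writes a report bundle to
#' `out_dir`: `classification.csv` (label and met criteria per case),
#' `indicators.json`, `validity.json` (confusion table and metrics),
#' `elimination.tsv` (the stepwise elimination table) and, when the profile
#' includes the transfusion criterion, `sweep.csv`. Re-running with identical
#' inputs produces byte-identical files.
#'
#' @param cohort an `mnm_cohort`, or a path to a cohort CSV.
#' @param denom an `mnm_denominators`, or a path to a JSON sidecar.
#' @param profile profile name (`"WHO"`, `"WHO-clinical"`, `"Haydom"`),
#'   `mnm_profile`, or path to a profile JSON.
#' @param out_dir output directory (created if needed), or NULL to skip
#'   writing and just return the objects.
#' @param thresholds transfusion thresholds for the sweep.
#' @param ci_method,alpha interval settings.
#' @param registry criterion registry.
#' @return Invisibly, a list with `classification`, `indicators`,
#'   `validity`, `elimination` (NULL if no positive carries a criterion),
#'   `sweep` (NULL if no transfusion criterion) and `paths`.
#' @export
run_audit <- function(cohort, denom, profile = "Haydom", out_dir = NULL,
                      thresholds = c(1L, 2L, 5L),
                      ci_method = "wilson", alpha = 0.05,
                      registry = builtin_registry()) {
  if (is.character(cohort)) cohort <- read_cohort_csv(cohort)
  cohort <- as_mnm_cohort(as.data.frame(cohort))
  if (is.character(denom)) denom <- read_denominators(denom)
  if (is.character(profile)) {
    profile <- if (file.exists(profile)) read_profile(profile, registry)
               else audit_profile(profile)
  }
  profile <- validate_profile(profile, registry)

  cl <- classify_cohort(cohort, profile, registry)
  if (nrow(cohort) == 0) {
    warning("empty cohort: outputs will be empty")
  }
  ind <- compute_indicators(cl, denom, cohort)
  val <- profile_validity(cl, total_population = denom$n_deliveries,
                          ci_method = ci_method, alpha = alpha)
  elim <- NULL
  pos <- positive_cases(cl) & criteria_positive(cl)
  if (sum(pos) > 0 && all(criteria_positive(cl)[positive_cases(cl)])) {
    elim <- stepwise_elimination(cl$met[pos, , drop = FALSE])
  }
  sweep <- NULL
  if ("transfusion" %in% profile$included_criteria && nrow(cohort) > 0) {
    sweep <- transfusion_threshold_sweep(cohort, profile, denom, thresholds,
                                         registry, ci_method, alpha)
  }

  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)

    met_ids <- apply(cl$met, 1, function(r) {
      paste(colnames(cl$met)[r], collapse = ";")
    })
    cls_df <- data.frame(case_id = cl$case_id, outcome = cl$outcome,
                         label = as.character(cl$label),
                         met_criteria = if (nrow(cohort)) met_ids
                                        else character(0))
    utils::write.csv(cls_df, p("classification.csv"), row.names = FALSE)
    paths$classification <- p("classification.csv")

    jsonlite::write_json(list(
      schema_version = "1.0",
      profile = profile$profile_name,
      n_MNM = ind$n_MNM, n_MD = ind$n_MD, n_SMO = ind$n_SMO,
      smo_ratio_per_1000_livebirths = ind$smo_ratio_per_1000_livebirths,
      cfr_percent = ind$cfr_percent,
      per_criterion_counts = as.list(ind$per_criterion_counts),
      completeness = as.list(ind$completeness)
    ), p("indicators.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE,
       na = "null")
    paths$indicators <- p("indicators.json")

    jsonlite::write_json(list(
      schema_version = "1.0",
      profile = profile$profile_name,
      confusion = val$confusion[c("tp", "fp", "fn", "tn")],
      ci_method = attr(val$metrics, "ci_method"),
      alpha = attr(val$metrics, "alpha"),
      metrics = val$metrics
    ), p("validity.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE,
       na = "null")
    paths$validity <- p("validity.json")

    if (!is.null(elim)) {
      write_elimination_tsv(elim, p("elimination.tsv"))
      paths$elimination <- p("elimination.tsv")
    }
    if (!is.null(sweep)) {
      write_sweep_csv(sweep, p("sweep.csv"))
      paths$sweep <- p("sweep.csv")
    }
  }

  invisible(list(classification = cl, indicators = ind, validity = val,
                 elimination = elim, sweep = sweep, paths = paths))
}
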