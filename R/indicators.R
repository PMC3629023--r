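# Cohort-level audit indicators and the transfusion-threshold sweep.
#
# All ratios are kept at full precision; round_half_up() is applied only at
# presentation (print methods, exports), matching how audit reports print one
# decimal.

#' Compute cohort near-miss indicators
#'
#' Severe maternal outcome (SMO) = MNM + MD. The SMO ratio is expressed per
#' 1,000 live births; the case fatality rate (CFR, also called the mortality
#' index) is MD / SMO in percent.
#'
#' @param cl an `mnm_classification` from [classify_cohort()].
#' @param denom an `mnm_denominators` (see [denominators()]).
#' @param cohort the cohort the classification came from; when supplied, a
#'   field completeness report is included.
#' @return An `indicator_report`: list with `n_MNM`, `n_MD`, `n_SMO`,
#'   `smo_ratio_per_1000_livebirths`, `cfr_percent` (NA when there are no
#'   positives), `per_criterion_counts`, and `completeness` (or NULL).
#' @export
compute_indicators <- function(cl, denom, cohort = NULL) {
  stopifnot(inherits(cl, "mnm_classification"),
            inherits(denom, "mnm_denominators"))
  n_MD <- sum(cl$label == "MD")
  n_MNM <- sum(cl$label == "MNM")
  n_SMO <- n_MD + n_MNM
  structure(list(
    n_MNM = n_MNM,
    n_MD = n_MD,
    n_SMO = n_SMO,
    smo_ratio_per_1000_livebirths = 1000 * n_SMO / denom$n_live_births,
    cfr_percent = if (n_SMO == 0) NA_real_ else 100 * n_MD / n_SMO,
    per_criterion_counts = criterion_frequency_table(cl),
    completeness = if (is.null(cohort)) NULL else completeness_report(cohort),
    denominators = denom,
    profile_name = cl$profile_name
  ), class = "indicator_report")
}

#' @export
print.indicator_report <- function(x, ...) {
  cat(sprintf("Near-miss indicators (profile '%s')\n", x$profile_name))
  cat(sprintf("  deliveries %d, live births %d\n",
              x$denominators$n_deliveries, x$denominators$n_live_births))
  cat(sprintf("  MNM %d + MD %d = SMO %d\n", x$n_MNM, x$n_MD, x$n_SMO))
  cat(sprintf("  SMO ratio : %.1f per 1,000 live births\n",
              round_half_up(x$smo_ratio_per_1000_livebirths)))
  if (is.na(x$cfr_percent)) {
    cat("  CFR       : undefined (no positives)\n")
  } else {
    cat(sprintf("  CFR       : %.1f%%\n", round_half_up(x$cfr_percent)))
  }
  invisible(x)
}

#' Per-criterion frequency among positive cases
#'
#' Counts, over the severe-maternal-outcome cases (MNM + MD) only, how many
#' meet each criterion of the profile. A case increments every criterion it
#' meets, so the column totals can exceed the number of positives.
#'
#' @param cl an `mnm_classification`.
#' @return Named integer vector in profile criterion order.
#' @export
criterion_frequency_table <- function(cl) {
  stopifnot(inherits(cl, "mnm_classification"))
  pos <- positive_cases(cl)
  counts <- colSums(cl$met[pos, , drop = FALSE])
  stats::setNames(as.integer(counts), colnames(cl$met))
}

#' Data completeness per field
#'
#' Fraction of records in which each field is populated. In audit data the
#' denominators are usually the positive cases; pass the subset you want.
#'
#' @param cohort an `mnm_cohort` (or coercible data.frame).
#' @param fields which fields to report (default: every schema field except
#'   `case_id` and `outcome`, which are always present).
#' @return Named numeric vector of fractions in \[0, 1\].
#' @export
completeness_report <- function(cohort,
                                fields = setdiff(cohort_schema()$name,
                                                 c("case_id", "outcome"))) {
  cohort <- as_mnm_cohort(as.data.frame(cohort))
  vapply(cohort[fields], function(col) mean(!is.na(col)), numeric(1))
}

#' Sweep the blood-transfusion inclusion threshold
#'
#' Re-classifies the cohort with the transfusion criterion's threshold set to
#' each value in `thresholds`, and reports for each: the number of positives,
#' the number of sole-transfusion positives (cases whose only met criterion
#' is the transfusion of blood, evaluated against the full profile minus the
#' transfusion criterion), the CFR, and diagnostic validity against death
#' among all delivered women. A threshold equal to the profile's own value
#' reproduces the unmodified classification.
#'
#' @param cohort an `mnm_cohort`.
#' @param profile profile including the `transfusion` criterion.
#' @param denom an `mnm_denominators`; `n_deliveries` is the validity
#'   population.
#' @param thresholds ascending integer thresholds, all >= 1.
#' @param registry criterion registry.
#' @param ci_method,alpha interval settings for the validity metrics.
#' @return An `mnm_sweep` data.frame with one row per threshold:
#'   `threshold_units`, `n_positives`, `n_sole_transfusion`, `cfr_percent`,
#'   `sensitivity`, `specificity`, `ppv`, `npv` (unrounded percent), with the
#'   full `validity_metrics` objects in the `"validity"` attribute.
#' @export
transfusion_threshold_sweep <- function(cohort, profile, denom,
                                        thresholds = c(1L, 2L, 5L),
                                        registry = builtin_registry(),
                                        ci_method = "wilson", alpha = 0.05) {
  cohort <- as_mnm_cohort(as.data.frame(cohort))
  if (is.character(profile)) profile <- audit_profile(profile)
  profile <- validate_profile(profile, registry)
  stopifnot(inherits(denom, "mnm_denominators"))
  if (!"transfusion" %in% profile$included_criteria) {
    stop_mnm("profile '%s' does not include the transfusion criterion",
             profile$profile_name)
  }
  if (any(thresholds < 1) || is.unsorted(thresholds, strictly = TRUE)) {
    stop_mnm("thresholds must be >= 1 and strictly ascending")
  }
  rows <- list()
  validity <- list()
  for (t in thresholds) {
    pr <- profile_with_override(profile, "transfusion",
                                list(transfusion_threshold_units = t))
    cl <- classify_cohort(cohort, pr, registry)
    pos <- criteria_positive(cl)
    other <- rowSums(cl$met[, setdiff(colnames(cl$met), "transfusion"),
                            drop = FALSE]) > 0
    sole <- pos & cl$met[, "transfusion"] & !other
    death <- cl$outcome == "dead"
    n_smo <- sum(cl$label != "non_case")
    ct <- build_confusion(pos, death, denom$n_deliveries)
    vm <- validity_metrics(ct, ci_method, alpha)
    est <- stats::setNames(vm$estimate, vm$metric)
    rows[[length(rows) + 1]] <- data.frame(
      threshold_units = t,
      n_positives = sum(pos),
      n_sole_transfusion = sum(sole),
      cfr_percent = if (n_smo == 0) NA_real_ else 100 * sum(death) / n_smo,
      sensitivity = est[["sensitivity"]],
      specificity = est[["specificity"]],
      ppv = est[["ppv"]],
      npv = est[["npv"]]
    )
    validity[[as.character(t)]] <- list(confusion = ct, metrics = vm)
  }
  out <- do.call(rbind, rows)
  structure(out, validity = validity, profile_name = profile$profile_name,
            class = c("mnm_sweep", "data.frame"))
}

#' @export
print.mnm_sweep <- function(x, ...) {
  cat(sprintf("Transfusion threshold sweep (profile '%s')\n",
              attr(x, "profile_name")))
  y <- as.data.frame(x)
  for (col in c("cfr_percent", "sensitivity", "specificity", "ppv", "npv")) {
    y[[col]] <- round_half_up(y[[col]])
  }
  print(y, row.names = FALSE)
  invisible(x)
}

#' Export a sweep as CSV
#'
#' @param sweep an `mnm_sweep`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE, na = "")
  invisible(path)
}
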