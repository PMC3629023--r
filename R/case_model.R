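# Case-level domain model: the cohort data.frame schema and bit-exact CSV I/O.
#
# One row per woman. Fields are episode summaries abstracted from the chart
# (e.g. the lowest systolic pressure sustained for >= 60 min), not raw vitals
# streams. Missingness is first-class: an empty CSV cell means "not measured /
# not recorded", which is distinct from an observed FALSE. The single
# exception is blood_units_transfused, where a transfusion is an affirmative
# event and an empty cell means 0 units.

#' Cohort column schema
#'
#' The fixed, published column set for case-level maternal audit records.
#' Columns are snake_case identifiers with units embedded in the name; no
#' dialect auto-detection is performed so that files interchange bit-exactly.
#'
#' @return A data.frame with columns `name`, `type`
#'   (`character`/`numeric`/`integer`/`logical`) and `required`.
#' @export
cohort_schema <- function() {
  s <- function(name, type, required = FALSE) {
    data.frame(name = name, type = type, required = required)
  }
  rbind(
    s("case_id", "character", TRUE),
    s("outcome", "character", TRUE),       # "alive" | "dead"
    s("pregnancy_timing", "character"),    # pregnant | intrapartum | postpartum_42d
    s("sbp_min_sustained_mmHg", "numeric"),
    s("pulse_max_concurrent_bpm", "numeric"),
    s("fluids_given_L", "numeric"),
    s("resp_rate_extreme_per_min", "numeric"),
    s("temp_extreme_C", "numeric"),
    s("wbc_10e9_per_L", "numeric"),
    s("clinical_infection_sign", "logical"),
    s("unconscious_hours", "numeric"),
    s("gcs_min", "integer"),
    s("urine_output_mL_per_h_4h", "numeric"),
    s("urine_output_mL_24h", "numeric"),
    s("oliguria_refractory", "logical"),
    s("clot_formation_minutes", "numeric"),
    s("spo2_min_pct", "numeric"),
    s("spo2_low_duration_min", "numeric"),
    s("platelets_per_mL", "numeric"),
    s("hypertension", "logical"),
    s("proteinuria", "logical"),
    s("fits", "logical"),
    s("jaundice", "logical"),
    s("acute_cyanosis", "logical"),
    s("gasping", "logical"),
    s("cardiac_arrest", "logical"),
    s("stroke", "logical"),
    s("uncontrollable_fit", "logical"),
    s("uterine_rupture", "logical"),
    s("blood_units_transfused", "integer"),
    s("hysterectomy_infection_or_haemorrhage", "logical"),
    s("cpr_performed", "logical"),
    s("icu_admission", "logical"),
    s("dialysis", "logical"),
    s("continuous_vasoactive_drugs", "logical"),
    s("intubation_minutes", "numeric"),
    s("intubation_anaesthesia_related", "logical"),
    s("pao2_fio2_mmHg", "numeric"),
    s("creatinine_umol_L", "numeric"),
    s("bilirubin_umol_L", "numeric"),
    s("ph_arterial", "numeric"),
    s("lactate_mmol_L", "numeric"),
    s("ketoacids_urine", "logical")
  )
}

schema_types <- function() {
  sc <- cohort_schema()
  stats::setNames(sc$type, sc$name)
}

#' Create an empty cohort of a given size
#'
#' All optional fields are missing; `outcome` defaults to `"alive"` and
#' `blood_units_transfused` to 0, so the result is a valid cohort.
#'
#' @param n number of rows.
#' @param case_id optional character vector of identifiers (default
#'   `case_001` ...).
#' @return A validated cohort data.frame (class `mnm_cohort`).
#' @export
empty_cohort <- function(n, case_id = sprintf("case_%03d", seq_len(n))) {
  ty <- schema_types()
  cols <- lapply(ty, function(t) {
    switch(t,
      character = rep(NA_character_, n),
      numeric = rep(NA_real_, n),
      integer = rep(NA_integer_, n),
      logical = rep(NA, n)
    )
  })
  df <- as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
  names(df) <- names(ty)
  df$case_id <- as.character(case_id)
  df$outcome <- rep("alive", n)
  df$blood_units_transfused <- rep(0L, n)
  as_mnm_cohort(df)
}

#' Validate a data.frame as a maternal-case cohort
#'
#' Checks the column set against [cohort_schema()], coerces column types, and
#' enforces the record invariants: `outcome` present and one of
#' `alive`/`dead`; `blood_units_transfused` a non-negative integer (missing
#' treated as 0); `gcs_min` in 3..15; `spo2_min_pct` in 0..100; durations and
#' volumes non-negative.
#'
#' @param df a data.frame with the schema columns (any order).
#' @return `df` with columns in schema order, classed `mnm_cohort`.
#' @export
as_mnm_cohort <- function(df) {
  stopifnot(is.data.frame(df))
  ty <- schema_types()
  unknown <- setdiff(names(df), names(ty))
  if (length(unknown) > 0) {
    stop_mnm("unknown column(s): %s", paste(unknown, collapse = ", "))
  }
  missing_cols <- setdiff(names(ty), names(df))
  if (length(missing_cols) > 0) {
    stop_mnm("missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  df <- df[, names(ty), drop = FALSE]
  for (nm in names(ty)) {
    df[[nm]] <- switch(ty[[nm]],
      character = as.character(df[[nm]]),
      numeric = as.numeric(df[[nm]]),
      integer = as.integer(df[[nm]]),
      logical = as.logical(df[[nm]])
    )
  }
  bad <- is.na(df$outcome) | !(df$outcome %in% c("alive", "dead"))
  if (any(bad)) {
    stop_mnm("outcome must be 'alive' or 'dead' and never missing (row %d)",
             which(bad)[1], class = "mnm_validation_error")
  }
  df$blood_units_transfused[is.na(df$blood_units_transfused)] <- 0L
  if (any(df$blood_units_transfused < 0)) {
    stop_mnm("blood_units_transfused must be >= 0 (row %d)",
             which(df$blood_units_transfused < 0)[1],
             class = "mnm_validation_error")
  }
  chk_range <- function(col, lo, hi) {
    x <- df[[col]]
    bad <- !is.na(x) & (x < lo | x > hi)
    if (any(bad)) {
      stop_mnm("%s must be in [%s, %s] (row %d)", col, lo, hi, which(bad)[1],
               class = "mnm_validation_error")
    }
  }
  chk_range("gcs_min", 3, 15)
  chk_range("spo2_min_pct", 0, 100)
  for (col in c("unconscious_hours", "spo2_low_duration_min",
                "intubation_minutes", "clot_formation_minutes",
                "fluids_given_L", "urine_output_mL_per_h_4h",
                "urine_output_mL_24h")) {
    chk_range(col, 0, Inf)
  }
  class(df) <- c("mnm_cohort", "data.frame")
  df
}

#' Read a case-level cohort from CSV
#'
#' RFC 4180 CSV, UTF-8, header required. The header must contain exactly the
#' [cohort_schema()] columns (unknown columns are rejected). Empty cells map
#' to missing, except `blood_units_transfused` which defaults to 0. Booleans
#' are parsed from `{0, 1}`; numbers use the `.` decimal separator regardless
#' of locale.
#'
#' @param path file path.
#' @return An `mnm_cohort` data.frame, rows in file order.
#' @seealso [write_cohort_csv()]
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_mnm("file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL, fileEncoding = "UTF-8")
  ty <- schema_types()
  unknown <- setdiff(names(raw), names(ty))
  if (length(unknown) > 0) {
    stop_mnm("unknown column(s) in %s: %s", path,
             paste(unknown, collapse = ", "), class = "mnm_parse_error")
  }
  missing_cols <- setdiff(names(ty), names(raw))
  if (length(missing_cols) > 0) {
    stop_mnm("missing column(s) in %s: %s", path,
             paste(missing_cols, collapse = ", "), class = "mnm_parse_error")
  }
  n <- nrow(raw)
  parse_col <- function(nm) {
    x <- raw[[nm]]
    empty <- is.na(x) | x == ""
    out <- switch(ty[[nm]],
      character = {
        y <- x
        y[empty] <- NA_character_
        y
      },
      logical = {
        bad <- !empty & !(x %in% c("0", "1", "TRUE", "FALSE"))
        if (any(bad)) {
          stop_mnm("column '%s', row %d: cannot parse '%s' as 0/1",
                   nm, which(bad)[1], x[which(bad)[1]],
                   class = "mnm_parse_error")
        }
        y <- rep(NA, length(x))
        y[!empty] <- x[!empty] %in% c("1", "TRUE")
        y
      },
      integer = {
        bad <- !empty & !grepl("^-?[0-9]+$", x)
        if (any(bad)) {
          stop_mnm("column '%s', row %d: cannot parse '%s' as integer",
                   nm, which(bad)[1], x[which(bad)[1]],
                   class = "mnm_parse_error")
        }
        y <- rep(NA_integer_, length(x))
        y[!empty] <- as.integer(x[!empty])
        y
      },
      numeric = {
        y <- rep(NA_real_, length(x))
        suppressWarnings(v <- as.numeric(x[!empty]))
        bad <- is.na(v)
        if (any(bad)) {
          i <- which(!empty)[which(bad)[1]]
          stop_mnm("column '%s', row %d: cannot parse '%s' as number",
                   nm, i, x[i], class = "mnm_parse_error")
        }
        y[!empty] <- v
        y
      }
    )
    out
  }
  cols <- lapply(names(ty), parse_col)
  names(cols) <- names(ty)
  df <- if (n == 0) {
    empty_cohort(0)
  } else {
    as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
  }
  names(df) <- names(ty)
  as_mnm_cohort(df)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort_csv()]: missing values become empty cells, logicals
#' become `0`/`1`, and numerics are written with the shortest decimal
#' representation that parses back to the identical double, so a write/read
#' round trip reproduces every field bit-exactly.
#'
#' @param cohort an `mnm_cohort` (or coercible data.frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  cohort <- as_mnm_cohort(as.data.frame(cohort))
  ty <- schema_types()
  out <- cohort
  for (nm in names(ty)) {
    out[[nm]] <- switch(ty[[nm]],
      character = cohort[[nm]],
      logical = ifelse(is.na(cohort[[nm]]), NA_character_,
                       ifelse(cohort[[nm]], "1", "0")),
      integer = ifelse(is.na(cohort[[nm]]), NA_character_,
                       as.character(cohort[[nm]])),
      numeric = fmt_roundtrip(cohort[[nm]])
    )
  }
  class(out) <- "data.frame"
  char_cols <- which(cohort_schema()$type == "character")
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, na = "",
                     quote = char_cols, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_mnm("cannot write %s: %s", path, conditionMessage(ok))
  invisible(path)
}

#' Which fields are populated, per record
#'
#' @param cohort an `mnm_cohort`.
#' @return Logical matrix, rows = cases, columns = schema fields; TRUE where
#'   the field is populated (non-missing).
#' @export
populated_mask <- function(cohort) {
  cohort <- as_mnm_cohort(as.data.frame(cohort))
  m <- !vapply(cohort, is.na, logical(nrow(cohort)))
  if (nrow(cohort) == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(cohort)))
  rownames(m) <- cohort$case_id
  m
}

#' Read cohort denominators from a JSON sidecar
#'
#' @param path JSON file of the form
#'   `{"n_deliveries": int, "n_live_births": int}`.
#' @return A validated list with `n_deliveries` and `n_live_births`.
#' @export
read_denominators <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  denominators(x$n_deliveries, x$n_live_births)
}

#' Cohort denominators
#'
#' @param n_deliveries,n_live_births positive integers. Live births may exceed
#'   deliveries (multiple births).
#' @return A list of class `mnm_denominators`.
#' @export
denominators <- function(n_deliveries, n_live_births) {
  if (!is.numeric(n_deliveries) || length(n_deliveries) != 1 ||
      is.na(n_deliveries) || n_deliveries <= 0 ||
      n_deliveries != trunc(n_deliveries)) {
    stop_mnm("n_deliveries must be a positive integer")
  }
  if (!is.numeric(n_live_births) || length(n_live_births) != 1 ||
      is.na(n_live_births) || n_live_births <= 0 ||
      n_live_births != trunc(n_live_births)) {
    stop_mnm("n_live_births must be a positive integer")
  }
  structure(list(n_deliveries = as.integer(n_deliveries),
                 n_live_births = as.integer(n_live_births)),
            class = "mnm_denominators")
}
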