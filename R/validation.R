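# Diagnostic validity of a criteria profile against maternal death.
#
# The criteria set is treated as a diagnostic test, the condition is death,
# and the population is every woman who delivered during the study period.
# Women with no recorded event are test-negative survivors: build_confusion()
# inflates the true-negative cell by (total_population - cases supplied).

#' Build a 2x2 confusion table against maternal death
#'
#' @param test_positive logical vector: case meets >= 1 profile criterion.
#' @param death logical vector, aligned with `test_positive`.
#' @param total_population total number of delivered women; must be at least
#'   `length(test_positive)`. The surplus is added to the true-negative cell.
#' @return A `confusion_table`: list with integer `tp`, `fp`, `fn`, `tn`.
#' @export
build_confusion <- function(test_positive, death,
                            total_population = length(test_positive)) {
  stopifnot(is.logical(test_positive), is.logical(death),
            length(test_positive) == length(death),
            !anyNA(test_positive), !anyNA(death))
  if (total_population < length(test_positive)) {
    stop_mnm("total_population (%d) < number of supplied cases (%d)",
             total_population, length(test_positive))
  }
  confusion_table(
    tp = sum(test_positive & death),
    fp = sum(test_positive & !death),
    fn = sum(!test_positive & death),
    tn = sum(!test_positive & !death) +
      (total_population - length(test_positive))
  )
}

#' @rdname build_confusion
#' @param tp,fp,fn,tn non-negative cell counts.
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop_mnm("confusion table cells must be non-negative")
  }
  structure(as.list(as.integer(cells)) |> stats::setNames(names(cells)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$tp + x$fp, x$fn, x$tn, x$fn + x$tn,
                x$tp + x$fn, x$fp + x$tn, x$tp + x$fp + x$fn + x$tn),
              3, 3, byrow = TRUE,
              dimnames = list(c("test +", "test -", "total"),
                              c("death", "no death", "total")))
  print(m)
  invisible(x)
}

#' Binomial proportion confidence interval (percent scale)
#'
#' Wilson score interval by default; Wald and Clopper-Pearson (exact) are
#' selectable. Bounds are reported in percent and clipped to \[0, 100\] (only
#' the Wald interval can exceed the range; Wilson and Clopper-Pearson lie
#' inside it by construction).
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials, `n > 0`.
#' @param method `"wilson"`, `"wald"` or `"clopper_pearson"`.
#' @param alpha two-sided error rate (default 0.05 for a 95\% interval).
#' @return Numeric vector `c(lower, upper)` in percent.
#' @export
binomial_ci <- function(k, n, method = c("wilson", "wald", "clopper_pearson"),
                        alpha = 0.05) {
  method <- match.arg(method)
  if (n <= 0) stop_mnm("n must be > 0")
  if (k < 0 || k > n) stop_mnm("k must be in [0, n]")
  p <- k / n
  ci <- switch(method,
    wilson = {
      z <- stats::qnorm(1 - alpha / 2)
      denom <- 1 + z^2 / n
      centre <- (p + z^2 / (2 * n)) / denom
      half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
      c(centre - half, centre + half)
    },
    wald = {
      z <- stats::qnorm(1 - alpha / 2)
      half <- z * sqrt(p * (1 - p) / n)
      c(p - half, p + half)
    },
    clopper_pearson = {
      lo <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
      hi <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
      c(lo, hi)
    }
  )
  100 * pmin(pmax(ci, 0), 1)
}

#' Sensitivity, specificity and predictive values with confidence intervals
#'
#' Point estimates in percent: sensitivity = 100 tp/(tp+fn), specificity =
#' 100 tn/(tn+fp), PPV = 100 tp/(tp+fp), NPV = 100 tn/(tn+fn). A metric whose
#' denominator is zero is reported as missing rather than 0.
#'
#' @param ct a `confusion_table`.
#' @param ci_method interval method passed to [binomial_ci()].
#' @param alpha two-sided error rate for the intervals.
#' @return A `validity_metrics` object: data.frame with one row per metric
#'   (`estimate`, `lower`, `upper`, all percent) plus `ci_method` and `alpha`
#'   attributes.
#' @export
validity_metrics <- function(ct, ci_method = c("wilson", "wald",
                                               "clopper_pearson"),
                             alpha = 0.05) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(ct, "confusion_table"))
  one <- function(k, n) {
    if (n == 0) return(c(NA_real_, NA_real_, NA_real_))
    c(100 * k / n, binomial_ci(k, n, ci_method, alpha))
  }
  m <- rbind(sensitivity = one(ct$tp, ct$tp + ct$fn),
             specificity = one(ct$tn, ct$tn + ct$fp),
             ppv = one(ct$tp, ct$tp + ct$fp),
             npv = one(ct$tn, ct$tn + ct$fn))
  out <- data.frame(metric = rownames(m), estimate = m[, 1],
                    lower = m[, 2], upper = m[, 3], row.names = NULL)
  structure(out, ci_method = ci_method, alpha = alpha,
            class = c("validity_metrics", "data.frame"))
}

#' @export
print.validity_metrics <- function(x, ...) {
  cat(sprintf("Diagnostic validity (%d%% CI, %s)\n",
              round(100 * (1 - attr(x, "alpha"))), attr(x, "ci_method")))
  for (i in seq_len(nrow(x))) {
    if (is.na(x$estimate[i])) {
      cat(sprintf("  %-11s : undefined (zero denominator)\n", x$metric[i]))
    } else {
      cat(sprintf("  %-11s : %5.1f%%  [%.1f%%-%.1f%%]\n", x$metric[i],
                  round_half_up(x$estimate[i]), round_half_up(x$lower[i]),
                  round_half_up(x$upper[i])))
    }
  }
  invisible(x)
}

#' Validity of a classified cohort against death
#'
#' Convenience wrapper: test = meets >= 1 profile criterion, condition =
#' death, with non-case delivered women counted as test-negative survivors.
#'
#' @param cl an `mnm_classification`.
#' @param total_population all women delivered in the period (defaults to the
#'   classified cases only).
#' @inheritParams validity_metrics
#' @return List with `confusion` and `metrics`.
#' @export
profile_validity <- function(cl, total_population = length(cl$case_id),
                             ci_method = "wilson", alpha = 0.05) {
  ct <- build_confusion(criteria_positive(cl), cl$outcome == "dead",
                        total_population)
  list(confusion = ct,
       metrics = validity_metrics(ct, ci_method, alpha))
}
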