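# Greedy stepwise elimination of inclusion criteria.
#
# The audit's refinement procedure: rank criteria by frequency of use among
# the included cases, exclude the most frequent one, remove (temporarily) all
# cases carrying it, recompute frequencies among the remainder, and repeat
# until no cases are left. Criteria selected while still covering >= 1 case
# contribute independently to case identification; criteria whose remaining
# count hits zero before they are ever selected only fire alongside more
# frequent ones (passive); criteria never met at all are unused.
#
# The procedure depends only on the per-step frequency marginals, never on
# within-step co-occurrence beyond the selected criterion — which is why a
# case x criterion matrix reconstructed from printed step marginals replays
# the published trace exactly.

#' Build / validate a case-by-criterion incidence matrix
#'
#' @param x logical matrix (cases in rows, criteria in columns) with
#'   dimnames, or an `mnm_classification` whose positive cases are taken.
#' @return A validated logical matrix of class `incidence_matrix`. Rows with
#'   no met criterion are rejected: every included case must carry at least
#'   one criterion.
#' @export
as_incidence_matrix <- function(x) {
  if (inherits(x, "mnm_classification")) {
    keep <- positive_cases(x) & criteria_positive(x)
    dropped <- sum(positive_cases(x)) - sum(keep)
    if (dropped > 0) {
      stop_mnm("%d positive case(s) meet no criterion; cannot build incidence matrix",
               dropped)
    }
    x <- x$met[keep, , drop = FALSE]
  }
  stopifnot(is.matrix(x), is.logical(x))
  if (anyNA(x)) stop_mnm("incidence matrix must not contain NA")
  if (is.null(colnames(x))) {
    colnames(x) <- sprintf("criterion_%02d", seq_len(ncol(x)))
  }
  if (is.null(rownames(x))) {
    rownames(x) <- sprintf("case_%03d", seq_len(nrow(x)))
  }
  zero <- rowSums(x) == 0
  if (any(zero)) {
    stop_mnm("case '%s' meets no criterion (all-zero row)",
             rownames(x)[which(zero)[1]])
  }
  structure(x, class = c("incidence_matrix", class(x)))
}

# Selection rule: maximum remaining frequency; ties broken first by the
# frequency in the original full cohort, then by column order.
select_top <- function(freq, full_counts) {
  ord <- order(-freq, -full_counts, seq_along(freq))
  ord[1]
}

#' Stepwise elimination of criteria by frequency of use
#'
#' @param m an `incidence_matrix` (see [as_incidence_matrix()]).
#' @return An `elimination_trace`: list with
#' \describe{
#'   \item{steps}{one entry per exclusion step: `step_index`,
#'     `selected_criterion`, `cases_removed`, `remaining_before`,
#'     `remaining_after`, and `frequency_snapshot` (counts among the cases
#'     remaining before the step);}
#'   \item{independent}{data.frame of criteria selected with count >= 1, in
#'     selection order, with the number of cases each removed;}
#'   \item{passive}{criteria met somewhere in the full cohort whose remaining
#'     count reached 0 before selection;}
#'   \item{unused}{criteria never met in the full cohort.}
#' }
#' The removed-case counts over all steps sum to the number of cases
#' (each case is removed exactly once, by the first selected criterion it
#' carries).
#' @export
stepwise_elimination <- function(m) {
  m <- as_incidence_matrix(unclass(m))
  full_counts <- colSums(m)
  remaining <- rep(TRUE, nrow(m))
  steps <- list()
  selected <- character()
  while (any(remaining)) {
    freq <- colSums(m[remaining, , drop = FALSE])
    freq[colnames(m) %in% selected] <- -1L   # never reselect
    j <- select_top(freq, full_counts)
    id <- colnames(m)[j]
    hit <- remaining & m[, j]
    steps[[length(steps) + 1]] <- list(
      step_index = length(steps) + 1L,
      selected_criterion = id,
      cases_removed = sum(hit),
      remaining_before = sum(remaining),
      remaining_after = sum(remaining) - sum(hit),
      frequency_snapshot = {
        s <- colSums(m[remaining, , drop = FALSE])
        s[colnames(m) %in% selected] <- 0L
        stats::setNames(as.integer(s), colnames(m))
      }
    )
    selected <- c(selected, id)
    remaining <- remaining & !hit
  }
  counts <- vapply(steps, `[[`, numeric(1), "cases_removed")
  independent <- data.frame(
    criterion = vapply(steps, `[[`, character(1), "selected_criterion"),
    count = as.integer(counts),
    step = seq_along(steps)
  )
  passive <- setdiff(colnames(m)[full_counts > 0], independent$criterion)
  unused <- colnames(m)[full_counts == 0]
  structure(list(steps = steps, independent = independent,
                 passive = passive, unused = unused,
                 criterion_ids = colnames(m),
                 full_counts = stats::setNames(as.integer(full_counts),
                                               colnames(m)),
                 n_cases = nrow(m)),
            class = "elimination_trace")
}

#' @export
print.elimination_trace <- function(x, ...) {
  cat(sprintf("<elimination_trace> %d cases, %d criteria, %d steps\n",
              x$n_cases, length(x$criterion_ids), length(x$steps)))
  for (s in x$steps) {
    cat(sprintf("  step %2d: %-24s removed %2d of %2d -> %2d remain\n",
                s$step_index, s$selected_criterion, s$cases_removed,
                s$remaining_before, s$remaining_after))
  }
  if (length(x$passive)) {
    cat("  passive:", paste(x$passive, collapse = ", "), "\n")
  }
  if (length(x$unused)) {
    cat("  unused :", paste(x$unused, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Partition criteria into independent and passive contributors
#'
#' @param trace an `elimination_trace`.
#' @return List with `independent` (data.frame: criterion, count, step),
#'   `passive` and `unused` (character vectors).
#' @export
independent_contribution <- function(trace) {
  stopifnot(inherits(trace, "elimination_trace"))
  list(independent = trace$independent, passive = trace$passive,
       unused = trace$unused)
}

#' Per-step frequency marginals of a trace
#'
#' Column `before_step_1` holds full-cohort counts; column `before_step_k`
#' the counts among cases remaining before step k (already-selected criteria
#' shown as 0); the final column is all zero.
#'
#' @param trace an `elimination_trace`.
#' @return An `elimination_marginals`: list with `counts` (criteria x
#'   steps+1 integer matrix) and `selected` (criterion per step).
#' @export
step_marginals <- function(trace) {
  stopifnot(inherits(trace, "elimination_trace"))
  K <- length(trace$steps)
  counts <- matrix(0L, length(trace$criterion_ids), K + 1,
                   dimnames = list(trace$criterion_ids,
                                   c(sprintf("before_step_%d", seq_len(K)),
                                     "final")))
  for (k in seq_len(K)) {
    counts[, k] <- trace$steps[[k]]$frequency_snapshot[trace$criterion_ids]
  }
  structure(list(counts = counts,
                 selected = vapply(trace$steps, `[[`, character(1),
                                   "selected_criterion")),
            class = "elimination_marginals")
}

#' Reconstruct an incidence matrix from per-step marginals
#'
#' Builds *a* case-by-criterion matrix whose stepwise elimination reproduces
#' the given marginals exactly. Only the marginals are identified by a
#' published elimination table; the within-step co-occurrence is
#' under-determined, and this function fixes it canonically: the cases
#' removed at step k all carry the step-k selected criterion, and for every
#' other criterion the count drop between steps gives how many of those cases
#' also carry it — assigned first-fit to the lowest-indexed cases of the
#' block. The elimination trace is invariant to this choice because the
#' procedure only ever looks at frequency marginals.
#'
#' @param marginals an `elimination_marginals` (or a list with `counts` and
#'   `selected` shaped like [step_marginals()] output; `NA` counts are read
#'   as 0, mirroring the dashes of a printed table).
#' @return An `incidence_matrix`.
#' @export
reconstruct_from_marginals <- function(marginals) {
  counts <- marginals$counts
  selected <- marginals$selected
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            length(selected) == ncol(counts) - 1,
            all(selected %in% rownames(counts)))
  counts[is.na(counts)] <- 0L
  crit <- rownames(counts)
  K <- length(selected)
  blocks <- list()
  for (k in seq_len(K)) {
    removed <- counts[selected[k], k]
    if (removed <= 0) {
      stop_mnm("step %d selects '%s' with count %d (must be >= 1)",
               k, selected[k], removed)
    }
    delta <- counts[, k] - counts[, k + 1]
    if (any(delta < 0)) {
      stop_mnm("count of '%s' increases at step %d",
               crit[which(delta < 0)[1]], k)
    }
    if (any(delta > removed)) {
      stop_mnm("count drop of '%s' at step %d (%d) exceeds cases removed (%d)",
               crit[which(delta > removed)[1]], k,
               delta[which(delta > removed)[1]], removed)
    }
    if (delta[selected[k]] != removed || counts[selected[k], k + 1] != 0) {
      stop_mnm("selected criterion '%s' must drop to 0 at step %d",
               selected[k], k)
    }
    later <- counts[selected[k], -seq_len(k)]
    if (any(later != 0)) {
      stop_mnm("'%s' reappears after its selection at step %d", selected[k], k)
    }
    block <- matrix(FALSE, removed, length(crit),
                    dimnames = list(NULL, crit))
    for (c_id in crit) {
      d <- delta[c_id]
      if (d > 0) block[seq_len(d), c_id] <- TRUE
    }
    block[, selected[k]] <- TRUE
    blocks[[k]] <- block
  }
  if (any(counts[, K + 1] != 0)) {
    stop_mnm("final column must be all zero ('%s' is not)",
             crit[which(counts[, K + 1] != 0)[1]])
  }
  m <- do.call(rbind, blocks)
  rownames(m) <- sprintf("case_%03d", seq_len(nrow(m)))
  as_incidence_matrix(m)
}

#' Export an elimination trace as a step table
#'
#' Mirrors the published layout: one row per criterion, one column per step
#' with the count among remaining cases (blank once a criterion is gone,
#' `EXCL` at the step where it is selected), plus the full-cohort column.
#'
#' @param trace an `elimination_trace`.
#' @return A character data.frame (criterion x columns).
#' @export
elimination_table <- function(trace) {
  stopifnot(inherits(trace, "elimination_trace"))
  K <- length(trace$steps)
  ids <- trace$criterion_ids
  sel <- vapply(trace$steps, `[[`, character(1), "selected_criterion")
  cols <- list(criterion = ids)
  fmt_col <- function(k) {
    # counts among cases remaining BEFORE step k+1 (i.e. after step k);
    # k = 0 is the full cohort.
    snap <- if (k < K) {
      trace$steps[[k + 1]]$frequency_snapshot[ids]
    } else {
      stats::setNames(integer(length(ids)), ids)
    }
    n_rem <- if (k == 0) trace$n_cases else trace$steps[[k]]$remaining_after
    out <- character(length(ids))
    for (i in seq_along(ids)) {
      id <- ids[i]
      sel_step <- match(id, sel)
      if (!is.na(sel_step) && k >= sel_step) {
        out[i] <- if (k == sel_step) "EXCL" else "-"
      } else if (snap[id] == 0) {
        out[i] <- "-"
      } else {
        out[i] <- sprintf("%d (%.1f%%)", snap[id],
                          round_half_up(100 * snap[id] / n_rem))
      }
    }
    out
  }
  cols[["full_cohort"]] <- fmt_col(0)
  for (k in seq_len(K)) {
    cols[[sprintf("step_%d_n%d", k, trace$steps[[k]]$remaining_after)]] <-
      fmt_col(k)
  }
  as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname elimination_table
#' @param path output path for a tab-separated export.
#' @export
write_elimination_tsv <- function(trace, path) {
  utils::write.table(elimination_table(trace), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
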