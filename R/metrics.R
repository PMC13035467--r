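#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes number of successes.
#' @param n number of trials (>= 1).
#' @param level two-sided confidence level.
#' @return Numeric vector `c(lower, upper)`, both in [0, 1] and bracketing
#'   the point estimate `successes/n`.
#' @export
wilson_ci <- function(successes, n, level = 0.95) {
  if (n < 1) stop("wilson_ci: undefined for n = 0", call. = FALSE)
  if (successes < 0 || successes > n) {
    stop("wilson_ci: successes must lie in [0, n]", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Performance summary from aggregate screening counts
#'
#' Lower-level constructor behind [summary.workflow_result()]; useful for
#' summarising published count tables directly. Conventions: CDR is detected
#' cancers per 1,000 screens; sensitivity uses the reference-standard cancer
#' count (cancers confirmed within the study); specificity uses
#' `n - reference_cancers` as denominator; PPV is detected cancers over
#' recalls and is `NA` (flagged undefined) when there are no recalls.
#'
#' @param n episodes screened.
#' @param recalls episodes recalled.
#' @param detected_cancers cancers detected (recalled and confirmed).
#' @param reference_cancers reference-standard confirmed cancers.
#' @param reads_by_role optional named vector of read counts.
#' @param baseline_total_reads optional routine-workflow read total, enabling
#'   `workload_savings`.
#' @param level confidence level for the Wilson intervals.
#' @return Object of class `performance_summary`.
#' @export
performance_summary <- function(n, recalls, detected_cancers,
                                reference_cancers,
                                reads_by_role = NULL,
                                baseline_total_reads = NULL,
                                level = 0.95) {
  stopifnot(n >= 1, recalls >= 0, detected_cancers >= 0,
            reference_cancers >= detected_cancers, recalls <= n)
  true_neg <- (n - reference_cancers) - (recalls - detected_cancers)
  est <- list(
    cdr_per_1000 = 1000 * detected_cancers / n,
    recall_rate = recalls / n,
    sensitivity = detected_cancers / reference_cancers,
    specificity = true_neg / (n - reference_cancers),
    ppv = if (recalls > 0) detected_cancers / recalls else NA_real_
  )
  ci <- list(
    cdr_per_1000 = 1000 * wilson_ci(detected_cancers, n, level),
    recall_rate = wilson_ci(recalls, n, level),
    sensitivity = wilson_ci(detected_cancers, reference_cancers, level),
    specificity = wilson_ci(true_neg, n - reference_cancers, level),
    ppv = if (recalls > 0) wilson_ci(detected_cancers, recalls, level) else
      c(lower = NA_real_, upper = NA_real_)
  )
  total_reads <- if (!is.null(reads_by_role)) sum(reads_by_role) else NA_real_
  savings <- if (!is.null(baseline_total_reads) && !is.null(reads_by_role)) {
    (baseline_total_reads - total_reads) / baseline_total_reads
  } else NA_real_
  structure(list(n = n, recalls = recalls,
                 detected_cancers = detected_cancers,
                 reference_cancers = reference_cancers,
                 estimates = est, ci = ci, level = level,
                 reads_by_role = reads_by_role, total_reads = total_reads,
                 workload_savings_vs_routine = savings),
            class = "performance_summary")
}

#' Summarise a workflow result
#'
#' Computes CDR, recall rate, sensitivity, specificity and PPV with 95%
#' Wilson confidence intervals, plus the reads-by-role workload ledger and,
#' when a baseline is given, the workload saving against it.
#'
#' @param object [apply_workflow()] result.
#' @param reference_cancers reference-standard cancer count; defaults to the
#'   cohort's confirmed cancers.
#' @param baseline optional routine [apply_workflow()] result on the same
#'   cohort.
#' @param level confidence level.
#' @param ... unused.
#' @return A [performance_summary()].
#' @export
summary.workflow_result <- function(object, reference_cancers = NULL,
                                    baseline = NULL, level = 0.95, ...) {
  ct <- object$counts
  if (is.null(reference_cancers)) reference_cancers <- ct$n_cancer
  if (reference_cancers < ct$detected_cancers) {
    stop("reference_cancers must be at least the detected cancer count",
         call. = FALSE)
  }
  performance_summary(
    n = ct$n, recalls = ct$recalls, detected_cancers = ct$detected_cancers,
    reference_cancers = reference_cancers, reads_by_role = ct$reads_by_role,
    baseline_total_reads = if (!is.null(baseline)) baseline$counts$total_reads,
    level = level)
}

#' @export
print.performance_summary <- function(x, ...) {
  fmt <- function(nm, scale = 100, unit = "%") {
    e <- x$estimates[[nm]]; ci <- x$ci[[nm]]
    if (is.na(e)) return(sprintf("  %-13s undefined\n", nm))
    sprintf("  %-13s %6.1f%s  (%s CI %.1f-%.1f)\n", nm, e * scale, unit,
            paste0(round(x$level * 100), "%"), ci[[1]] * scale, ci[[2]] * scale)
  }
  cat(sprintf("Screening performance on n = %d (reference cancers = %d)\n",
              x$n, x$reference_cancers))
  cat(sprintf("  %-13s %6.1f per 1,000  (CI %.1f-%.1f)\n", "cdr",
              x$estimates$cdr_per_1000, x$ci$cdr_per_1000[[1]],
              x$ci$cdr_per_1000[[2]]))
  cat(fmt("recall_rate"), fmt("sensitivity"), fmt("specificity"), fmt("ppv"),
      sep = "")
  if (!is.null(x$reads_by_role)) {
    cat(sprintf("  total reads   %d", x$total_reads))
    if (!is.na(x$workload_savings_vs_routine)) {
      cat(sprintf("  (workload saving vs routine %.1f%%)",
                  100 * x$workload_savings_vs_routine))
    }
    cat("\n")
  }
  invisible(x)
}

#' Relative workload saving of a workflow against a baseline
#'
#' Workload is the sum of examinations read by reader 1, reader 2 and the
#' arbitration reader, plus additionally arbitrated examinations multiplied
#' by the panel size. Positive values are savings.
#'
#' @param result,baseline [apply_workflow()] results on the same cohort.
#' @return Signed fraction `(baseline - result) / baseline`.
#' @export
workload_savings <- function(result, baseline) {
  if (result$counts$n != baseline$counts$n) {
    stop("workload_savings: results come from different cohorts", call. = FALSE)
  }
  base <- baseline$counts$total_reads
  if (base == 0) stop("workload_savings: baseline has zero reads", call. = FALSE)
  (base - result$counts$total_reads) / base
}

#' Tabulate additional-review outcomes by review-time band
#'
#' For an additional-read workflow, counts reviewed episodes, panel recalls
#' and cancers per review-time band, with the reporting conventions of the
#' study tables: band share as % of all reviewed, recalls as % of the band's
#' reviews, cancers as % of the band's recalls.
#'
#' @param result [apply_workflow()] result of a workflow with an
#'   additional-read component.
#' @param cohort the cohort it was applied to.
#' @return data.frame with one row per band.
#' @export
time_category_table <- function(result, cohort) {
  out <- result$outcomes
  stopifnot(nrow(out) == nrow(cohort))
  flagged <- out$reads_additional_arbitration > 0
  bands <- c("t0_30", "t30_60", "t60_120", "t120_300", "unrecorded")
  band <- factor(cohort$review_time_category, levels = bands)
  recalled <- flagged & out$final_decision == "recall"
  cancer_rec <- recalled & cohort$cancer
  reviewed_n <- as.integer(table(band[flagged]))
  recalled_n <- as.integer(table(band[recalled]))
  cancers_n <- as.integer(table(band[cancer_rec]))
  data.frame(
    band = bands,
    n_reviewed = reviewed_n,
    pct_of_reviewed = if (sum(reviewed_n) > 0) {
      100 * reviewed_n / sum(reviewed_n)
    } else rep(0, length(bands)),
    n_recalled = recalled_n,
    pct_recalled_of_band = ifelse(reviewed_n > 0,
                                  100 * recalled_n / reviewed_n, 0),
    n_cancers = cancers_n,
    pct_cancers_of_recalls = ifelse(recalled_n > 0,
                                    100 * cancers_n / recalled_n, 0),
    stringsAsFactors = FALSE
  )
}

#' Chi-squared test for trend in proportions across ordered bands
#'
#' Cochran-Armitage trend test of recall proportion across ordered
#' review-time bands (scores 1..k). The `unrecorded` band must be excluded
#' by the caller before testing.
#'
#' @param recalled integer vector of recalls per band.
#' @param reviewed integer vector of reviews per band (all > 0).
#' @return List with `statistic` (chi-squared, 1 df) and `p.value`
#'   (two-sided). All-zero recalls return `p = 1` by convention.
#' @export
trend_test <- function(recalled, reviewed) {
  stopifnot(length(recalled) == length(reviewed), length(reviewed) >= 2,
            all(reviewed > 0), all(recalled >= 0), all(recalled <= reviewed))
  if (sum(recalled) == 0 || all(recalled == reviewed)) {
    return(list(statistic = 0, p.value = 1))
  }
  tt <- suppressWarnings(stats::prop.trend.test(recalled, reviewed,
                                                score = seq_along(recalled)))
  list(statistic = unname(tt$statistic), p.value = tt$p.value)
}

#' Chi-squared comparison of two independent proportions
#'
#' Yates-corrected chi-squared test of `k1/n1` versus `k2/n2`, with Fisher's
#' exact test available as an option.
#'
#' @param k1,n1,k2,n2 successes and totals of the two groups.
#' @param exact use Fisher's exact test instead.
#' @return The two-sided p-value.
#' @export
two_proportion_test <- function(k1, n1, k2, n2, exact = FALSE) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  if (exact) {
    m <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
    return(stats::fisher.test(m)$p.value)
  }
  if (k1 == k2 && n1 == n2) return(1)
  suppressWarnings(stats::prop.test(c(k1, k2), c(n1, n2), correct = TRUE)$p.value)
}
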