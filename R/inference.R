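.metric_keys <- c("cdr", "recall_rate", "sensitivity", "specificity", "ppv")
.metric_labels <- c(CDR = "cdr", RR = "recall_rate", SEN = "sensitivity",
                    SPEC = "specificity", PPV = "ppv")
.metric_directions <- c(cdr = "higher_better", sensitivity = "higher_better",
                        specificity = "higher_better", ppv = "higher_better",
                        recall_rate = "lower_better")

#' Settings for the comparative bootstrap inference
#'
#' Defaults follow the study's analysis plan: 50,000 bootstrap repetitions,
#' two-sided 90% percentile confidence intervals for metric ratios, a
#' relative non-inferiority margin of 0.1 at one-sided alpha 0.05, and a
#' superiority test at alpha 0.1 (both decisions read off a single bound of
#' the same two-sided 90% CI, so the triplet is internally consistent).
#'
#' @param n_boot bootstrap repetitions.
#' @param ci_level two-sided level of the percentile interval.
#' @param ni_margin relative non-inferiority margin.
#' @param ni_alpha one-sided alpha of the non-inferiority test.
#' @param sup_alpha alpha of the superiority test.
#' @param seed integer seed for the bootstrap stream.
#' @param metric_directions named map of metric to `higher_better` /
#'   `lower_better`.
#' @return Object of class `inference_config`.
#' @export
inference_config <- function(n_boot = 50000L, ci_level = 0.90,
                             ni_margin = 0.1, ni_alpha = 0.05,
                             sup_alpha = 0.1, seed = 1L,
                             metric_directions = .metric_directions) {
  stopifnot(n_boot >= 2, ci_level > 0, ci_level < 1,
            ni_margin > 0, ni_margin < 1, ni_alpha > 0, ni_alpha < 1,
            sup_alpha > 0, sup_alpha < 1)
  if (abs((1 - ci_level) / 2 - ni_alpha) > 1e-8) {
    warning("ci_level and ni_alpha are inconsistent: the one-sided ",
            "non-inferiority decision reads the lower bound of the two-sided ",
            "interval", call. = FALSE)
  }
  structure(list(n_boot = as.integer(n_boot), ci_level = ci_level,
                 ni_margin = ni_margin, ni_alpha = ni_alpha,
                 sup_alpha = sup_alpha, seed = as.integer(seed),
                 metric_directions = metric_directions),
            class = "inference_config")
}

# Collapse per-episode paired outcomes (workflow recall, routine recall,
# cancer) into multinomial cells. Because workflow application is
# deterministic per episode, resampling episodes with replacement is exactly
# equivalent to drawing the cell counts from a multinomial, which makes
# 50,000-replicate bootstraps cheap.
.outcome_cells <- function(cohort, spec, ops, panel = NULL) {
  res_w <- apply_workflow(cohort, spec, ops, panel)
  res_r <- apply_workflow(cohort, workflow_spec("routine"), ops)
  rec_w <- res_w$outcomes$final_decision == "recall"
  rec_r <- res_r$outcomes$final_decision == "recall"
  cancer <- cohort$cancer
  code <- 4L * rec_w + 2L * rec_r + cancer + 1L
  counts <- tabulate(code, nbins = 8L)
  keep <- counts > 0L
  grid <- expand.grid(cancer = c(FALSE, TRUE), rec_r = c(FALSE, TRUE),
                      rec_w = c(FALSE, TRUE))
  list(profiles = grid[keep, c("rec_w", "rec_r", "cancer")],
       counts = counts[keep], n = nrow(cohort),
       result_workflow = res_w, result_routine = res_r)
}

# Ratios of one metric across bootstrap cell-count replicates. C is a
# cells x n_boot count matrix.
.ratio_from_cells <- function(C, pr, metric) {
  cs <- function(w) as.numeric(w %*% C)
  det_w <- cs(as.numeric(pr$rec_w & pr$cancer))
  det_r <- cs(as.numeric(pr$rec_r & pr$cancer))
  switch(metric,
    cdr = ,
    sensitivity = det_w / det_r,
    recall_rate = cs(as.numeric(pr$rec_w)) / cs(as.numeric(pr$rec_r)),
    specificity = cs(as.numeric(!pr$rec_w & !pr$cancer)) /
                  cs(as.numeric(!pr$rec_r & !pr$cancer)),
    ppv = det_w * cs(as.numeric(pr$rec_r)) /
          (det_r * cs(as.numeric(pr$rec_w))),
    stop("unknown metric: ", metric, call. = FALSE))
}

# Draw bootstrap ratios for several metrics from one paired resampling
# stream; degenerate replicates (zero denominator for any requested metric)
# are dropped and redrawn.
.boot_ratios <- function(cells, metrics, n_boot) {
  prob <- cells$counts / cells$n
  draw <- function(k) matrix(stats::rmultinom(k, cells$n, prob),
                             nrow = length(prob))
  C <- draw(n_boot)
  ratios <- sapply(metrics, function(m) .ratio_from_cells(C, cells$profiles, m))
  ratios <- matrix(ratios, ncol = length(metrics),
                   dimnames = list(NULL, metrics))
  n_redrawn <- 0L
  for (i in seq_len(100L)) {
    bad <- !apply(is.finite(ratios), 1L, all)
    if (!any(bad)) break
    n_redrawn <- n_redrawn + sum(bad)
    C2 <- draw(sum(bad))
    ratios[bad, ] <- sapply(metrics, function(m)
      .ratio_from_cells(C2, cells$profiles, m))
  }
  if (any(!apply(is.finite(ratios), 1L, all))) {
    stop("bootstrap degenerate: could not draw non-degenerate replicates",
         call. = FALSE)
  }
  attr(ratios, "n_redrawn") <- n_redrawn
  ratios
}

.point_ratio <- function(cells, metric) {
  C1 <- matrix(cells$counts, ncol = 1)
  r <- .ratio_from_cells(C1, cells$profiles, metric)
  if (!is.finite(r)) {
    stop("metric denominator is zero in the full sample for ", metric,
         call. = FALSE)
  }
  r
}

#' Paired bootstrap ratio confidence interval for a workflow metric
#'
#' Resamples episodes with replacement; within each replicate the same
#' resample indexes both the AI workflow and routine double reading (recorded
#' panel outcomes travel with their episodes), so the ratio is computed on
#' genuinely paired re-applications. The two-sided percentile interval at
#' `cfg$ci_level` is returned. A fixed seed reproduces the interval exactly.
#'
#' @param cohort validated evaluation [cohort_table()].
#' @param spec [workflow_spec()] to compare against routine.
#' @param metric one of `cdr`, `recall_rate`, `sensitivity`, `specificity`,
#'   `ppv`.
#' @param cfg [inference_config()].
#' @param ops [operating_points()].
#' @param panel optional panel decision provider (see [apply_workflow()]).
#' @return List with `point`, `lower`, `upper`, `metric`, and `n_redrawn`
#'   (degenerate replicates that were redrawn).
#' @export
bootstrap_ratio_ci <- function(cohort, spec, metric, cfg = inference_config(),
                               ops, panel = NULL) {
  metric <- match.arg(metric, .metric_keys)
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  cells <- .outcome_cells(cohort, spec, ops, panel)
  point <- .point_ratio(cells, metric)
  set.seed(cfg$seed)
  ratios <- .boot_ratios(cells, metric, cfg$n_boot)
  alpha <- (1 - cfg$ci_level) / 2
  qs <- stats::quantile(ratios[, 1], c(alpha, 1 - alpha), type = 6,
                        names = FALSE)
  list(point = point, lower = qs[1], upper = qs[2], metric = metric,
       n_redrawn = attr(ratios, "n_redrawn"))
}

#' Non-inferiority verdict from a ratio confidence interval
#'
#' For higher-is-better metrics the workflow is non-inferior when the lower
#' CI bound of the workflow/routine ratio exceeds `1 - margin`; for
#' lower-is-better metrics when the upper bound is below `1 + margin`.
#'
#' @param ci list or vector with `lower` and `upper` bounds.
#' @param direction `"higher_better"` or `"lower_better"`.
#' @param margin relative margin.
#' @return `TRUE` if non-inferiority is established.
#' @export
noninferiority_verdict <- function(ci, direction, margin = 0.1) {
  direction <- match.arg(direction, c("higher_better", "lower_better"))
  if (direction == "higher_better") ci$lower > 1 - margin
  else ci$upper < 1 + margin
}

#' Superiority verdict from a ratio confidence interval
#'
#' Higher-is-better: lower bound above 1; lower-is-better: upper bound
#' below 1.
#'
#' @inheritParams noninferiority_verdict
#' @return `TRUE` if superiority is established.
#' @export
superiority_verdict <- function(ci, direction) {
  direction <- match.arg(direction, c("higher_better", "lower_better"))
  if (direction == "higher_better") ci$lower > 1 else ci$upper < 1
}

#' The a-priori gating table for combination workflows
#'
#' Maps each of the ten combination workflows to its ordered list of five
#' metric labels (CDR, RR, SEN, SPEC, PPV). Ships as an editable YAML file.
#'
#' @param path optional alternative YAML path.
#' @return Named list of character vectors, class `gating_table`.
#' @export
gating_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "gating.yaml", package = "screenflow",
                        mustWork = TRUE)
  }
  tab <- yaml::read_yaml(path)
  if (length(tab) != 10L) {
    stop("gating table must list exactly the 10 combination workflows",
         call. = FALSE)
  }
  for (nm in names(tab)) {
    if (!setequal(tab[[nm]], names(.metric_labels)) ||
        length(tab[[nm]]) != 5L) {
      stop("gating order for ", nm, " must be a permutation of ",
           paste(names(.metric_labels), collapse = ", "), call. = FALSE)
    }
  }
  structure(tab, class = "gating_table")
}

#' Run the gated non-inferiority/superiority comparison for one workflow
#'
#' Evaluates the five metric ratios (workflow vs routine) in the workflow's
#' a-priori gating order. All intervals come from one paired bootstrap pass.
#' Each metric is tested for non-inferiority; the first failure makes every
#' later metric exploratory (still computed and reported). Superiority is
#' only evaluated where non-inferiority passed on that metric.
#'
#' @param cohort validated evaluation [cohort_table()].
#' @param spec a combination [workflow_spec()] present in the gating table.
#' @param gating [gating_table()].
#' @param cfg [inference_config()].
#' @param ops [operating_points()].
#' @param panel optional panel decision provider.
#' @return Object of class `gated_comparison`: a per-metric data.frame
#'   (`table`) plus the spec and settings.
#' @export
run_gated_comparison <- function(cohort, spec, gating = gating_table(),
                                 cfg = inference_config(), ops, panel = NULL) {
  if (!spec$name %in% names(gating)) {
    stop("workflow ", spec$name, " is not in the gating table (only ",
         "combination workflows receive gated verdicts)", call. = FALSE)
  }
  order_labels <- gating[[spec$name]]
  metrics <- unname(.metric_labels[order_labels])
  cells <- .outcome_cells(cohort, spec, ops, panel)
  points <- vapply(metrics, function(m) .point_ratio(cells, m), numeric(1))
  set.seed(cfg$seed)
  ratios <- .boot_ratios(cells, metrics, cfg$n_boot)
  alpha <- (1 - cfg$ci_level) / 2
  rows <- vector("list", length(metrics))
  failed_before <- FALSE
  for (i in seq_along(metrics)) {
    m <- metrics[i]
    qs <- stats::quantile(ratios[, m], c(alpha, 1 - alpha), type = 6,
                          names = FALSE)
    ci <- list(lower = qs[1], upper = qs[2])
    dirn <- cfg$metric_directions[[m]]
    ni <- noninferiority_verdict(ci, dirn, cfg$ni_margin)
    sup <- if (ni) superiority_verdict(ci, dirn) else NA
    status <- if (failed_before) "exploratory" else "confirmatory"
    verdict <- if (status == "exploratory") "exploratory"
               else if (!ni) "inferior"
               else if (isTRUE(sup)) "superior" else "noninferior"
    rows[[i]] <- data.frame(
      order = i, label = order_labels[i], metric = m,
      point_ratio = points[[m]], lower = ci$lower, upper = ci$upper,
      noninferior = ni, superior = sup, status = status, verdict = verdict,
      stringsAsFactors = FALSE)
    if (!ni) failed_before <- TRUE
  }
  structure(list(workflow = spec$name, spec = spec,
                 table = do.call(rbind, rows), cfg = cfg,
                 n_redrawn = attr(ratios, "n_redrawn")),
            class = "gated_comparison")
}

#' @export
print.gated_comparison <- function(x, ...) {
  cat("Gated comparison:", x$workflow, "vs routine double reading\n")
  cat(sprintf("  %d bootstrap repetitions, %d%% percentile CIs, margin %.2f\n",
              x$cfg$n_boot, round(100 * x$cfg$ci_level), x$cfg$ni_margin))
  tb <- x$table
  for (i in seq_len(nrow(tb))) {
    cat(sprintf("  %d. %-4s ratio %.3f (%.3f-%.3f)  %s [%s]\n", tb$order[i],
                tb$label[i], tb$point_ratio[i], tb$lower[i], tb$upper[i],
                tb$verdict[i], tb$status[i]))
  }
  invisible(x)
}
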