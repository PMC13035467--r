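.op_labels <- c("OP1", "OP2", "OP3", "OP4")
.wf_modes <- c("routine", "additional_read", "triage", "triage_negatives",
               "triage_plus_additional", "trineg_plus_additional")

#' Operating-point threshold set
#'
#' Vendor-style decision thresholds on the AI malignancy score. OP1 is the
#' most specific (highest threshold) and OP4 the most sensitive; thresholds
#' must be strictly inside (0,1) and non-increasing from OP1 to OP4. A score
#' greater than or equal to the threshold counts as an AI recall.
#'
#' @param ... named thresholds, e.g. `OP1 = 0.6, OP2 = 0.4`; labels must be
#'   among OP1..OP4.
#' @return Object of class `operating_points` (named numeric vector).
#' @export
operating_points <- function(...) {
  thr <- unlist(list(...))
  if (length(thr) == 0L || is.null(names(thr)) ||
      !all(names(thr) %in% .op_labels)) {
    stop("operating_points: thresholds must be named OP1..OP4", call. = FALSE)
  }
  thr <- thr[intersect(.op_labels, names(thr))]
  if (any(thr <= 0 | thr >= 1)) {
    stop("operating-point thresholds must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  if (is.unsorted(rev(thr))) {
    stop("thresholds must be non-increasing from OP1 (most specific) to OP4 ",
         "(most sensitive)", call. = FALSE)
  }
  structure(thr, class = "operating_points")
}

#' @export
print.operating_points <- function(x, ...) {
  cat("Operating points (score >= threshold recalls):\n")
  for (nm in names(x)) cat(sprintf("  %s: %.6f\n", nm, x[[nm]]))
  invisible(x)
}

#' Look up one operating-point threshold
#' @param ops [operating_points()].
#' @param op label, e.g. `"OP2"`.
#' @return The threshold (numeric scalar).
#' @export
op_threshold <- function(ops, op) {
  stopifnot(inherits(ops, "operating_points"))
  if (!op %in% names(ops)) {
    stop("operating point ", op, " not present in threshold set", call. = FALSE)
  }
  unname(ops[[op]])
}

#' Specify one AI reading workflow configuration
#'
#' @param mode one of `routine`, `additional_read`, `triage`,
#'   `triage_negatives`, `triage_plus_additional`, `trineg_plus_additional`.
#' @param op_triage operating-point label for the triage component; required
#'   iff the mode involves triage.
#' @param op_additional operating-point label for the additional-read
#'   component; required iff the mode involves the additional read.
#' @param n_arbiters panel size (1-3) charged per additionally arbitrated
#'   episode.
#' @return Object of class `workflow_spec`.
#' @export
workflow_spec <- function(mode, op_triage = NULL, op_additional = NULL,
                          n_arbiters = 1L) {
  if (!mode %in% .wf_modes) {
    stop("unknown workflow mode: ", mode, call. = FALSE)
  }
  needs_triage <- mode %in% c("triage", "triage_negatives",
                              "triage_plus_additional", "trineg_plus_additional")
  needs_add <- mode %in% c("additional_read", "triage_plus_additional",
                           "trineg_plus_additional")
  if (needs_triage != !is.null(op_triage)) {
    stop("op_triage must be supplied iff the mode involves triage", call. = FALSE)
  }
  if (needs_add != !is.null(op_additional)) {
    stop("op_additional must be supplied iff the mode involves the additional read",
         call. = FALSE)
  }
  if (!n_arbiters %in% 1:3) stop("n_arbiters must be 1, 2 or 3", call. = FALSE)
  for (op in c(op_triage, op_additional)) {
    if (!op %in% .op_labels) stop("unknown operating point label: ", op, call. = FALSE)
  }
  spec <- structure(list(mode = mode, op_triage = op_triage,
                         op_additional = op_additional,
                         n_arbiters = as.integer(n_arbiters)),
                    class = "workflow_spec")
  spec$name <- .spec_name(spec)
  spec
}

.spec_name <- function(spec) {
  switch(spec$mode,
    routine = "routine",
    additional_read = paste0("addread_", spec$op_additional),
    triage = paste0("triage_", spec$op_triage),
    triage_negatives = paste0("trineg_", spec$op_triage),
    triage_plus_additional = paste0("triage_", spec$op_triage,
                                    "_plus_addread_", spec$op_additional),
    trineg_plus_additional = paste0("trineg_", spec$op_triage,
                                    "_plus_addread_", spec$op_additional))
}

#' @export
print.workflow_spec <- function(x, ...) {
  cat("Workflow:", x$name, "(mode", x$mode, "")
  if (!is.null(x$op_triage)) cat("| triage", x$op_triage, "")
  if (!is.null(x$op_additional)) cat("| additional read", x$op_additional, "")
  cat("| arbiters", x$n_arbiters, ")\n")
  invisible(x)
}

#' The catalogue of the 17 evaluated AI workflows
#'
#' Enumerates the full set of non-routine configurations: two AI
#' additional-read workflows (OP1, OP2), two triage workflows (OP1, OP2),
#' three triage-negatives workflows (OP2-OP4), six triage-negatives +
#' additional-read combinations and four triage + additional-read
#' combinations. The catalogue ships as a YAML file under `extdata` and can
#' be edited or replaced.
#'
#' @param n_arbiters panel size applied to every spec.
#' @param path optional path to an alternative catalogue YAML.
#' @return Named list of 17 [workflow_spec()] objects.
#' @export
workflow_catalogue <- function(n_arbiters = 1L, path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "workflows.yaml", package = "screenflow",
                        mustWork = TRUE)
  }
  entries <- yaml::read_yaml(path)
  specs <- lapply(entries, function(e) {
    workflow_spec(e$mode, op_triage = e$op_triage,
                  op_additional = e$op_additional, n_arbiters = n_arbiters)
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(names(specs))) {
    stop("workflow catalogue contains duplicate configurations", call. = FALSE)
  }
  specs
}

#' Does the AI recall an episode at a given operating point?
#'
#' A score exactly equal to the threshold counts as a recall.
#'
#' @param e episode data.frame (one or more rows of a [cohort_table()]).
#' @param op operating-point label.
#' @param ops [operating_points()].
#' @return Logical vector, one element per episode.
#' @export
ai_recalls <- function(e, op, ops) {
  if (any(!e$ai_eligible)) {
    stop("ai_recalls: episode(s) not AI-eligible: ",
         paste(utils::head(e$episode_id[!e$ai_eligible], 5L), collapse = ", "),
         call. = FALSE)
  }
  e$ai_score >= op_threshold(ops, op)
}

#' Routine double-reading decision for episodes
#'
#' Recall iff both readers recall, or the readers disagree and the arbiter
#' recalls. Reads charged: reader 1 and reader 2 always, arbitration for
#' discordant pairs only.
#'
#' @param e episode data.frame (one or more rows).
#' @return data.frame with `episode_id`, `final_decision`, `detected_cancer`
#'   and per-role read counts.
#' @export
routine_decision <- function(e) {
  discord <- e$r1_opinion != e$r2_opinion
  if (any(discord & e$arbitration_opinion == "not_applicable")) {
    stop("routine_decision: discordant episode(s) lack an arbitration opinion",
         call. = FALSE)
  }
  rr <- .routine_recall(e)
  data.frame(
    episode_id = e$episode_id,
    final_decision = ifelse(rr, "recall", "no_recall"),
    detected_cancer = e$cancer & rr,
    reads_r1 = 1L,
    reads_r2 = 1L,
    reads_arbitration = as.integer(discord),
    reads_additional_arbitration = 0L,
    stringsAsFactors = FALSE
  )
}

#' Panel decision provider for simulated additional arbitration
#'
#' Returns a function that, given a cohort, produces one deterministic
#' simulated panel recall decision per episode (used only where no live
#' panel outcome was recorded). Decisions are a seeded Bernoulli draw with
#' status-specific recall probabilities, fixed per episode so that repeated
#' workflow applications and bootstrap resamples see the same decision.
#'
#' @param recall_given_cancer,recall_given_benign recall probabilities.
#' @param seed integer seed.
#' @return Function `cohort -> logical vector`.
#' @export
make_panel_provider <- function(recall_given_cancer = 0.99,
                                recall_given_benign = 0.033,
                                seed = 1L) {
  force(recall_given_cancer); force(recall_given_benign); force(seed)
  function(cohort) {
    set.seed(seed)
    u <- stats::runif(nrow(cohort))
    u < ifelse(cohort$cancer, recall_given_cancer, recall_given_benign)
  }
}

#' Apply one AI workflow configuration to a cohort
#'
#' Deterministically replays the configured reading pathway for every
#' episode and returns per-episode final decisions plus a reads-by-role
#' ledger:
#'
#' * `routine`: standard double reading with arbitration.
#' * `additional_read`: routine first; episodes finally not recalled whose
#'   AI score clears `op_additional` are additionally arbitrated
#'   (`n_arbiters` reads) and take the panel decision.
#' * `triage`: the AI stands in for reader 2 whenever it agrees with reader
#'   1 (on recall or no-recall) at `op_triage`; disagreements get a human
#'   second read and the usual arbitration pathway.
#' * `triage_negatives`: the AI stands in for reader 2 only when both it and
#'   reader 1 say no-recall; everything else follows the routine pathway.
#' * combinations: the triage component first, then the additional-read rule
#'   applied to every episode whose resulting decision is no-recall.
#'
#' Recorded live panel outcomes travel with their episodes; episodes flagged
#' only under a simulated operating point (no recorded outcome) take the
#' `panel` provider's decision, and their count is reported in the result
#' provenance.
#'
#' @param cohort validated [cohort_table()]; must be all AI-eligible unless
#'   `spec$mode == "routine"`.
#' @param spec [workflow_spec()].
#' @param ops [operating_points()].
#' @param panel either `NULL` (recorded outcomes only), a logical vector of
#'   fallback decisions, or a provider function from [make_panel_provider()].
#' @return Object of class `workflow_result`: `spec`, per-episode `outcomes`,
#'   aggregate `counts`, and `provenance`.
#' @export
apply_workflow <- function(cohort, spec, ops, panel = NULL) {
  stopifnot(inherits(spec, "workflow_spec"))
  n <- nrow(cohort)
  if (spec$mode != "routine" && any(!cohort$ai_eligible)) {
    stop("apply_workflow: AI workflows require an all-eligible evaluation ",
         "cohort; run build_evaluation_cohort() first", call. = FALSE)
  }
  out <- routine_decision(cohort)
  final <- out$final_decision == "recall"
  single_read <- rep(FALSE, n)

  if (spec$mode %in% c("triage", "triage_plus_additional")) {
    ai_t <- ai_recalls(cohort, spec$op_triage, ops)
    r1 <- cohort$r1_opinion == "recall"
    single_read <- ai_t == r1
    final[single_read] <- r1[single_read]
  } else if (spec$mode %in% c("triage_negatives", "trineg_plus_additional")) {
    ai_t <- ai_recalls(cohort, spec$op_triage, ops)
    r1 <- cohort$r1_opinion == "recall"
    single_read <- !r1 & !ai_t
    final[single_read] <- FALSE
  }
  out$reads_r2[single_read] <- 0L
  out$reads_arbitration[single_read] <- 0L

  n_simulated <- 0L
  if (spec$mode %in% c("additional_read", "triage_plus_additional",
                       "trineg_plus_additional")) {
    flagged <- !final & ai_recalls(cohort, spec$op_additional, ops)
    recorded <- cohort$panel_opinion != "not_applicable"
    decision <- rep(NA, n)
    decision[recorded] <- cohort$panel_opinion[recorded] == "recall"
    need_sim <- flagged & !recorded
    if (any(need_sim)) {
      if (is.null(panel)) {
        stop("apply_workflow: ", sum(need_sim), " flagged episode(s) have no ",
             "recorded panel outcome and no panel provider was supplied",
             call. = FALSE)
      }
      sim <- if (is.function(panel)) panel(cohort) else panel
      stopifnot(length(sim) == n)
      decision[need_sim] <- sim[need_sim]
      n_simulated <- sum(need_sim)
    }
    final[flagged] <- decision[flagged]
    out$reads_additional_arbitration[flagged] <- spec$n_arbiters
  }

  out$final_decision <- ifelse(final, "recall", "no_recall")
  out$detected_cancer <- cohort$cancer & final
  res <- structure(list(spec = spec, outcomes = out,
                        counts = .aggregate_outcomes(out, cohort),
                        provenance = list(n_panel_simulated = n_simulated)),
                   class = "workflow_result")
  res
}

.aggregate_outcomes <- function(out, cohort) {
  recall <- out$final_decision == "recall"
  reads <- c(r1 = sum(out$reads_r1), r2 = sum(out$reads_r2),
             arbitration = sum(out$reads_arbitration),
             additional_arbitration = sum(out$reads_additional_arbitration))
  list(n = nrow(out),
       n_cancer = sum(cohort$cancer),
       recalls = sum(recall),
       detected_cancers = sum(out$detected_cancer),
       true_positives = sum(out$detected_cancer),
       false_positives = sum(recall & !cohort$cancer),
       true_negatives = sum(!recall & !cohort$cancer),
       false_negatives = sum(!recall & cohort$cancer),
       reads_by_role = reads,
       total_reads = sum(reads))
}

#' @export
print.workflow_result <- function(x, ...) {
  ct <- x$counts
  cat("Workflow result:", x$spec$name, "\n")
  cat(sprintf("  n = %d | recalls = %d | detected cancers = %d/%d | total reads = %d\n",
              ct$n, ct$recalls, ct$detected_cancers, ct$n_cancer, ct$total_reads))
  cat(sprintf("  reads by role: r1 %d, r2 %d, arbitration %d, additional arbitration %d\n",
              ct$reads_by_role[["r1"]], ct$reads_by_role[["r2"]],
              ct$reads_by_role[["arbitration"]],
              ct$reads_by_role[["additional_arbitration"]]))
  if (x$provenance$n_panel_simulated > 0) {
    cat("  note:", x$provenance$n_panel_simulated,
        "panel decisions were simulated (no recorded outcome)\n")
  }
  invisible(x)
}
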