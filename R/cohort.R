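#' @keywords internal
"_PACKAGE"

# Canonical categorical vocabularies for the episode table. Spellings are
# lower snake case; readers normalise case-insensitively.
.opinion_levels <- c("recall", "no_recall")
.arb_levels <- c("recall", "no_recall", "not_applicable")
.time_levels <- c("t0_30", "t30_60", "t60_120", "t120_300", "unrecorded",
                  "not_applicable")
.channel_levels <- c("routine", "ai_additional", "none")
.exclusion_stages <- c("opt_out", "technical_recall", "not_sent_to_ai",
                       "ai_ineligible")
.excl_levels <- c("none", .exclusion_stages)

.episode_columns <- c("episode_id", "age_years", "r1_opinion", "r2_opinion",
                      "arbitration_opinion", "ai_eligible", "ai_score",
                      "panel_opinion", "review_time_category", "cancer",
                      "detection_channel", "excluded_reason")

#' Construct a cohort table of screening episodes
#'
#' A cohort table holds one row per screened woman (one screening episode):
#' the two human reader opinions, the arbitration opinion for discordant
#' pairs, the AI malignancy score and eligibility flag, the live
#' additional-arbitration panel outcome with its review-time band, the
#' confirmed-cancer status, the derived detection channel and any exclusion
#' reason. All invariants are checked on construction.
#'
#' @param episodes data.frame with exactly the episode columns (see
#'   [episode_columns()]).
#' @param provenance named list of free-form metadata (source, seed,
#'   generator parameters).
#' @return An object of class `cohort_table` (a validated data.frame).
#' @export
cohort_table <- function(episodes, provenance = list()) {
  episodes <- as.data.frame(episodes, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.episode_columns, names(episodes))
  extra_cols <- setdiff(names(episodes), .episode_columns)
  if (length(missing_cols) || length(extra_cols)) {
    stop("episode table schema error; missing: [",
         paste(missing_cols, collapse = ", "), "]; unexpected: [",
         paste(extra_cols, collapse = ", "), "]", call. = FALSE)
  }
  episodes <- episodes[, .episode_columns]
  rownames(episodes) <- NULL
  structure(episodes, provenance = provenance,
            class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("Screening cohort: ", nrow(x), " episodes (",
      sum(x$cancer), " confirmed cancers, ",
      sum(x$excluded_reason != "none"), " marked for exclusion)\n", sep = "")
  if (length(prov$source)) cat("Source:", prov$source, "\n")
  invisible(x)
}

#' Episode table column names
#' @return Character vector of the canonical column names, in file order.
#' @export
episode_columns <- function() .episode_columns

# Routine double-reading final decision, as a logical vector: recall iff both
# readers recall, or the readers disagree and the arbiter recalls.
.routine_recall <- function(x) {
  r1 <- x$r1_opinion == "recall"
  r2 <- x$r2_opinion == "recall"
  (r1 & r2) | ((r1 != r2) & x$arbitration_opinion == "recall")
}

.fail_rows <- function(bad, x, rule) {
  if (any(bad)) {
    ids <- utils::head(x$episode_id[bad], 5L)
    stop("cohort validation error [", rule, "] for episode(s): ",
         paste(ids, collapse = ", "),
         if (sum(bad) > 5L) sprintf(" (and %d more)", sum(bad) - 5L) else "",
         call. = FALSE)
  }
}

#' Validate a cohort table
#'
#' Checks every row-wise episode invariant: category membership, unique ids,
#' age at least 50, arbitration present exactly for discordant reader pairs,
#' AI score present exactly for AI-eligible episodes, panel outcomes only for
#' routine non-recalls of AI-eligible episodes, review-time bands only for
#' panel-reviewed episodes, and consistency of the derived detection channel.
#'
#' @param x cohort_table or compatible data.frame.
#' @return `x`, invisibly, if valid; otherwise an error naming the episode
#'   ids and the violated rule.
#' @export
validate_cohort <- function(x) {
  if (!inherits(x, "cohort_table")) x <- cohort_table(x)
  if (nrow(x) == 0L) return(invisible(x))
  .fail_rows(is.na(x$episode_id) | duplicated(x$episode_id), x,
             "episode_id must be unique and non-missing")
  .fail_rows(is.na(x$age_years) | x$age_years < 50 | x$age_years != round(x$age_years),
             x, "age_years must be an integer >= 50")
  .fail_rows(!x$r1_opinion %in% .opinion_levels, x, "r1_opinion category")
  .fail_rows(!x$r2_opinion %in% .opinion_levels, x, "r2_opinion category")
  .fail_rows(!x$arbitration_opinion %in% .arb_levels, x, "arbitration_opinion category")
  .fail_rows(!x$panel_opinion %in% .arb_levels, x, "panel_opinion category")
  .fail_rows(!x$review_time_category %in% .time_levels, x, "review_time_category category")
  .fail_rows(!x$detection_channel %in% .channel_levels, x, "detection_channel category")
  .fail_rows(!x$excluded_reason %in% .excl_levels, x, "excluded_reason category")
  .fail_rows(is.na(x$ai_eligible) | is.na(x$cancer), x,
             "ai_eligible and cancer must be TRUE/FALSE")

  discord <- x$r1_opinion != x$r2_opinion
  .fail_rows((x$arbitration_opinion != "not_applicable") != discord, x,
             "arbitration_opinion present iff readers disagree")
  .fail_rows(is.na(x$ai_score) & x$ai_eligible, x,
             "ai_score required for AI-eligible episodes")
  .fail_rows(!is.na(x$ai_score) & !x$ai_eligible, x,
             "ai_score must be absent for AI-ineligible episodes")
  .fail_rows(!is.na(x$ai_score) & (x$ai_score < 0 | x$ai_score > 1), x,
             "ai_score must lie in [0, 1]")

  rr <- .routine_recall(x)
  has_panel <- x$panel_opinion != "not_applicable"
  .fail_rows(has_panel & (rr | !x$ai_eligible), x,
             "panel_opinion only for AI-eligible routine non-recalls")
  .fail_rows((x$review_time_category != "not_applicable") & !has_panel, x,
             "review_time_category only for panel-reviewed episodes")

  expected_channel <- ifelse(x$cancer & rr, "routine",
                      ifelse(x$cancer & !rr & x$panel_opinion == "recall",
                             "ai_additional", "none"))
  .fail_rows(x$detection_channel != expected_channel, x,
             "detection_channel inconsistent with decisions and cancer status")
  invisible(x)
}

.sep_for <- function(path) if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","

#' Read an episode table from CSV/TSV
#'
#' The file must carry exactly the canonical header (see
#' [episode_columns()]); categorical tokens are accepted case-insensitively
#' and normalised to lower snake case. `not_applicable` is an explicit token;
#' the only permitted empty cell is `ai_score` for AI-ineligible episodes.
#'
#' @param path file path; `.tsv` selects tab separation, anything else comma.
#' @param schema_version schema label, currently only `"1"`.
#' @return A validated [cohort_table()].
#' @export
read_cohort <- function(path, schema_version = "1") {
  if (!identical(schema_version, "1")) {
    stop("unknown episode-table schema version: ", schema_version, call. = FALSE)
  }
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = .sep_for(path), header = TRUE,
                           colClasses = "character", na.strings = NULL,
                           quote = "\"", stringsAsFactors = FALSE,
                           check.names = FALSE)
  missing_cols <- setdiff(.episode_columns, names(raw))
  extra_cols <- setdiff(names(raw), .episode_columns)
  if (length(missing_cols) || length(extra_cols)) {
    stop("episode table schema error; missing: [",
         paste(missing_cols, collapse = ", "), "]; unexpected: [",
         paste(extra_cols, collapse = ", "), "]", call. = FALSE)
  }
  norm <- function(v) tolower(trimws(v))
  out <- data.frame(
    episode_id = trimws(raw$episode_id),
    age_years = as.numeric(raw$age_years),
    r1_opinion = norm(raw$r1_opinion),
    r2_opinion = norm(raw$r2_opinion),
    arbitration_opinion = norm(raw$arbitration_opinion),
    ai_eligible = norm(raw$ai_eligible) %in% c("true", "t", "1"),
    ai_score = suppressWarnings(as.numeric(ifelse(trimws(raw$ai_score) == "",
                                                  NA, raw$ai_score))),
    panel_opinion = norm(raw$panel_opinion),
    review_time_category = norm(raw$review_time_category),
    cancer = norm(raw$cancer) %in% c("true", "t", "1"),
    detection_channel = norm(raw$detection_channel),
    excluded_reason = norm(raw$excluded_reason),
    stringsAsFactors = FALSE
  )
  bad_bool <- !norm(raw$ai_eligible) %in% c("true", "t", "1", "false", "f", "0") |
    !norm(raw$cancer) %in% c("true", "t", "1", "false", "f", "0")
  if (any(bad_bool)) {
    stop("cohort validation error [ai_eligible/cancer must be boolean] for episode(s): ",
         paste(utils::head(out$episode_id[bad_bool], 5L), collapse = ", "),
         call. = FALSE)
  }
  x <- cohort_table(out, provenance = list(source = path))
  validate_cohort(x)
  x
}

#' Write an episode table to CSV/TSV
#'
#' Output is byte-stable for a given cohort: fixed column order, unquoted
#' tokens, `ai_score` rendered with 17 significant digits so that reading the
#' file back reproduces every field exactly.
#'
#' @param cohort a valid [cohort_table()].
#' @param path destination path; `.tsv` selects tab separation.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  out <- as.data.frame(cohort)
  out$ai_score <- ifelse(is.na(out$ai_score), "",
                         vapply(out$ai_score, function(s)
                           if (is.na(s)) "" else format(s, digits = 17, trim = TRUE),
                           character(1)))
  out$ai_eligible <- ifelse(cohort$ai_eligible, "true", "false")
  out$cancer <- ifelse(cohort$cancer, "true", "false")
  ok <- tryCatch({
    utils::write.table(out, path, sep = .sep_for(path), quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write cohort to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Filter screening attendees down to the evaluation cohort
#'
#' Applies the study-flow exclusions in fixed order (opt-out, technical
#' recall, not sent to the AI, AI-ineligible) and reports the count removed
#' at each stage. Each episode is counted at most once, at the first stage
#' that applies; when a per-episode `flags` table is supplied the
#' `excluded_reason` column is (re)derived under that precedence, otherwise
#' the stored `excluded_reason` is taken as already encoding the first
#' applicable stage.
#'
#' @param attendees [cohort_table()] of all screening attendees.
#' @param flags optional data.frame of logicals with one column per exclusion
#'   stage (`opt_out`, `technical_recall`, `not_sent_to_ai`, `ai_ineligible`)
#'   and one row per attendee.
#' @return List with `cohort` (episodes retained for evaluation) and
#'   `exclusions` (named integer vector of per-stage counts, in stage order).
#' @export
build_evaluation_cohort <- function(attendees, flags = NULL) {
  stopifnot(inherits(attendees, "cohort_table"))
  x <- as.data.frame(attendees)
  if (!is.null(flags)) {
    stopifnot(nrow(flags) == nrow(x), all(.exclusion_stages %in% names(flags)))
    reason <- rep("none", nrow(x))
    for (stage in rev(.exclusion_stages)) {           # earlier stages overwrite
      reason[as.logical(flags[[stage]])] <- stage
    }
    x$excluded_reason <- reason
  }
  counts <- vapply(.exclusion_stages, function(stage)
    sum(x$excluded_reason == stage), integer(1))
  kept <- x[x$excluded_reason == "none", , drop = FALSE]
  prov <- attr(attendees, "provenance")
  prov$exclusions <- as.list(counts)
  list(cohort = cohort_table(kept, provenance = prov), exclusions = counts)
}

#' Age band of an episode
#'
#' Five-year screening age bands: 50-54, 55-59, 60-64, 65-69, 70+.
#' @param age_years integer vector of ages.
#' @return Factor with levels `50_54`, `55_59`, `60_64`, `65_69`, `70_plus`.
#' @export
age_band <- function(age_years) {
  cut(age_years, breaks = c(50, 55, 60, 65, 70, Inf), right = FALSE,
      labels = c("50_54", "55_59", "60_64", "65_69", "70_plus"))
}
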