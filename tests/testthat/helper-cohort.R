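# Build episode rows with sensible defaults; any field can be overridden.
make_episodes <- function(n = 1L, ...) {
  base <- data.frame(
    episode_id = sprintf("t%04d", seq_len(n)),
    age_years = 60,
    r1_opinion = "no_recall",
    r2_opinion = "no_recall",
    arbitration_opinion = "not_applicable",
    ai_eligible = TRUE,
    ai_score = 0.1,
    panel_opinion = "not_applicable",
    review_time_category = "not_applicable",
    cancer = FALSE,
    detection_channel = "none",
    excluded_reason = "none",
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

# Exhaustive 64-episode truth-table cohort: every combination of reader 1,
# reader 2, arbitration, cancer status, and four AI score levels spanning
# the operating points. Concordant reader pairs force arbitration to
# not_applicable (the grid then contains duplicates, which is intentional).
toy_ops <- function() operating_points(OP1 = 0.85, OP2 = 0.65, OP3 = 0.45,
                                       OP4 = 0.25)

toy_truth_table_cohort <- function() {
  grid <- expand.grid(r1 = c("recall", "no_recall"),
                      r2 = c("recall", "no_recall"),
                      arb = c("recall", "no_recall"),
                      cancer = c(TRUE, FALSE),
                      score = c(0.05, 0.50, 0.70, 0.90),
                      stringsAsFactors = FALSE)
  arb <- ifelse(grid$r1 == grid$r2, "not_applicable", grid$arb)
  cohort_table(make_episodes(nrow(grid),
                             r1_opinion = grid$r1, r2_opinion = grid$r2,
                             arbitration_opinion = arb, ai_score = grid$score,
                             cancer = grid$cancer))
}

# Independent brute-force oracle for the workflow engine: literal
# per-episode if/else transcription of each pathway, written separately
# from the vectorised engine. panel_dec is one fallback decision per
# episode, used when no live panel outcome is recorded.
oracle_apply <- function(cohort, mode, op_t = NULL, op_a = NULL, ops,
                         n_arbiters = 1L, panel_dec = NULL) {
  out <- data.frame(episode_id = cohort$episode_id, final = NA,
                    r1 = NA_integer_, r2 = NA_integer_, arb = NA_integer_,
                    addarb = NA_integer_)
  for (i in seq_len(nrow(cohort))) {
    e <- cohort[i, ]
    r1 <- e$r1_opinion == "recall"
    r2 <- e$r2_opinion == "recall"
    routine <- if (r1 == r2) r1 else e$arbitration_opinion == "recall"
    reads <- c(r1 = 1L, r2 = 1L, arb = if (r1 != r2) 1L else 0L, addarb = 0L)
    final <- routine

    if (mode %in% c("triage", "triage_plus_additional")) {
      ai <- e$ai_score >= ops[[op_t]]
      if (ai == r1) {
        final <- r1
        reads[["r2"]] <- 0L
        reads[["arb"]] <- 0L
      }
    }
    if (mode %in% c("triage_negatives", "trineg_plus_additional")) {
      ai <- e$ai_score >= ops[[op_t]]
      if (!ai && !r1) {
        final <- FALSE
        reads[["r2"]] <- 0L
        reads[["arb"]] <- 0L
      }
    }
    if (mode %in% c("additional_read", "triage_plus_additional",
                    "trineg_plus_additional")) {
      if (!final && e$ai_score >= ops[[op_a]]) {
        reads[["addarb"]] <- n_arbiters
        final <- if (e$panel_opinion != "not_applicable") {
          e$panel_opinion == "recall"
        } else panel_dec[i]
      }
    }
    out$final[i] <- final
    out[i, c("r1", "r2", "arb", "addarb")] <- as.list(reads)
  }
  out
}

# Numerical-integration truth for the generator model: probability that
# routine double reading recalls a case of the given status, and the
# probability that a cancer is missed by routine reading but flagged by the
# AI at threshold thr. Independent of the simulation code path.
integrate_routine_recall <- function(cfg, cancer) {
  w <- cfg$difficulty_corr
  t_read <- if (cancer) qnorm(1 - cfg$reader_sens) else qnorm(cfg$reader_spec)
  p_arb <- if (cancer) cfg$arbiter_sens else 1 - cfg$arbiter_spec
  f <- function(d) {
    q <- 1 - pnorm((t_read - sqrt(w) * d) / sqrt(1 - w))
    dnorm(d) * (q^2 + 2 * q * (1 - q) * p_arb)
  }
  integrate(f, -8, 8, rel.tol = 1e-10)$value
}

integrate_miss_and_flag <- function(cfg, thr) {
  w <- cfg$difficulty_corr
  t_read <- qnorm(1 - cfg$reader_sens)
  c_ai <- qnorm(pbeta(thr, cfg$ai_score_cancer[1], cfg$ai_score_cancer[2]))
  f <- function(d) {
    q <- 1 - pnorm((t_read - sqrt(w) * d) / sqrt(1 - w))
    pmiss <- (1 - q)^2 + 2 * q * (1 - q) * (1 - cfg$arbiter_sens)
    pflag <- 1 - pnorm((c_ai - sqrt(w) * d) / sqrt(1 - w))
    dnorm(d) * pmiss * pflag
  }
  integrate(f, -8, 8, rel.tol = 1e-10)$value
}

# Fixture reproducing a printed additional-review time table: per band
# (0-30, 30-60, 60-120, 120-300 s, unrecorded) the number reviewed,
# recalled, and cancers among the recalls.
review_time_fixture <- function(reviewed = c(848L, 357L, 114L, 16L, 10L),
                                recalled = c(7L, 19L, 19L, 5L, 5L),
                                cancers = c(3L, 4L, 2L, 2L, 0L)) {
  bands <- c("t0_30", "t30_60", "t60_120", "t120_300", "unrecorded")
  rows <- do.call(rbind, lapply(seq_along(bands), function(b) {
    n <- reviewed[b]
    rec <- c(rep(TRUE, recalled[b]), rep(FALSE, n - recalled[b]))
    can <- c(rep(TRUE, cancers[b]), rep(FALSE, n - cancers[b]))
    make_episodes(n, episode_id = sprintf("%s_%04d", bands[b], seq_len(n)),
                  ai_score = 0.9, review_time_category = bands[b],
                  panel_opinion = ifelse(rec, "recall", "no_recall"),
                  cancer = can,
                  detection_channel = ifelse(rec & can, "ai_additional",
                                             "none"))
  }))
  cohort_table(rows)
}

# Drop provenance/class attributes for content-level cohort comparisons.
strip_cohort <- function(x) {
  x <- as.data.frame(x)
  attr(x, "provenance") <- NULL
  class(x) <- "data.frame"
  rownames(x) <- NULL
  x
}
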