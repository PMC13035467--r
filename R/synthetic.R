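#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions of a UK double-reading screening
#' service with a live AI additional-read arm: 10,889 women, 117 confirmed
#' cancers (106 detectable by routine double reading, the rest reachable only
#' through the AI-flag pathway), an overall recall rate near 4.5%, an AI that
#' recalls 14.6% of episodes at its live operating point (flagging 12.4% of
#' the cohort once routine recalls are removed), and a review panel that
#' recalls about 4.1% of flagged episodes at a positive predictive value near
#' 20%. Reader operating characteristics were solved numerically, once, so
#' that the latent-difficulty model below reproduces those aggregates.
#'
#' The generative model: each episode draws a cancer status and a latent
#' difficulty `d ~ N(0,1)`. Each human reader's suspiciousness is
#' `z = sqrt(w) d + sqrt(1-w) e` with independent noise `e` and
#' `w = difficulty_corr`, so `z` is standard normal marginally and readers
#' (and the AI) agree more on easy episodes. A reader recalls a cancer when
#' `z` exceeds `qnorm(1 - reader_sens)` and a non-cancer when `z` exceeds
#' `qnorm(reader_spec)`, which makes the configured sensitivity and
#' specificity the exact marginals. Discordant pairs go to an arbiter with
#' its own accuracy. The AI score is drawn from a status-specific Beta
#' distribution through a Gaussian copula on the same latent difficulty.
#' Episodes whose routine decision is no-recall and whose score clears the
#' live operating point are flagged; the panel recalls flagged episodes with
#' status-specific probabilities and a review-time band is drawn for them.
#'
#' @param n_women number of episodes.
#' @param p_cancer prevalence of study-confirmed cancer.
#' @param reader_sens,reader_spec marginal per-reader sensitivity/specificity.
#' @param difficulty_corr weight of the shared latent difficulty in [0,1];
#'   induces reader-reader and reader-AI agreement.
#' @param arbiter_sens,arbiter_spec arbiter accuracy on discordant pairs.
#' @param ai_score_cancer,ai_score_noncancer Beta `(shape1, shape2)` pairs
#'   for the AI malignancy score by cancer status.
#' @param op_targets named vector of target marginal AI recall fractions per
#'   operating point label; must be non-decreasing from OP1 to OP4.
#' @param live_op operating point used for live additional-read flagging.
#' @param panel_recall_given_cancer,panel_recall_given_benign panel recall
#'   probabilities for flagged episodes.
#' @param time_category_probs probability vector over the five review-time
#'   bands (0-30 s, 30-60 s, 60-120 s, 120-300 s, unrecorded).
#' @param time_band_recall_probs optional named vector giving the panel
#'   recall probability for flagged non-cancers per review-time band,
#'   reproducing a rising recall fraction with review time; overrides
#'   `panel_recall_given_benign` when supplied.
#' @param age_band_probs probabilities of the five screening age bands.
#' @param seed integer RNG seed.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_women = 10889L,
                             p_cancer = 117 / 10889,
                             reader_sens = 0.8185,
                             reader_spec = 0.9294,
                             difficulty_corr = 0.30,
                             arbiter_sens = 0.85,
                             arbiter_spec = 0.80,
                             ai_score_cancer = c(6, 0.6),
                             ai_score_noncancer = c(0.7, 4),
                             op_targets = c(OP1 = 0.10, OP2 = 0.146,
                                            OP3 = 0.25, OP4 = 0.40),
                             live_op = "OP2",
                             panel_recall_given_cancer = 0.99,
                             panel_recall_given_benign = 0.033,
                             time_category_probs = c(t0_30 = 848, t30_60 = 357,
                                                     t60_120 = 114, t120_300 = 16,
                                                     unrecorded = 10) / 1345,
                             time_band_recall_probs = NULL,
                             age_band_probs = c(0.231, 0.262, 0.232, 0.201, 0.074),
                             seed = 20230227L) {
  cfg <- list(n_women = as.integer(n_women), p_cancer = p_cancer,
              reader_sens = reader_sens, reader_spec = reader_spec,
              difficulty_corr = difficulty_corr,
              arbiter_sens = arbiter_sens, arbiter_spec = arbiter_spec,
              ai_score_cancer = ai_score_cancer,
              ai_score_noncancer = ai_score_noncancer,
              op_targets = op_targets, live_op = live_op,
              panel_recall_given_cancer = panel_recall_given_cancer,
              panel_recall_given_benign = panel_recall_given_benign,
              time_category_probs = time_category_probs,
              time_band_recall_probs = time_band_recall_probs,
              age_band_probs = age_band_probs, seed = as.integer(seed))
  probs <- c(p_cancer, reader_sens, reader_spec, arbiter_sens, arbiter_spec,
             panel_recall_given_cancer, panel_recall_given_benign,
             time_category_probs, age_band_probs, difficulty_corr,
             time_band_recall_probs)
  if (any(probs < 0 | probs > 1)) {
    stop("generator_config: all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_women < 0) stop("n_women must be non-negative", call. = FALSE)
  if (abs(sum(time_category_probs) - 1) > 1e-9) {
    stop("time_category_probs must sum to 1", call. = FALSE)
  }
  if (abs(sum(age_band_probs) - 1) > 1e-9) {
    stop("age_band_probs must sum to 1", call. = FALSE)
  }
  if (any(c(ai_score_cancer, ai_score_noncancer) <= 0)) {
    stop("Beta shape parameters must be positive", call. = FALSE)
  }
  if (length(op_targets) == 0L || is.null(names(op_targets))) {
    stop("op_targets must be a non-empty named vector", call. = FALSE)
  }
  if (!live_op %in% names(op_targets)) {
    stop("live_op must be one of the op_target labels", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

# Mixture exceedance probability of the AI score at threshold t.
.score_exceedance <- function(t, cfg) {
  cfg$p_cancer * (1 - stats::pbeta(t, cfg$ai_score_cancer[1], cfg$ai_score_cancer[2])) +
    (1 - cfg$p_cancer) * (1 - stats::pbeta(t, cfg$ai_score_noncancer[1],
                                           cfg$ai_score_noncancer[2]))
}

#' Calibrate operating-point thresholds to target recall fractions
#'
#' Finds score thresholds whose marginal exceedance fraction, on a probe
#' sample simulated from the configured score mixture, matches each target in
#' `op_targets` to within 0.5 percentage points. Targets must be
#' non-decreasing from OP1 (most specific) to OP4 (most sensitive).
#'
#' @param config [generator_config()].
#' @param n_probe probe sample size.
#' @return An [operating_points()] set.
#' @export
calibrate_thresholds <- function(config, n_probe = 200000L) {
  stopifnot(inherits(config, "generator_config"))
  targets <- config$op_targets
  ord <- intersect(c("OP1", "OP2", "OP3", "OP4"), names(targets))
  if (length(ord) != length(targets)) {
    stop("op_targets labels must be among OP1..OP4", call. = FALSE)
  }
  targets <- targets[ord]
  if (is.unsorted(targets)) {
    stop("op_targets must be non-decreasing from OP1 to OP4", call. = FALSE)
  }
  set.seed(config$seed)
  n_c <- stats::rbinom(1L, n_probe, config$p_cancer)
  scores <- c(stats::rbeta(n_c, config$ai_score_cancer[1], config$ai_score_cancer[2]),
              stats::rbeta(n_probe - n_c, config$ai_score_noncancer[1],
                           config$ai_score_noncancer[2]))
  thr <- vapply(targets, function(tg) {
    if (tg >= 1) return(1e-12)                  # floor: everything recalled
    unname(stats::quantile(scores, 1 - tg, type = 8, names = FALSE))
  }, numeric(1))
  do.call(operating_points, as.list(thr))
}

#' Generate a synthetic screening cohort
#'
#' Draws `n_women` episodes under the latent-difficulty model documented in
#' [generator_config()]. One global seed feeds a fixed-width per-episode
#' block of uniform draws, so enlarging `n_women` extends the cohort without
#' reshuffling earlier episodes, and identical seeds reproduce identical
#' cohorts. All generated episodes are AI-eligible evaluation episodes
#' (`excluded_reason = "none"`).
#'
#' @param config [generator_config()].
#' @param ops optional [operating_points()]; defaults to
#'   [calibrate_thresholds()] on `config`.
#' @return A validated [cohort_table()].
#' @export
generate_cohort <- function(config, ops = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(ops)) ops <- calibrate_thresholds(config)
  thr_live <- op_threshold(ops, config$live_op)
  n <- config$n_women
  if (n == 0L) {
    empty <- as.data.frame(stats::setNames(rep(list(character(0)), 12),
                                           .episode_columns))
    empty$age_years <- numeric(0); empty$ai_score <- numeric(0)
    empty$ai_eligible <- logical(0); empty$cancer <- logical(0)
    return(cohort_table(empty, provenance = list(source = "synthetic",
                                                 seed = config$seed)))
  }
  set.seed(config$seed)
  u <- matrix(stats::runif(n * 10L), ncol = 10L, byrow = TRUE)

  cancer <- u[, 1] < config$p_cancer
  w <- config$difficulty_corr
  d <- stats::qnorm(u[, 2])
  z1 <- sqrt(w) * d + sqrt(1 - w) * stats::qnorm(u[, 3])
  z2 <- sqrt(w) * d + sqrt(1 - w) * stats::qnorm(u[, 4])
  t_read <- ifelse(cancer, stats::qnorm(1 - config$reader_sens),
                   stats::qnorm(config$reader_spec))
  r1 <- z1 > t_read
  r2 <- z2 > t_read
  discord <- r1 != r2
  p_arb <- ifelse(cancer, config$arbiter_sens, 1 - config$arbiter_spec)
  arb <- ifelse(discord, ifelse(u[, 5] < p_arb, "recall", "no_recall"),
                "not_applicable")

  u_ai <- stats::pnorm(sqrt(w) * d + sqrt(1 - w) * stats::qnorm(u[, 6]))
  score <- ifelse(cancer,
                  stats::qbeta(u_ai, config$ai_score_cancer[1], config$ai_score_cancer[2]),
                  stats::qbeta(u_ai, config$ai_score_noncancer[1],
                               config$ai_score_noncancer[2]))

  rr <- (r1 & r2) | (discord & arb == "recall")
  flagged <- !rr & score >= thr_live

  band_levels <- c("t0_30", "t30_60", "t60_120", "t120_300", "unrecorded")
  band_idx <- findInterval(u[, 8], cumsum(config$time_category_probs),
                           left.open = TRUE) + 1L
  band <- ifelse(flagged, band_levels[pmin(band_idx, 5L)], "not_applicable")

  p_panel <- ifelse(cancer, config$panel_recall_given_cancer,
                    config$panel_recall_given_benign)
  if (!is.null(config$time_band_recall_probs)) {
    tb <- config$time_band_recall_probs[band]
    p_panel <- ifelse(!cancer & !is.na(tb), unname(tb), p_panel)
  }
  panel <- ifelse(flagged, ifelse(u[, 7] < p_panel, "recall", "no_recall"),
                  "not_applicable")

  band_lo <- c(50L, 55L, 60L, 65L, 70L)
  age_idx <- pmin(findInterval(u[, 9], cumsum(config$age_band_probs),
                               left.open = TRUE) + 1L, 5L)
  age <- band_lo[age_idx] + floor(u[, 10] * 5)

  channel <- ifelse(cancer & rr, "routine",
             ifelse(cancer & !rr & panel == "recall", "ai_additional", "none"))

  x <- data.frame(
    episode_id = sprintf("ep%07d", seq_len(n)),
    age_years = age,
    r1_opinion = ifelse(r1, "recall", "no_recall"),
    r2_opinion = ifelse(r2, "recall", "no_recall"),
    arbitration_opinion = arb,
    ai_eligible = TRUE,
    ai_score = score,
    panel_opinion = panel,
    review_time_category = band,
    cancer = cancer,
    detection_channel = channel,
    excluded_reason = "none",
    stringsAsFactors = FALSE
  )
  out <- cohort_table(x, provenance = list(
    source = "synthetic", seed = config$seed, live_op = config$live_op,
    live_threshold = unname(thr_live)))
  validate_cohort(out)
  out
}
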