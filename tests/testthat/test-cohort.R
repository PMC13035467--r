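test_that("episode table round-trips through CSV and TSV byte-stably", {
  cfg <- generator_config(n_women = 1000L, seed = 42L)
  co <- generate_cohort(cfg)
  for (ext in c("csv", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_cohort(co, path)
    back <- read_cohort(path)
    expect_equal(strip_cohort(back), strip_cohort(co))
    # determinism: writing the same cohort again yields identical bytes
    path2 <- withr::local_tempfile(fileext = paste0(".", ext))
    write_cohort(co, path2)
    expect_identical(readLines(path), readLines(path2))
  }
})

test_that("an empty cohort writes a header-only file and reads back", {
  co <- generate_cohort(generator_config(n_women = 0L),
                        ops = operating_points(OP2 = 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  expect_length(readLines(path), 1L)
  expect_equal(nrow(read_cohort(path)), 0L)
})

test_that("reader normalises case and rejects schema violations", {
  x <- make_episodes(3, r1_opinion = c("Recall", "NO_RECALL", "no_recall"),
                     r2_opinion = c("recall", "no_recall", "no_recall"),
                     arbitration_opinion = c("not_applicable", "not_applicable",
                                             "not_applicable"),
                     ai_score = c(0.9, 0.2, 0.3))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  co <- read_cohort(path)
  expect_equal(co$r1_opinion, c("recall", "no_recall", "no_recall"))

  # missing column
  utils::write.csv(x[, -3], path, row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(path), "missing.*r1_opinion")
  # extra column
  x2 <- cbind(x, extra = 1)
  utils::write.csv(x2, path, row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(path), "unexpected.*extra")
})

test_that("invariant violations are reported with episode id and rule", {
  # concordant readers but an arbitration opinion recorded
  bad <- make_episodes(1, arbitration_opinion = "recall")
  expect_error(validate_cohort(cohort_table(bad)),
               "t0001.*|arbitration.*t0001")
  # discordant readers without arbitration
  bad <- make_episodes(1, r1_opinion = "recall")
  expect_error(validate_cohort(cohort_table(bad)), "arbitration")
  # AI-eligible without a score
  bad <- make_episodes(1, ai_score = NA_real_)
  expect_error(validate_cohort(cohort_table(bad)), "ai_score")
  # score present for an ineligible episode
  bad <- make_episodes(1, ai_eligible = FALSE)
  expect_error(validate_cohort(cohort_table(bad)), "ai_score")
  # panel outcome on a routine recall
  bad <- make_episodes(1, r1_opinion = "recall", r2_opinion = "recall",
                       panel_opinion = "recall", ai_score = 0.9,
                       detection_channel = "none")
  expect_error(validate_cohort(cohort_table(bad)), "panel_opinion")
  # review time without panel review
  bad <- make_episodes(1, review_time_category = "t0_30")
  expect_error(validate_cohort(cohort_table(bad)), "review_time")
  # inconsistent detection channel
  bad <- make_episodes(1, cancer = TRUE, r1_opinion = "recall",
                       r2_opinion = "recall", detection_channel = "none")
  expect_error(validate_cohort(cohort_table(bad)), "detection_channel")
  # duplicated id
  bad <- make_episodes(2, episode_id = c("a", "a"))
  expect_error(validate_cohort(cohort_table(bad)), "unique")
})

test_that("a mixed fixture parses with exact category counts", {
  x <- rbind(
    make_episodes(4, episode_id = sprintf("c%02d", 1:4),
                  r1_opinion = c("recall", "recall", "no_recall", "no_recall"),
                  r2_opinion = c("recall", "no_recall", "recall", "no_recall"),
                  arbitration_opinion = c("not_applicable", "recall",
                                          "no_recall", "not_applicable"),
                  ai_score = c(0.95, 0.5, 0.2, 0.1),
                  cancer = c(TRUE, TRUE, FALSE, FALSE),
                  detection_channel = c("routine", "routine", "none", "none")),
    make_episodes(5, episode_id = sprintf("d%02d", 1:5),
                  panel_opinion = c("recall", "recall", "no_recall",
                                    "no_recall", "no_recall"),
                  review_time_category = c("t0_30", "t30_60", "t60_120",
                                           "t120_300", "unrecorded"),
                  ai_score = 0.9,
                  cancer = c(TRUE, FALSE, FALSE, FALSE, FALSE),
                  detection_channel = c("ai_additional", rep("none", 4))),
    make_episodes(4, episode_id = sprintf("e%02d", 1:4),
                  ai_eligible = FALSE, ai_score = NA_real_,
                  excluded_reason = c("opt_out", "technical_recall",
                                      "not_sent_to_ai", "ai_ineligible")),
    make_episodes(7, episode_id = sprintf("f%02d", 1:7),
                  age_years = c(50, 54, 55, 60, 65, 70, 90))
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort_table(x), path)
  co <- read_cohort(path)
  expect_equal(nrow(co), 20L)
  expect_equal(sum(co$panel_opinion == "recall"), 2L)
  expect_equal(as.vector(table(factor(co$excluded_reason,
                                      levels = c("none", "opt_out",
                                                 "technical_recall",
                                                 "not_sent_to_ai",
                                                 "ai_ineligible")))),
               c(16L, 1L, 1L, 1L, 1L))
  expect_equal(sum(co$review_time_category != "not_applicable"), 5L)
  expect_equal(sum(co$cancer), 3L)
  expect_equal(as.vector(table(age_band(co$age_years))),
               c(2L, 1L, 14L, 1L, 2L))
})

test_that("evaluation-cohort filtering matches the study flow accounting", {
  n <- 17421L
  reason <- rep("none", n)
  reason[1:93] <- "opt_out"
  reason[94:268] <- "technical_recall"
  reason[269:5260] <- "not_sent_to_ai"
  reason[5261:6520] <- "ai_ineligible"
  attendees <- cohort_table(make_episodes(n, episode_id = sprintf("a%05d", 1:n),
                                          excluded_reason = reason))
  res <- build_evaluation_cohort(attendees)
  expect_equal(unname(res$exclusions),
               c(93L, 175L, 4992L, 1260L))
  expect_equal(nrow(res$cohort), n - 93L - 175L - 4992L - 1260L)
  expect_true(all(res$cohort$excluded_reason == "none"))
  # stage counts sum to attendees minus retained
  expect_equal(sum(res$exclusions), n - nrow(res$cohort))
  # idempotent
  res2 <- build_evaluation_cohort(res$cohort)
  expect_equal(nrow(res2$cohort), nrow(res$cohort))
  expect_equal(sum(res2$exclusions), 0L)
})

test_that("an episode with several applicable exclusion reasons is counted once, at the earliest stage", {
  attendees <- cohort_table(make_episodes(3, episode_id = c("a", "b", "c")))
  flags <- data.frame(opt_out = c(TRUE, FALSE, FALSE),
                      technical_recall = c(TRUE, TRUE, FALSE),
                      not_sent_to_ai = c(FALSE, TRUE, FALSE),
                      ai_ineligible = c(TRUE, FALSE, FALSE))
  res <- build_evaluation_cohort(attendees, flags)
  expect_equal(unname(res$exclusions), c(1L, 1L, 0L, 0L))
  expect_equal(res$cohort$episode_id, "c")
})

test_that("all-retained attendees pass through unchanged", {
  attendees <- cohort_table(make_episodes(5, episode_id = letters[1:5]))
  res <- build_evaluation_cohort(attendees)
  expect_equal(strip_cohort(res$cohort), strip_cohort(attendees))
  expect_equal(sum(res$exclusions), 0L)
})
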