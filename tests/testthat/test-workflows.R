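test_that("routine double reading follows the two-reader-plus-arbitration rule", {
  e <- make_episodes(3,
                     r1_opinion = c("recall", "recall", "recall"),
                     r2_opinion = c("recall", "no_recall", "no_recall"),
                     arbitration_opinion = c("not_applicable", "no_recall",
                                             "recall"))
  out <- routine_decision(e)
  expect_equal(out$final_decision, c("recall", "no_recall", "recall"))
  expect_equal(out$reads_r1, rep(1L, 3))
  expect_equal(out$reads_r2, rep(1L, 3))
  expect_equal(out$reads_arbitration, c(0L, 1L, 1L))
  expect_equal(out$reads_additional_arbitration, rep(0L, 3))

  bad <- make_episodes(1, r1_opinion = "recall",
                       arbitration_opinion = "not_applicable")
  expect_error(routine_decision(bad), "arbitration")
})

test_that("AI recall respects the boundary rule and operating-point nesting", {
  ops <- toy_ops()
  e <- make_episodes(2, ai_score = c(0.9, 0.65))
  expect_equal(ai_recalls(e, "OP2", ops), c(TRUE, TRUE))  # equality recalls
  expect_equal(ai_recalls(e, "OP1", ops), c(TRUE, FALSE))

  set.seed(42)
  e <- make_episodes(500, ai_score = runif(500))
  rec <- sapply(c("OP1", "OP2", "OP3", "OP4"), function(op)
    ai_recalls(e, op, ops))
  # a recall at a stricter OP implies recall at every more sensitive OP
  expect_true(all(rec[, "OP1"] <= rec[, "OP2"]))
  expect_true(all(rec[, "OP2"] <= rec[, "OP3"]))
  expect_true(all(rec[, "OP3"] <= rec[, "OP4"]))

  e$ai_eligible[3] <- FALSE
  expect_error(ai_recalls(e, "OP2", ops), "eligible")
})

test_that("workflow catalogue enumerates exactly the 17 configurations", {
  cat17 <- workflow_catalogue()
  expect_length(cat17, 17L)
  modes <- table(vapply(cat17, `[[`, character(1), "mode"))
  expect_equal(modes[["additional_read"]], 2L)
  expect_equal(modes[["triage"]], 2L)
  expect_equal(modes[["triage_negatives"]], 3L)
  expect_equal(modes[["trineg_plus_additional"]], 6L)
  expect_equal(modes[["triage_plus_additional"]], 4L)
  expect_true("trineg_OP3_plus_addread_OP2" %in% names(cat17))
})

test_that("workflow specs reject inconsistent arguments", {
  expect_error(workflow_spec("triage"), "op_triage")
  expect_error(workflow_spec("routine", op_triage = "OP1"), "op_triage")
  expect_error(workflow_spec("additional_read"), "op_additional")
  expect_error(workflow_spec("additional_read", op_additional = "OP9"), "OP9")
  expect_error(workflow_spec("additional_read", op_additional = "OP2",
                             n_arbiters = 4), "arbiters")
  expect_error(workflow_spec("double_read"), "mode")
})

test_that("every workflow's decisions and read ledger match the brute-force oracle", {
  co <- toy_truth_table_cohort()
  ops <- toy_ops()
  panel_dec <- co$cancer          # deterministic toy panel: recall iff cancer
  for (spec in workflow_catalogue(n_arbiters = 2L)) {
    res <- apply_workflow(co, spec, ops, panel = panel_dec)
    orc <- oracle_apply(co, spec$mode, spec$op_triage, spec$op_additional,
                        ops, n_arbiters = 2L, panel_dec = panel_dec)
    expect_equal(res$outcomes$final_decision == "recall", orc$final,
                 info = spec$name, ignore_attr = TRUE)
    expect_equal(res$outcomes$reads_r2, orc$r2, info = spec$name)
    expect_equal(res$outcomes$reads_arbitration, orc$arb, info = spec$name)
    expect_equal(res$outcomes$reads_additional_arbitration, orc$addarb,
                 info = spec$name)
    expect_equal(res$outcomes$detected_cancer,
                 co$cancer & orc$final, info = spec$name)
  }
})

test_that("aggregate counts fold the per-episode outcomes", {
  co <- generate_cohort(generator_config(n_women = 2000L, seed = 13L))
  res <- apply_workflow(co, workflow_spec("routine"),
                        operating_points(OP2 = 0.5))
  ct <- res$counts
  expect_equal(ct$recalls, sum(res$outcomes$final_decision == "recall"))
  expect_equal(ct$detected_cancers, sum(res$outcomes$detected_cancer))
  expect_equal(ct$true_negatives + ct$false_positives, ct$n - ct$n_cancer)
  expect_equal(ct$total_reads, sum(ct$reads_by_role))
  # routine read conservation: 2n plus one arbitration per discordant pair
  expect_equal(ct$total_reads,
               2L * ct$n + sum(co$r1_opinion != co$r2_opinion))
})

test_that("triage-negatives never adds recalls and additional read never removes them", {
  cfg <- generator_config(n_women = 5000L, seed = 17L)
  ops <- calibrate_thresholds(cfg)
  co <- generate_cohort(cfg, ops)
  panel <- make_panel_provider(seed = 18L)
  routine <- apply_workflow(co, workflow_spec("routine"), ops)
  for (op in c("OP2", "OP3", "OP4")) {
    tn <- apply_workflow(co, workflow_spec("triage_negatives", op_triage = op),
                         ops, panel)
    expect_lte(tn$counts$recalls, routine$counts$recalls)
  }
  for (op in c("OP1", "OP2")) {
    ar <- apply_workflow(co, workflow_spec("additional_read",
                                           op_additional = op), ops, panel)
    expect_gte(ar$counts$recalls, routine$counts$recalls)
    # per-episode monotonicity, not just in aggregate
    expect_true(all(ar$outcomes$final_decision == "recall" |
                      routine$outcomes$final_decision == "no_recall"))
  }
})

test_that("triage on an always-disagreeing AI reduces to routine reading", {
  co <- cohort_table(make_episodes(
    6,
    r1_opinion = c("recall", "recall", "no_recall", "no_recall", "recall",
                   "no_recall"),
    r2_opinion = c("recall", "no_recall", "recall", "no_recall", "recall",
                   "no_recall"),
    arbitration_opinion = c("not_applicable", "recall", "no_recall",
                            "not_applicable", "not_applicable",
                            "not_applicable"),
    # scores chosen so the AI disagrees with reader 1 at OP2 everywhere
    ai_score = c(0.1, 0.2, 0.9, 0.8, 0.3, 0.7)))
  ops <- toy_ops()
  routine <- apply_workflow(co, workflow_spec("routine"), ops)
  triage <- apply_workflow(co, workflow_spec("triage", op_triage = "OP2"), ops)
  expect_equal(triage$outcomes, routine$outcomes)
})

test_that("a panel provider is required only for unrecorded flagged episodes", {
  co <- cohort_table(make_episodes(2, ai_score = c(0.9, 0.9),
                                   panel_opinion = c("recall",
                                                     "not_applicable"),
                                   review_time_category = c("t0_30",
                                                            "not_applicable"),
                                   cancer = c(TRUE, FALSE),
                                   detection_channel = c("ai_additional",
                                                         "none")))
  ops <- toy_ops()
  spec <- workflow_spec("additional_read", op_additional = "OP2")
  expect_error(apply_workflow(co, spec, ops), "panel")
  res <- apply_workflow(co, spec, ops, panel = c(FALSE, FALSE))
  expect_equal(res$outcomes$final_decision, c("recall", "no_recall"))
  expect_equal(res$provenance$n_panel_simulated, 1L)
  # recorded outcomes take precedence over the provider
  res2 <- apply_workflow(co, spec, ops, panel = c(FALSE, TRUE))
  expect_equal(res2$outcomes$final_decision, c("recall", "recall"))
})

test_that("AI workflows refuse cohorts with ineligible episodes", {
  co <- cohort_table(make_episodes(2, ai_eligible = c(TRUE, FALSE),
                                   ai_score = c(0.5, NA)))
  expect_error(apply_workflow(co, workflow_spec("triage", op_triage = "OP2"),
                              toy_ops()), "eligible")
  expect_silent(apply_workflow(co, workflow_spec("routine"), toy_ops()))
})

test_that("a stricter additional-read point inside triage-negatives only flags double-read episodes", {
  cfg <- generator_config(n_women = 4000L, seed = 23L)
  ops <- calibrate_thresholds(cfg)
  co <- generate_cohort(cfg, ops)
  panel <- make_panel_provider(seed = 19L)
  spec <- workflow_spec("trineg_plus_additional", op_triage = "OP3",
                        op_additional = "OP2")
  res <- apply_workflow(co, spec, ops, panel)
  flagged <- res$outcomes$reads_additional_arbitration > 0
  expect_true(all(res$outcomes$reads_r2[flagged] == 1L))
})
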