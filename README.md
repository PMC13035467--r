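# screenflow

Simulation and inference tools for evaluating how an AI reader can be
integrated into a double-reading breast screening programme.

## The problem

In population breast screening (as in the UK NHS programme), every
mammogram is read independently by two human readers; discrepancies go to a
third-reader arbitration. An AI system that outputs a continuous malignancy
score can be inserted into this pathway in many ways:

* **AI additional read** — when routine double reading decides *not* to
  recall a woman but the AI score clears a decision threshold, the case is
  flagged for an extra human arbitration panel, which can add cancer
  detections at the cost of extra reads and recalls.
* **Triage** — the AI stands in for the second reader whenever its opinion
  agrees with reader 1 (on recall or no-recall), saving second reads.
* **Triage negatives** — the AI replaces the second reader only when both
  it and reader 1 agree *not* to recall, saving reads without ever adding
  recalls.
* **Combinations** — a triage component followed by the additional-read
  rule on the resulting non-recalls.

With four vendor operating points OP1–OP4 (OP1 most specific, OP4 most
sensitive; a score **≥** threshold counts as an AI recall), these modes give
a catalogue of 17 configurations plus the routine baseline. `screenflow`
deterministically replays any of them over an episode-level cohort table and
quantifies the trade-offs.

## What it computes

For a cohort of n screened women with R recalls, D detected cancers and C
reference-standard cancers (cancers confirmed within the study):

* CDR = 1000·D/n per 1,000 screens, recall rate R/n, sensitivity D/C,
  specificity TN/(n−C), PPV D/R — each with a 95% Wilson score interval;
* a reads-by-role workload ledger: reads = r1 + r2 + arbitration +
  (additionally arbitrated × panel size), and relative savings versus
  routine double reading;
* paired percentile-bootstrap confidence intervals for metric ratios
  (workflow/routine): episodes are resampled with replacement, the same
  resample indexing both workflows, with 50,000 repetitions and two-sided
  90% intervals by default;
* gated non-inferiority (relative margin 0.1, one-sided α = 0.05) and
  superiority (α = 0.1) verdicts per workflow, following an a-priori metric
  order; the first non-inferiority failure makes all later tests
  exploratory;
* Monte-Carlo power for a paired non-inferiority design on confirmed
  positives (four-cell detection model: both / routine-only / AI-only /
  neither);
* a calibrated synthetic cohort generator (latent-difficulty reader model,
  Beta-mixture AI scores through a Gaussian copula) so that the entire
  pipeline is testable without access to any real screening data.

## Worked example

```r
library(screenflow)

cfg    <- generator_config(seed = 20230227L)   # calibrated defaults, n = 10,889
ops    <- calibrate_thresholds(cfg)            # OP1-OP4 score thresholds
cohort <- generate_cohort(cfg, ops)
panel  <- make_panel_provider(seed = 1L)       # simulated panel fallback

routine <- apply_workflow(cohort, workflow_spec("routine"), ops)
primary <- apply_workflow(cohort,
  workflow_spec("trineg_plus_additional", op_triage = "OP3",
                op_additional = "OP2"), ops, panel)
summary(primary, baseline = routine)
```

```
Screening performance on n = 10889 (reference cancers = 136)
  cdr             12.5 per 1,000  (CI 10.6-14.8)
  recall_rate      4.6%  (95% CI 4.2-5.0)
  sensitivity    100.0%  (95% CI 97.3-100.0)
  specificity     96.7%  (95% CI 96.3-97.0)
  ppv             27.4%  (95% CI 23.7-31.5)
  total reads   16410  (workload saving vs routine 28.9%)
```

This simulated cohort happened to carry 136 confirmed cancers, of which
routine double reading detects 127 (`summary(routine)`: CDR 11.7 per
1,000); the combination workflow recovers the remainder through the
additional-read panel while trimming the recall count and saving 28.9% of
human reads. The gated comparison runs the five ratio tests in the
workflow's pre-specified order:

```r
run_gated_comparison(cohort,
  workflow_spec("trineg_plus_additional", op_triage = "OP3",
                op_additional = "OP2"),
  cfg = inference_config(n_boot = 50000L, seed = 2L), ops = ops,
  panel = panel)
```

```
Gated comparison: trineg_OP3_plus_addread_OP2 vs routine double reading
  50000 bootstrap repetitions, 90% percentile CIs, margin 0.10
  1. CDR  ratio 1.071 (1.034-1.114)  superior [confirmatory]
  2. RR   ratio 0.996 (0.958-1.035)  noninferior [confirmatory]
  3. SEN  ratio 1.071 (1.034-1.114)  superior [confirmatory]
  4. SPEC ratio 1.001 (0.999-1.003)  noninferior [confirmatory]
  5. PPV  ratio 1.075 (1.027-1.128)  superior [confirmatory]
```

So cancer detection is superior (7.1% higher, with the 90% interval
entirely above 1) while the recall rate is non-inferior; every test stays
confirmatory because no earlier gate failed.

`run_pipeline()` orchestrates generate → apply → summarise → compare →
power as one reproducible run directory (cohort, per-workflow outcome CSVs,
summary and workload tables, gated verdict JSON, manifest, log).

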