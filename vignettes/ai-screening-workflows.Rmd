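---
title: "Modelling AI integration into double-read breast screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling AI integration into double-read breast screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenflow)
```

## Scope and data model

`screenflow` evaluates reading-workflow configurations for a breast
screening service that double-reads every mammogram, arbitrates
discrepancies with a third reader, and runs an AI malignancy scorer
alongside. The unit of analysis is the *screening episode* — one woman's
screen — carrying the two reader opinions, the arbitration opinion where
the readers disagreed, the AI score (a real in [0, 1]) with an eligibility
flag, the live additional-arbitration panel outcome with its review-time
band, the confirmed-cancer status, and a derived detection channel. The
episode table round-trips through plain CSV/TSV with explicit
`not_applicable` tokens; every structural invariant (arbitration present
iff the readers disagree, AI score present iff eligible, panel outcomes
only on routine non-recalls, channel consistency) is validated on read and
on construction.

Cancers are defined as those histologically confirmed within the study
episode. Interval cancers are unobservable on this horizon, so
"sensitivity" is always relative to this reference standard: the cancers
detectable at all are those found by routine reading or by the AI-flag
pathway. This is a genuine limitation, not a modelling choice — absolute
sensitivity of either pathway cannot be estimated from these data.

## Workflow semantics

All seventeen AI configurations (plus the routine baseline) are
deterministic per-episode decision rules:

* *additional read at OPa*: routine reading first; an episode finally not
  recalled whose score is ≥ the OPa threshold is charged `n_arbiters`
  additional-arbitration reads and takes the panel decision.
* *triage at OPt*: the AI acts as reader 2 whenever it agrees with reader 1
  (one human read); otherwise reader 2 reads and the usual
  discrepancy-arbitration pathway completes.
* *triage negatives at OPt*: single-read shortcut only when reader 1 and
  the AI both say no-recall.
* combinations apply the triage component first, then the additional-read
  rule to the resulting non-recalls.

Two conventions deserve note. First, a score exactly equal to a threshold
counts as an AI recall; vendor behaviour at the boundary is unspecified and
a fixed convention keeps the flag sets nested across operating points
(OP1 ⊆ OP2 ⊆ OP3 ⊆ OP4). Second, when the AI and reader 1 *disagree* under
triage, the engine routes the episode through the full human pathway
(reader 2, then arbitration if needed). The alternative — sending
disagreements straight to arbitration — is a coherent design but changes
the workload ledger; the conservative reader-2 routing is the only pathway
implemented, and it is the one the invariants and oracle tests pin down.

Panel decisions are data, not behaviour: recorded live outcomes travel
with their episodes everywhere (including inside the bootstrap), and only
episodes flagged under a *simulated* operating point that the live pathway
never reviewed fall back to a seeded simulated panel provider. Results
report how many decisions were simulated.

## The synthetic cohort generator

No episode-level data are distributable, so the generator exists to
produce cohorts with the statistical structure the analysis assumes, at
the aggregate operating characteristics of a real service. Per episode:

1. cancer status is Bernoulli(`p_cancer`), default 117/10,889 ≈ 0.0107;
2. a latent difficulty `d ~ N(0,1)` is shared by all readers of that
   episode; each reader's suspiciousness is
   `z = sqrt(w)·d + sqrt(1−w)·e`, `w = difficulty_corr = 0.30`, so `z` is
   standard normal marginally and the configured per-reader sensitivity
   (0.8185) and specificity (0.9294) are *exact* marginals regardless of
   `w`;
3. discordant pairs draw an arbiter decision with its own accuracy
   (sensitivity 0.85, specificity 0.80);
4. the AI score comes from a status-specific Beta — Beta(6, 0.6) for
   cancers, Beta(0.7, 4) for non-cancers — through a Gaussian copula on
   the same difficulty, so AI-reader agreement rides the same single dial;
5. episodes not recalled by routine reading whose score clears the live
   operating point are flagged; the panel recalls flagged cancers with
   probability 0.99 and flagged benigns with probability 0.033, and a
   review-time band is drawn for flagged episodes.

The reader and panel parameters were solved numerically, once, so that the
model's closed-form aggregates match a realistic service profile: routine
detection of 106/117 cancers (9.7 per 1,000), an overall recall rate of
4.5%, a marginal AI recall fraction of 14.6% at the live operating point,
a flagged fraction of 12.4% of the cohort, panel recalls of 4.1% of
flagged episodes and a panel PPV near 20%. The default operating-point
*targets* are OP1 = 0.10, OP2 = 0.146, OP3 = 0.25 and OP4 = 0.40 marginal
AI recall; OP2 is the calibrated live point, OP1 was set so the stricter
additional read flags roughly two-thirds as many episodes as OP2, and OP3
and OP4 were chosen so the triage-negatives workflows save roughly a third
of reads — values a screening service running such a programme would find
unremarkable. `calibrate_thresholds()` converts targets to thresholds by
empirical quantiles of the simulated score mixture (0.5 percentage-point
tolerance, monotonicity enforced).

Reproducibility: one global seed feeds a fixed-width block of uniform
draws per episode, so enlarging `n_women` extends a cohort without
reshuffling earlier episodes, and all downstream stages (panel provider,
bootstrap, power) use separate named seeds.

What the generator does *not* emulate: reader-experience heterogeneity and
behavioural drift under live AI use, AI score drift across imaging
hardware or software changes, age- or density-dependence of reader or AI
accuracy, and any joint opinion structure beyond the single shared
difficulty. The published marginals under-determine the joint distribution
of (reader 1, reader 2, arbitration, AI); the one-dial copula reproduces
arbitration volumes and complementarity qualitatively, so passing tests
demonstrate correctness of the *pipeline*, not fidelity of the joint law
of any particular service.

## Metrics and workload

CDR (per 1,000), recall rate, sensitivity, specificity and PPV carry 95%
Wilson score intervals. Specificity uses `n − reference cancers` as its
denominator. PPV with zero recalls is reported as an undefined-metric `NA`
rather than an error. Workload is the sum of examinations read by reader
1, reader 2 and the arbitration reader plus additionally arbitrated
examinations × the panel size (1–3, configurable); savings are relative to
the routine ledger, and are strictly decreasing in the panel size whenever
at least one episode is flagged. The review-time tabulation mirrors the
live pathway's reporting conventions (band share of reviews, recalls as a
share of the band, cancers as a share of band recalls); the
Cochran–Armitage trend test (via `stats::prop.trend.test`) excludes the
`unrecorded` band, and the two-proportion comparison uses the
Yates-corrected chi-squared test with Fisher's exact test as an option.

## Paired bootstrap and gated testing

Ratios of workflow metrics to routine are interval-estimated by a paired
case-resampling bootstrap: each replicate resamples episodes with
replacement and re-evaluates *both* workflows on the same resample.
Because workflow application is deterministic per episode, an episode
contributes only its outcome profile (workflow recall, routine recall,
cancer status) — at most eight distinct cells — so resampling episodes is
exactly equivalent to drawing the cell counts from a multinomial. The
implementation exploits this: 50,000 replicates reduce to multinomial
draws and a few inner products, which is what makes the default
repetition count, the coverage study and the power calculator cheap on a
single CPU. Intervals are two-sided 90% percentile intervals
(order-statistic interpolation, quantile type 6); the non-inferiority
decision reads the bound against `1 ± 0.1` (lower bound for
higher-is-better metrics, upper bound for the recall rate) and the
superiority decision reads the same bound against 1. Replicates with a
zero ratio denominator (e.g. a resample with no routine recalls) are
dropped and redrawn, with the count reported; at cohort scale this is
vanishingly rare.

Verdicts follow a fixed-sequence gating order per combination workflow
(shipped as editable YAML): tests run in the pre-specified metric order,
the first non-inferiority failure demotes every later test to exploratory
(still computed and reported), and superiority is evaluated only where
non-inferiority passed. Solo workflows get descriptive intervals without
verdicts. No further multiplicity adjustment is applied — the gating
itself limits the hypotheses confirmed.

In simulation at 2,000-episode cohorts with ~100 cancers, the 90%
percentile interval for the CDR ratio covers the integration-derived true
ratio about 89% of the time, with the shortfall concentrated in the upper
bound — the familiar small-sample behaviour of percentile intervals for
positively skewed count ratios. At realistic full-cohort scales the
discordant counts are smaller still, so ratio intervals for rare-event
metrics should be read with that caveat.

## Power for the paired non-inferiority design

`simulate_power()` sizes a comparison of detected proportions among
confirmed positives under a four-cell paired model: both workflows detect
(0.950), routine only (0.019), AI only (0.030), neither (the 0.001
residual; a toggle reassigns it to "both"). Each simulated study draws
`n_positives` multinomial outcomes and applies the same
percentile-bootstrap non-inferiority decision as the comparative module
(lower 90%-interval bound of the detected-proportion ratio > 0.9 at
one-sided α = 0.05); power is the passing fraction with a binomial
Monte-Carlo standard error.

The estimate is sensitive to which arm carries the larger discordant
cell, and markedly less so to the test itself. At 65 positives the
defaults above give ≈ 98% power; *transposing* the discordant cells
(routine-only 3.0%, AI-only 1.9% — the conservative assignment under
which one would normally size a non-inferiority study) gives ≈ 90.5%, and
a closed-form paired-difference calculation reproduces both figures to
within a couple of points. Planning numbers quoted for such designs
should therefore state the cell assignment explicitly; `power_design()`
takes the cells as explicit arguments for exactly this reason.
`required_positives()` inverts the curve by bisection with common random
numbers.

## Numerical and testing choices

* Thresholds live strictly inside (0, 1); a recall-everything calibration
  target returns a tiny positive floor rather than 0.
* Cohort CSV output renders scores with 17 significant digits so
  write-then-read is the identity on doubles, and output is byte-stable.
* Degenerate inputs: empty cohorts are valid (filters and writers handle
  zero rows); an all-zero trend table returns p = 1 by convention.
* The test suite checks the engine against an independently written
  per-episode brute-force oracle on a 64-episode truth table covering
  every combination of reader opinions, arbitration, cancer status and AI
  score level; marginal recovery of the generator at n = 200,000;
  bootstrap coverage at 500 × 2,000-episode cohorts against an
  integration-derived truth; and the power simulator against exhaustive
  multinomial enumeration at 5 positives. These sizes keep the full suite
  under a minute on one CPU while leaving Monte-Carlo error well inside
  the asserted tolerances.

## Known limitations

Simulated triage workflows assume reader behaviour is unchanged by AI
presence and by workload; panel behaviour for never-reviewed episodes is a
two-parameter Bernoulli model; the reference standard excludes interval
cancers; and the generator's joint opinion law is a deliberate
single-parameter simplification. Conclusions about any *specific* service
require its own episode table, which the cohort reader accepts directly.
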