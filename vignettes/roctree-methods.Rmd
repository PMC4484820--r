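---
title: "Kappa-maximizing ROC recursive partitioning for remission prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kappa-maximizing ROC recursive partitioning for remission prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roctree)
library(dplyr)
```

## The problem

Fewer than half of patients with major depressive disorder (MDD) reach
symptomatic remission — a 17-item Hamilton Rating Scale for Depression
(HRSD17) score of 7 or less after eight weeks — on their first
antidepressant. A pre-treatment measurement that reliably *rules out*
a medication for an identifiable subgroup would shorten the
trial-and-error cycle of current practice. Structural MRI supplies
candidate measurements at clinical scale: gray-matter volumes for the
116 regions of the AAL parcellation (mL) and mean fractional
anisotropy (FA, a unitless diffusion coherence index in $[0,1]$) for
46 white-matter tracts of the JHU ICBM-DTI-81 atlas.

`roctree` implements the full analysis pipeline for this design: a
signal-detection (ROC) recursive-partitioning tree builder over such
feature tables, independent-cohort validation of the resulting
decision rules, subsampling cross-validation of rule specificity,
serial/parallel rule combination, and a seeded synthetic cohort
generator that plants known decision trees so every stage is testable
without patient data.

## The partitioning procedure

At a node holding subjects $S$, every observed value $v$ of every
candidate predictor $x$ defines a split $\{x \ge v\}$ versus
$\{x < v\}$. Each candidate is scored by Cohen's kappa between branch
membership and the remission label,

$$\kappa = \frac{p_o - p_e}{1 - p_e},$$

with $p_o$ the observed agreement of the branch-based classification
and $p_e$ its margin-expected agreement; maximizing kappa maximizes
sensitivity and specificity jointly. The best candidate is the one
with the largest kappa whose association reaches significance, and it
splits the node; the search recurses into both branches and stops in
any branch where no candidate is significant. Every node reports its
remitter/non-remitter counts and remission probability. A root-to-node
path whose subjects are at least 80% non-remitters is an *actionable
rule*: a conjunction of threshold conditions proposed as a clinical
rule-out test.

Decisions the procedure's description leaves open, and how this
implementation fixes them:

* **Significance test.** Two-sided Fisher's exact test on the
  candidate's 2×2 table, with the stopping rule $p < \alpha$,
  $\alpha = 0.01$ by default. An exact test remains valid at the small
  node sizes partitioning produces. (The same exact test is the
  published choice for per-cut-point replication.) No multiple-testing
  correction is applied across candidates — method-faithful, not
  statistically conservative; the significance gate is a stopping
  heuristic, not a calibrated error rate.
* **Tie-breaking.** Among equal-kappa candidates: smaller p-value,
  then the predictor listed earliest in the caller's feature order,
  then the smaller threshold. Fitting is therefore fully
  deterministic.
* **Boundary and direction.** Thresholds use $\ge$ on the high side
  everywhere; the branch with the higher non-remission proportion is
  recorded as the "positive" (predicted non-remission) side at fit
  time and never re-inferred when a stored tree is applied. A subject
  exactly at a threshold follows the $\ge$ branch.
* **Minimum node size.** Both branches of a candidate must hold at
  least 2 subjects; below that Fisher's test is degenerate.
  Candidates with a degenerate margin (kappa undefined, reported as 0)
  are never selected.
* **Missing features.** Candidate tables use complete cases per
  feature. A subject missing the feature chosen for a split cannot be
  routed past it and is counted as unrouted (fitting) or unclassified
  (application) rather than imputed.

Computationally, candidate tables for all thresholds of a feature are
built in one sorted pass, and exact p-values are evaluated lazily down
the kappa-ordered candidate list after pruning candidates whose
hypergeometric point probability already exceeds $\alpha$ (the
two-sided Fisher p is bounded below by the observed table's point
probability, so such candidates can never pass the gate). The selected
split is identical to the brute-force search, which the test suite
verifies by exhaustive comparison.

## Validation statistics

* **Replication test.** A rule that classified $k$ of $n$ selected
  validation-cohort subjects correctly is compared with its
  test-cohort accuracy $p_0$ by the one-sided lower-tail exact
  binomial probability $P(X \le k \mid n, p_0)$. For example, 9 of 13
  against $p_0 = 0.90$ gives $p = 0.034$ — a significant failure to
  replicate.
* **Chance test.** Selection performance is compared with chance
  using the population remission rate (default 35%, the prevalence
  observed across large antidepressant cohorts): the upper-tail exact
  binomial probability of at least $k$ non-remitters among $n$
  selected at success probability $1 - 0.35$. The exact tail is
  reported throughout. (For the published node counts 26/29 and 31/38
  the exact tails are ≈0.003 and ≈0.020; the corresponding printed
  values, 0.002 and 0.019, evidently come from a slightly different
  computation that is not described; the discrepancy is immaterial at
  the decision level and the exact tail is retained.)
* **Group characterization.** Selected non-remitters are compared
  with non-selected groups variable by variable: pooled-variance
  independent t-tests for continuous measures (Welch available by
  flag) and Pearson chi-square without continuity correction for
  binary ones, with no multiplicity correction — matching how such
  cohort tables are conventionally presented.
* **Subsampling cross-validation.** Because the validation cohort's
  non-remission rate is much higher than the test cohort's, rule
  specificity is also estimated by drawing 1000 random subsamples of
  100 subjects *without replacement* from the pooled cohort
  ("randomly chosen" participants, not a with-replacement bootstrap;
  with-replacement is available by flag), applying the fixed rule, and
  summarizing the per-subsample specificity (non-remitters among
  selected) and coverage (selected among non-remitters) as mean ± sd.
  Subsamples where the rule selects nobody have undefined specificity;
  they are excluded from the summaries and counted. With the
  subsample size equal to the pooled size every draw is the full
  cohort and the sd is exactly 0 — a degenerate case the tests pin
  down.

## The synthetic cohort generator

No subject-level data accompany the study, so the generator is a
first-class module: it emulates the *structure* the analysis assumes,
with planted ground truth, and its defaults reproduce the published
cohort layout (`ispotd_config()`):

* two cohorts — test (76 subjects with usable volumetric scans, 74 of
  them with usable DTI) and validation (83 subjects) — with planted
  decision trees at the published cut-points: left middle frontal
  gyrus volume 14.82 mL then right angular gyrus volume 6.25 mL
  (leaf compositions 25/33, 7/14, 3/29 remitters in the test cohort),
  and FA 0.63 (left cingulum, cingulate portion), 0.54 (right
  superior fronto-occipital fasciculus), 0.50 (right superior
  longitudinal fasciculus) with leaf compositions 17/22, 2/20, 2/13
  and the residual node 13/19 implied by subtraction;
* subjects are first assigned to planted leaves in exactly the target
  counts, the label is drawn per leaf (Bernoulli by default; an
  `"exact"` mode places exactly `round(p * n)` remitters per leaf so
  printed node compositions are reproduced by construction);
* each split feature is drawn from a normal distribution truncated to
  the leaf's side of its threshold; all other ("noise") features are
  drawn independently of the label, truncated to their domain
  (volumes > 0, FA in $[0,1]$).

Choices the study leaves open:

* **Feature distributions.** Nothing is published about ROI volume or
  FA distributions beyond the cut-points. Defaults are normals with
  the planted features centred on their thresholds (so both sides of
  every split are populated) and generic scales elsewhere (volumes
  10 ± 2 mL, FA 0.50 ± 0.06); all means/sds are configurable. The
  synthetic anatomy is *not* calibrated to real morphometry, and no
  spatial covariance between neighbouring regions is simulated —
  passing tests demonstrate correctness of the procedure, not
  real-data effect sizes.
* **Two modalities, one label.** A subject's label cannot be driven
  by two planted trees at once. The designated label tree (volumetric
  by default, matching the modality whose tree survived validation)
  drives remission; the other tree's leaf membership is then drawn
  *conditional on the label* from the composition its leaf counts
  imply, which reproduces that tree's node counts in expectation.
* **Validation leaf allocations.** Only the actionable nodes'
  validation compositions are published (31/38 volumetric; 9/13 and
  5/6 DTI). The remaining validation leaves are fixed synthetic
  choices consistent with the cohort size (83) and its 20 remitters.
* **Missing scans.** The two test-cohort subjects without usable DTI
  are represented by leaving all 46 FA features `NA` for two subjects
  whose labels keep the DTI-complete composition at 34 remitters / 40
  non-remitters.
* **Clinical covariates** are drawn from the published cohort summary
  statistics (e.g. age 34 ± 12, baseline HRSD17 ≈ 21.5 ± 3.5,
  arm-specific doses 13 ± 5 / 61 ± 27 / 100 ± 35 mg/day), independent
  of the imaging features; the week-8 HRSD17 score is drawn
  conditional on the label so that `remitted == (hrsd17_week8 <= 7)`
  holds identically.
* **Randomness.** One integer seed governs a whole cohort through R's
  Mersenne-Twister stream; the generator records the algorithm and
  seed in the output's `generator` attribute, and identical
  config + seed is bit-identical.

Alongside the stochastic generator, `ispotd_pooled_cohort()` builds a
*deterministic* pooled table (157 subjects) whose joint membership in
the volumetric and DTI selections reproduces every published selection
count exactly — including the serial (10 selected, all non-remitters)
and parallel (76 selected, 63 non-remitters) combinations, whose joint
composition is implied uniquely by the published margins through
inclusion–exclusion. This fixture anchors the worked-example tests and
the reproduction script.

## Numerical and degenerate-input policy

* Kappa returns 0 for degenerate margins instead of 0/0.
* Exact binomial tails are computed by `pbinom` summation; the test
  suite checks them against independent log-factorial summation to
  1e-12 on $n \le 200$, and the Fisher p against hypergeometric
  enumeration under the probability-ordering rule.
* Candidate thresholds are observed values only; the candidate at the
  feature minimum (empty `<` branch) is dropped; a constant feature
  contributes no candidates.
* Empty cohorts, single-class subsamples, rules selecting nobody, and
  subjects missing a routed feature all have defined, tested
  behaviour (error, no-split, counted-undefined, and unclassified
  respectively).
* Tree JSON is written with 17 significant digits so serialization
  round-trips IEEE doubles exactly.

## What recovery means under label noise

With noise-free planted labels, the planted cut-point is the unique
kappa maximizer and the fitted tree reproduces the planted features,
thresholds and directions exactly (the suite constructs such cohorts
deterministically). With noisy leaf rates the recovered *region* is
stable — at $n = 150$ with the volumetric tree's published leaf rates,
or with 0.9/0.1 leaf contrast, the root feature is recovered in
effectively every simulation (the suites require ≥ 95/100) — but the
recovered *threshold* is an observed order statistic whose position
jitters by a few observations around the planted cut: a single
mislabeled subject adjacent to the boundary legitimately moves the
empirical kappa argmax, and truncated sampling concentrates
observations exactly there. Threshold identity is therefore asserted
only in the noise-free construction; under noise the recovered cut is
checked to lie well inside the planted feature's support.

The simulation scales used by the suites — 100 seeded cohorts of 150
subjects with a 20-region candidate set for recovery, 1000×100 for the
subsampling cross-validation — are the package's chosen verification
sizes: large enough for the stated rates to be sharp, small enough to
run routinely.

## Worked example

```{r example}
report <- run_pipeline(
  config = ispotd_config(label_mode = "exact"),
  modality = "volumes", n_iter = 200, seed = 11
)
report$rules$path
report$validation |> select(rule, n_selected, n_correct, accuracy,
                            p_vs_reference, p_vs_chance)
glance(report$bootstrap)
```

And the published-count fixture:

```{r fixture}
pooled <- ispotd_pooled_cohort()
pooled |>
  apply_rules(ispotd_rules("volumetric")) |>
  evaluate_selection(reference_accuracy = 26 / 29)
```

## Limitations

* The generator reproduces marginal and planted-tree structure, not
  anatomy: no inter-regional covariance, no site or scanner effects,
  no longitudinal HRSD17 trajectory beyond the week-8 endpoint.
* The raw $p < 0.01$ stopping rule overfits by construction (the
  recursive search tests thousands of candidates); deep splits on
  noise features appear routinely in simulation exactly as the method
  allows. The package reports what the procedure finds; it does not
  prune or correct.
* Chance tests depend on the assumed 35% population remission rate;
  sensitivity to that choice is the caller's to explore.
* Serial/parallel combination covers two rule sets; no probability
  calibration or cost-sensitive thresholding is attempted.
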