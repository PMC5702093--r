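---
title: "Classifying need for personal support and deriving allocation guidelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying need for personal support and deriving allocation guidelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psalloc)
```

## The problem

Home-care programs allocate paid help with daily activities ("personal
support") largely by clinical judgment, which produces wide variation in
hours received by patients with comparable needs. `psalloc` implements a
decision-support pipeline for this problem: standardised assessment items are
summarised into clinical scales, a decision tree classifies each patient into
one of six ordered need groups, historical billed hours per group define
percentile guideline bands, and a derivation engine lets analysts re-derive
such trees from their own cohorts. Because the administrative cohorts behind
the published algorithm are not publicly available, the package also ships a
calibrated synthetic-cohort generator so every step is exercisable, testable
and reproducible without any data access.

## Clinical scales

Five summaries are computed from the raw items (`scale_profile()`):

* **Self-Reliance Index** — impaired when daily decision making shows any
  difficulty (code ≥ 1) or when any of bathing, personal hygiene, dressing
  lower body, walking indoors/outdoors or locomotion needs supervision or
  physical help (code ≥ 2). This binary indicator is the classifier's root.
* **ADL Short Scale (0–16)** — sum over personal hygiene, toilet use,
  locomotion and eating of a 0–4 dependence recode of the 0–6/8
  self-performance codes. The recode ships as a CSV resource
  (`adl_recode_table()`) so it can be corrected without touching code.
* **ADL Hierarchy (0–6)** — hierarchical score over the same four items that
  ranks dependence in late-loss activities (eating, toilet use) above
  equivalent dependence in early-loss activities (hygiene, locomotion).
* **Cognitive Performance Scale (0–6)** — graded from decision making,
  short-term memory, making self understood and eating.
* **IADL Difficulty (0–6)** — sum of the 0–2 difficulty codes for meal
  preparation, ordinary housework and phone use.

Code 8 ("activity did not occur") is treated as total dependence throughout
— a deliberately conservative reading: a person for whom bathing never
occurs is assumed to need rather than decline it.

The algorithm's published description names these scales without restating
their formulas; the implementations follow the published interRAI/MDS scale
definitions. Two of its verbal phrases are genuinely ambiguous and resolved
here as data-model choices: "walking (or wheeling) indoors or outdoors" is exposed as three
items (walking indoors, walking outdoors, locomotion), any of which triggers
the index; and "communication difficulties" in the highest-need branch is
taken as *making self understood* ≥ 2.

## The classifier

The classifier is entirely table-driven (`psa_treespec` JSON): split nodes
carry a variable, strictly increasing cut points and children; a value `x`
follows the first branch with `x < cut`, else the last branch. This
left-closed convention is part of the schema, so classification is
deterministic and reproducible from the tree file alone. The bundled
reference tree (`psa_reference_tree()`) is a *declared reconstruction* of the
published six-group algorithm: the narrative structure is faithful, but the
exact printed tree and its cut points are not public, so the defaults are
documented, configurable data:

* "low ADL impairment" = ADL Short ≤ 2; the moderate/high boundary at 11;
* "some impairment in daily decision making" = code ≥ 1;
* "great difficulty with IADLs" = IADL Difficulty ≥ 5 (the published band);
* "cognitive impairment" = CPS ≥ 3 (the published moderate band);
* bladder/bowel incontinence "at least weekly" = code ≥ 2;
* sublevels 1A/1B/1C ordered by increasing IADL difficulty (≤ 1, 2–4, ≥ 5),
  consistent with the convention that higher labels mean greater need — the
  publication lists the sublevels without defining their order.

Two properties are enforced by test sweeps over the discretised input
domain: *totality* (every input reaches exactly one terminal; the label set
is exactly {1A, 1B, 1C, 2, …, 6}) and *order consistency* (worsening any
single need indicator never lowers the top-level group).

## The derivation engine

`psa_tree(formula, data)` re-implements the derivation method as a classic R
model fit. At each node every candidate partition of every candidate
variable is scored by the one-way ANOVA F statistic on the target
(variance-reduction splitting): all `c − 1` binary cuts of a variable with
`c` observed levels, plus all `choose(c − 1, 2)` contiguous 3-way partitions
when multi-way splitting is allowed. The raw p-value of each candidate is
Bonferroni-multiplied by the **total number of candidate partitions at the
node across all variables**. This node-level multiplicity is a deliberate
design choice: adjusting within each variable separately would still test
many variables per node and inflate the family-wise false-split rate well
above the nominal level, whereas the node-level product keeps the
probability of any split on pure-noise data at or below `alpha` (verified by
a 500-replicate null simulation in the test suite). Defaults mirror the
published protocol: at most six levels in the tree, at least 100
observations per terminal node, `alpha = 0.05`, binary splits preferred.

Numerical and procedural details that the method description leaves open:

* **Tie-breaking** among equal adjusted p-values is deterministic: binary
  before multi-way, then the smaller first cut, then the lexicographically
  smaller variable name. Growth is therefore fully reproducible; the
  recorded seed only pins provenance.
* **Forced first variable** reproduces interactive growth ("entering known
  covariates as the first variable"). A forced root split is an explicit
  analyst override: it bypasses the significance gate but still respects the
  minimum leaf size. All automatic splits require adjusted p < `alpha`.
* **Missing split values**: rows missing the evaluated variable are excluded
  from that variable's evaluation and leave the tree at the node where the
  chosen variable is missing; exclusions are messaged. No surrogate splits.
* **Leaf collapsing** (`collapse_leaves()`) mirrors the manual step of
  combining terminals with similar averages: leaves are sorted by mean and
  partitioned into `k` contiguous groups minimising leaf-size-weighted
  within-group sum of squares by exact dynamic programming. `k` remains the
  analyst's choice, as it was in the original working group. Group means
  must come out strictly increasing; ties across a boundary raise a warning
  rather than silently producing indistinguishable groups.
* The 70/30 derivation/validation split (`partition_cohort()`) is a seeded
  simple random partition.

## Dependent variables and cohort filters

The primary target is **weekly billed hours** (`weekly_billed_hours()`):
personal-support services within a half-open 12-week window after the
assessment, `(assessment_date, assessment_date + 84 d]`; total hours divided
by the first-to-last-visit span in days and multiplied by 7. The span is
floored at one day — the published formula is undefined for single-visit
patients, and the guard makes such patients visible (`single_visit_flag`)
instead of dropping them. "Less than three weeks of active service" is
operationalised as a span under 21 days. The secondary target converts the
assessment's 7-day-lookback aide plus homemaking minutes to hours per week.

Derivation filters run structural rules first (assessed in hospital;
case-management/placement-only; under three weeks of service) and compute
the 99th-percentile utilisation ceiling on the *remaining* cohort, so the
ceiling reflects the analytic population. The computed ceiling is returned
(`p99_threshold`), and passing it back re-applies the identical filter set —
the operation is idempotent *given* the ceiling; recomputing the percentile
on filtered data would necessarily trim a further 1% each pass. Exclusions
use first-match accounting so the ledger columns sum exactly to the input
size. The guideline-path filters (congregate settings; waitlisted with no
service; Groups 3–6 with no service) deliberately keep the highest
utilisers.

## Validation metrics and guideline bands

`explained_variance()` is `1 − SSE/SST` with group means as predictions —
the R² of regressing hours on group indicators. `model_cv()` is `100 ×`
within-group RMSE divided by the grand mean; the published table reporting a
"coefficient of variation" near 100 does not state its formula, so this
definition is a documented reconstruction consistent with case-mix
conventions. `group_ratio()` divides the highest group mean by the lowest.
`stratified_fit()` repeats the three metrics within region or year strata
and summarises their range, the consistency check used to validate the
algorithm across regions and over time.

Guideline bands (`build_guidelines()`) are the 20th/35th/50th/65th/80th
percentiles of hours per group, computed with the linear-interpolation
quantile rule (R type 7) — fixed so bands are reproducible. The inner band
can be narrowed (e.g. 45th–55th) via the `inner` argument.
`allocation_zone()` makes the band semantics exact: *typical* within
[p35, p65] inclusive, *occasional* within [p20, p80] but outside the inner
band, *exceptional* beyond — boundaries are inclusive toward the centre so
the three zones partition the hours line with no gaps or overlaps.
`statutory_check()` encodes the statutory ceilings (120 h in the first
30-day period, 90 h in any later one) inclusively — "up to" the ceiling
passes — with exemptions (long-term-care waitlist, end of life,
extraordinary circumstances) suppressing the flag but always logged.

## The synthetic cohort generator

`generate_cohort()` emulates the joint structure the published tables
constrain, and nothing more:

* **Group shares** 6.4 / 45.5 / 28.2 / 7.6 / 6.6 / 5.7% for Groups 1–6,
  with Group 1 split evenly across 1A/1B/1C (the source reports Group 1
  only in aggregate).
* **Hours models** per group. Group 1 is zero-inflated — 80% exact zeros
  with a small lognormal positive part — because its printed interquartile
  range is all zeros (quartile calibration is impossible at zero) and its
  mean is 0.4. Group 3 uses gamma moment calibration
  (`fit_moment_gamma()`, mean 4.8, SD 4.3), which reproduces mean and SD
  exactly in expectation. Groups 2, 4, 5 and 6 use lognormal quantile
  calibration (`fit_quantile_lognormal()`): the median is matched exactly
  and the quartiles by least squares on the log scale, with a warning when
  a two-parameter lognormal cannot reproduce both printed quartiles within
  10% (Group 6's printed quartiles are such a case; its median — the
  quantity the calibration target cares about — is still exact). Two modes
  exist because printed means and quartiles are generally not jointly
  attainable in one two-parameter family.
* **Assessment records** are drawn from group-tailored proposal
  distributions over the item space and accepted only if the reference tree
  classifies them into the requested group, so generated records round-trip
  through the classifier by construction. Marginal rates of non-classifier
  fields (age, sex, living alone, settings) approximate the published
  cohort description; no attempt is made to reproduce the joint
  distribution of item prevalences, which is unidentifiable from published
  margins.
* **Billing logs** decompose each drawn weekly target into visits of
  0.25-hour granularity: a service span `s` (21–83 days, so generated
  patients pass the three-week filter and stay inside the 12-week window)
  and a quarter-hour total `k` are chosen so the realised
  `7 × 0.25k / s` best approximates the target — a rational approximation
  that recovers targets above ~0.1 h/week to well under 2% relative error.
  At least two visits are always scheduled so the span is realised;
  per-visit durations are capped at 4 h and visits spread evenly across the
  span.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: informative missingness (generated records are
complete), regional heterogeneity, measurement error in the assessment
items, within-person correlation between the hours level and item patterns
beyond group membership, and hospital or service interruptions. Results on
synthetic cohorts validate the *machinery*, not the clinical performance of
the algorithm on any real population.

## Problem sizes and numerical tolerances

The test suite exercises: the full discretised classifier domain (~1.1
million combinations) for totality and order consistency; cohorts of
10,000 for share recovery (3 binomial standard errors); 50,000 single-group
pipelines for hours-calibration recovery (2% relative on the Group 3 mean,
5% on the Group 6 median); 500 null replicates at n = 400 with five
independent ordinal features for the type-I property; 100 seeded runs at
n = 2,000 for planted-split recovery (step height twice the noise SD);
200 random tree/data pairs for the monotone-collapse property; and
brute-force cross-checks (ANOVA via `lm`, manual quantile interpolation,
exhaustive split enumeration) at 1e-10 tolerance on instances of up to 12
rows. These sizes were chosen so each property is measured with comfortable
statistical margin while the whole suite stays quick to run.

## Known limitations

* The reference tree is a reconstruction: 16 terminal nodes expressing the
  published narrative, not the original 25-leaf structure, and its cut
  points are defaults, not recovered constants. Analyses requiring the
  original instrument must treat results as indicative.
* The engine handles continuous targets only, with no surrogate splits and
  no cross-validation pruning (the original method validated on a held-out
  sample rather than pruning; `partition_cohort()` supports the same
  workflow).
* `model_cv()` is a reconstruction of an unstated formula; comparisons to
  published coefficient-of-variation values are order-of-magnitude only.
* Exact replay of the original interactive derivation (roughly twenty
  manually grown trees) is impossible from the published record; the forced
  first variable and per-parameter control are the supported interactive
  levers.
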