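---
title: "Methods: auditing CT-report completeness and prioritizing parameters for abdominal wall reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: auditing CT-report completeness and prioritizing parameters for abdominal wall reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stampc)
```

## The problem

Surgeons planning abdominal wall reconstruction (AWR) for complex ventral
hernias depend on preoperative CT, yet radiology reports routinely omit the
hernia-specific measurements the operation is planned around: defect width,
the plane of previously implanted mesh, the Tanaka index, concurrent
hernias. `stampc` implements, as reusable and tested code, the two halves
of the analysis behind the STAMP-C reporting framework:

1. a **completeness audit** that scores each CT report against operative
   and registry ground truth for 16 consensus parameters, and
2. an **AHP-weighted multi-criteria decision analysis (MCDA)** that
   aggregates three evidence sources into a prioritization of those
   parameters, a three-tier classification, and the STAMP-C essential
   panel.

Because the original registry, report abstractions and survey responses
are not public, the package ships a seeded synthetic-cohort generator
whose defaults are parameterized from the published cohort tables; the
published per-parameter counts, final scores and AHP weights are carried
as reference inputs (`reference_documentation_counts()`,
`reference_final_scores()`, `reference_ahp_weights()`).

## The parameter catalog

`load_parameter_catalog()` fixes the analysis axis: 16 parameters, eight
*generalizable* (assessable on any CT — defect width/length, number of
defects, EHS location, Tanaka index, hernia content, rectus measurements,
patient habitus) and eight *patient-specific* (conditional on surgical
history — prior mesh, old mesh plane, central mesh fracture, mesh
migration, concurrent inguinal and parastomal/stomal hernias, wall
abnormalities, ongoing surgical site occurrences). Ids are snake-case
slugs used as join keys by every downstream table; seven parameters carry
a STAMP-C letter (C maps to the two concurrent-hernia parameters).

## The completeness audit

Documentation is binary: a report either explicitly addresses a parameter
or it does not. The audit statistic is a percentage with a
category-appropriate denominator:

* generalizable: `100 * documented / n_cohort` — always in [0, 100];
* patient-specific: `100 * documented / occurrence`, where occurrence is
  the count of patients in whom the finding was confirmed
  intraoperatively. This "percent of occurrence" can exceed 100 when
  radiologists over-call findings not confirmed at surgery.

Two denominator conventions matter and are fixed in code. The occurrence
for `old_mesh_plane` is the prior-mesh-present count (a plane exists iff a
mesh does); with the published counts this gives 10/593 = 1.7%. A
patient-specific parameter with zero occurrence has an *undefined* rate —
`documentation_rate()` raises an error rather than reporting 0, since "no
report documented it" and "there was nothing to document" must not be
conflated.

Summaries use the midpoint median (mean of the two central order
statistics for even counts) and the min–max range, per category and
pooled over all 16 rates (`category_summary()`, `overall_summary()`). The
pooled overall median mixes the two denominator conventions deliberately:
that is how the original headline figure was defined. One discrepancy is
worth stating plainly: pooling the sixteen published rates gives a
midpoint median of 32.0 (central order statistics 31.4 and 32.6), while
the published overall headline is 34.4 — exactly the mean of the 9th and
10th order statistics rather than the 8th and 9th. The package computes
the standard median and does not adopt a nonstandard convention to absorb
the difference; the acceptance test records it. The per-category medians
(24.2 generalizable, 87.8 patient-specific) follow the standard convention
and reproduce exactly. Display rounds percentages to one decimal, but all
internal comparisons carry full precision with a ±0.1 tolerance, because
the published tables are themselves inconsistent at the last digit
(215/593 = 36.26% is printed as 36.2%).

## The synthetic cohort generator

`generator_config()` defaults *are* the published study conditions; they
are not tuning knobs. The emulated cohort is 834 elective TAR patients
with recurrent incisional hernias:

* **Ground truth** (`generate_registry()`): prior mesh prevalence 0.711;
  marginal prevalences 0.101 (central mesh fracture), 0.092 (migration),
  0.041 (each concurrent hernia type), 0.300 (wall abnormalities), 0.277
  (ongoing SSO). Fracture and migration are sampled only among
  mesh-present patients at conditional rate `marginal / 0.711`, so the
  configured marginals are recovered. The mesh plane mix among
  mesh-present patients is onlay 0.30 / sublay 0.56 / underlay 0.14.
  Defect width and length are normal (17.0 ± 6.8 and 24.0 ± 6.2 cm)
  truncated at 0 by rejection; the number of prior repairs follows the
  published distribution over 1–5 (normalized, as the printed percentages
  sum to 100.1).
* **Reports** (`generate_report_abstractions()`): generalizable
  parameters are documented with their published unconditional rates
  (e.g. defect width 272/834). Patient-specific parameters have two
  channels, P(documented | present) and P(documented | absent). The
  second is the over-calling channel, which is how documented counts can
  exceed occurrence; the original analysis attributes rates like 241.2%
  to radiologists flagging incidental or sub-threshold CT findings. By
  default the four over-called parameters take
  P(documented | present) = 1 with P(documented | absent) solved by
  `calibrate_overcall()` to match the published totals, and the
  under-documented parameters take the published rate as sensitivity with
  no over-calling — the simplest calibration consistent with published
  totals that never split documented counts by ground-truth status. Plane
  documentation is only possible in reports that document mesh presence
  (10/215 conditional default).
* **Survey** (`generate_survey()`): the response model is a latent normal
  clamped to [1, 10] and rounded — the simplest bounded discrete model
  able to reproduce every published mean ± SD pair. The response
  distribution shape was never published; this is a modeling choice.
  `calibrate_truncated_likert()` solves (mu, sigma) against the exact
  moment sums over the 10 support points (Nelder–Mead on squared moment
  error, required accuracy 1e-3 on both moments). Feasibility is bounded
  by the two-point distribution: no distribution on [1, 10] with mean m
  has SD ≥ sqrt((10 − m)(m − 1)), and infeasible targets error with the
  feasible range. A target SD of 0 is handled degenerately (all ratings
  equal the rounded mean).

One user seed expands into fixed per-stage substreams (registry, reports,
survey, sensitivity), so each stage is independently re-runnable yet the
whole pipeline is reproducible; identical seed and config give
byte-identical CSV/JSON artifacts.

`expected_documentation_rates()` returns the closed-form audit rates a
configuration implies, which the recovery tests compare against at
n = 50,000: documentation probabilities recover within 2 percentage
points, and over-call ratios within 5% relative — the ratio of two
binomial counts at occurrence prevalence 0.041 carries roughly 1.5–3%
relative sampling noise even at that cohort size, so a 2-point absolute
band would be below the noise floor for a 241% rate.

## The AHP engine

Criterion weights come from a Saaty pairwise comparison matrix: positive,
reciprocal, unit diagonal, entries on the 1–9 scale (strictness is
configurable; out-of-scale entries degrade to warnings when
`strict_saaty = FALSE`). `ahp_weights()` extracts priorities by the
principal right eigenvector (power iteration, successive normalized
iterates within 1e-12 in max norm, 10,000-iteration cap), Saaty's original
method; row geometric means are exposed as a cross-check and coincide
exactly on perfectly consistent matrices. `lambda_max` is the mean of the
component-wise Rayleigh ratios `(M w)_i / w_i` — standard AHP practice
and exact at the true eigenvector. Consistency uses
`CI = (lambda_max − n)/(n − 1)` and `CR = CI / RI(n)` with Saaty's
classic random-index table (orders up to 10; larger orders are an error),
and the conventional acceptability rule CR < 0.10; CR is defined as 0 for
n ≤ 2. The original analysis reported weights (0.406, 0.323, 0.271) for
(systematic review, expert audit, surgeon survey) with CR = 0.082 from a
matrix published only in supplementary material, so those weights are
reference inputs here, not recomputed quantities.

## The MCDA prioritizer

`mcda_prioritize()` normalizes each source column, aggregates
`final = scale_factor * sum_s w_s * normalized_s`, then ranks and tiers.
Three normalizations are provided — `sum_to_100` (default), `min_max`,
`z_score` — with constant columns rejected as degenerate under the latter
two. The published final scores (14.51 down to 3.58, summing to about
134) cannot be reproduced without the supplementary raw source scores, so
the scale is configurable and the published scores load as reference
input through `rank_and_tier()`.

Tiers use fixed thresholds, closed at the top boundary: Tier 1
(Essential) for scores ≥ 9.0, Tier 2 (Highly Recommended) on [6.0, 9.0),
Tier 3 (Recommended) below. The thresholds were derived empirically from
natural score clustering in the original analysis and are taken as given
numbers here — no clustering is re-run. Ties break by catalog order with
consecutive ranks, a determinism choice with no published guidance.
`stampc_panel()` defines panel membership as Tier-1 membership (seven
parameters with the published scores, including the 9.52 of concurrent
inguinal hernias); a Tier-1 set other than the canonical seven warns but
still emits the panel from the tiers.

`weight_sensitivity()` perturbs the weight vector with Dirichlet draws
centered on the baseline (`alpha = concentration * baseline`;
concentration 100 keeps draws within a few percent of baseline),
recomputes the full prioritization per draw, and reports the fraction of
draws whose top-k identity set (k = baseline Tier-1 size) matches
baseline plus the mean Kendall tau against the baseline ranking. The
perturbation mechanism behind the original stability claim was
unspecified; a Dirichlet centered on the baseline is the standard simplex
perturbation.

## Supporting statistics

`cohens_kappa()` implements two-rater chance-corrected agreement for
binary abstractions (the three-reviewer design is handled pairwise, since
Cohen's statistic is two-rater); po = pe = 1 conventionally yields kappa
1. `chi_square_2x2()` is the Pearson statistic with optional Yates
correction (off by default; the choice was unspecified in the source
analysis), df = 1, p from the chi-square survival function; zero margins
are an error. `likert_summary()` reports sample means and sample SDs
(n − 1), with SD undefined (not 0) for a single rater.

## Worked example

```{r example, eval = FALSE}
cfg <- generator_config(seed = 2026)      # the emulated study conditions
cohort <- generate_cohort(cfg)
rates <- audit_cohort(cohort)
overall_summary(rates)

res <- rank_and_tier(reference_final_scores())
stampc_panel(res)

src <- generate_source_scores(generate_survey(61, seed = 2026),
                              default_source_inputs()$audit_ranks,
                              default_source_inputs()$literature_freq)
weight_sensitivity(src, n_draws = 500, concentration = 100, seed = 2026)
```

`run_pipeline()` chains simulate → audit → prioritize → sensitivity →
report, writing `rates.csv`, `summary.json`, `mcda.csv`, `stampc.json`,
`sensitivity.json` and a STAMP-C-ordered `report.md` beside a frozen YAML
config echo and an MD5 manifest; a failing stage aborts with its name and
removes partial artifacts.

## Problem sizes, defaults and limitations

The test suite exercises generator recovery at cohorts of 20,000–50,000
patients (seconds on one core), the survey at its native n = 61, AHP
oracles at orders 3–8, and sensitivity at 500 draws — sizes at which the
stochastic checks have comfortable statistical margins while the full
suite runs in well under a minute.

What the synthetic data does *not* emulate: correlation between
parameters beyond the mesh-conditional structure (e.g. defect size and
wall abnormality are independent here), per-radiologist or temporal
variation in documentation behavior, report accuracy (a documented
parameter is not necessarily *correct* — the audit measures completeness
only, as did the original design), and the free-text reports themselves.
Passing recovery tests therefore demonstrates that the audit and
prioritization machinery is correct under the published marginal
structure, not that the generator reproduces a real EMR population.
Default expert-audit ranks and literature citation frequencies in
`default_source_inputs()` are synthetic stand-ins (only the top
parameter's rank and most-cited status were published) and are labelled
as such.
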