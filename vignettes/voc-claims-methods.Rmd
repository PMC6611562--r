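---
title: "Methods: VOC episode construction from administrative claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: VOC episode construction from administrative claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocepi)
library(data.table)
```

# Scope and model

`vocepi` turns claim-level service records into an epidemiological
description of vaso-occlusive crisis (VOC) burden in sickle cell disease
(SCD). The analysis object is the *episode of care*: a maximal cluster
of VOC-coded claims in which each claim begins no more than
`episode_gap_days` after the running end of the cluster. Everything else
— cohort entry, setting, complication status, visit reasons, rates — is
defined relative to these episodes and to a small set of ICD-9-CM code
sets that are held as data ([`study_config()`]), never hard-coded into
algorithms.

The package assumes day-resolution claims (Medicaid MAX-style extracts
carry no times), closed service intervals (both endpoints are service
days), and ordered diagnosis fields in which position 1 is the primary
discharge diagnosis.

# The episode grouper

The merge rule reads "claims without a 3-day gap form one episode" as:
claim *c* joins the current episode iff
`start(c) - end(episode) <= episode_gap_days`. A 3-day separation merges
and a 4-day separation splits; this matches the motivating example of
multiple ER presentations culminating in an admission within a 3-day
window being counted once, and the threshold is configurable for
sensitivity analysis. Claims are pre-sorted by
`(service_start, service_end, claim_id)` so the grouping is
deterministic; the partition itself is order-invariant, which the test
suite verifies by checking the greedy grouper against a brute-force
transitive-closure interval clustering on thousands of random claim
sets (the two provably coincide for interval data sorted by start).

Implementation note: greedy merging against the episode's running end
is computed vectorially against the per-patient cumulative maximum of
claim ends. These agree because whenever a new episode opens, its first
claim ends later than every earlier claim of that patient, so the
cumulative maximum is thereafter carried by the new episode.

Each episode's **setting** is the highest-priority place of service
among its member claims under the hierarchy
`inpatient > ER > outpatient > office > other`. A claim whose place of
service is missing from the configured hierarchy is a hard error rather
than a silent "other": claims feeds routinely contain surprise codes and
we prefer the pipeline to stop.

An episode is **complicated** when any claim — VOC-coded or not,
including the VOC claims' own secondary diagnoses — whose service
interval intersects the episode interval carries a code from a
complication category. Category attribution is reported twice: from
primary-position diagnoses only, and from any position. Both are kept
because the two rankings answer different questions (what the visit was
*for* versus what was *present*).

# Code sets and their provenance

Four code sets matter:

* `scd_codes` (282.41, 282.42, 282.60–282.69; twelve codes after literal
  range expansion) — cohort identification;
* `voc_episode_codes` (282.42, 282.62, 282.64, 282.69) — episode
  membership;
* `voc_primary_reason_codes` (the twelve-code SCD crisis list) — visit
  reason attribution;
* `trial_exclusion_codes` (V70.7).

The episode-definition list and the primary-reason list differ in the
source study design, and we keep them as two separate configuration
fields rather than reconciling them; users who consider this a
historical accident can set them equal in one line of JSON.

The authoritative SCD-complication code list is not publicly printed, so
the shipped `default_complication_categories()` is an **illustrative,
synthetic** mapping of the six commonly-named categories to ICD-9
prefixes (fever → 780.6x, DVT → 453.x, cerebrovascular → 430–438, and
so on). It keeps the pipeline runnable and testable; a real study must
supply its authoritative list via `load_config()`. Codes are stored
dot-less internally and matched dot-insensitively, because claims files
use both dialects. Configuration files are JSON only in this build (the
YAML parser is not part of the dependency footprint).

# Cohort rules and numerical conventions

Decisions that the source design leaves open, fixed here and used
consistently everywhere:

* **Month arithmetic.** "6 months" and "12 months" are day counts:
  183 and 365, both configurable. Day counts are reproducible; calendar
  months are not.
* **Age.** Completed years at the index date; `min_age` defaults to 18.
* **Enrollment.** Spans must carry both medical and pharmacy benefits;
  abutting spans (end *d*, next start *d + 1*) are continuous. The
  follow-up requirement demands continuity over the first
  `followup_min_days` only; `followup_end` is the end of continuous
  post-index enrollment capped at `study_end`, so later coverage gaps
  truncate exposure instead of excluding the patient.
* **Exclusion order.** First violated rule wins, in the order: no SCD
  claim in window, under age, insufficient baseline, insufficient
  follow-up, trial code (scanned over the whole study period), dual
  eligibility (any span, ever).
* **LOS.** Discharge minus admission in days, same-day stays count as
  1. The convention is arbitrary but documented and applied to baseline
  stays, follow-up stays and the generator alike.
* **ER visits.** One per patient per calendar day; an ER visit followed
  by an admission within `episode_gap_days` (or falling inside a stay)
  is absorbed into the inpatient visit. The absorption mirrors the
  episode grouper's treatment of ER-to-admission chains; it is the one
  place where the source description is genuinely silent about
  deduplication, so the behaviour is localized in `build_visits()` and
  controlled by the same gap parameter.
* **Quantiles.** Median and IQR use linear interpolation
  (`stats::quantile` type 7). Sample SD uses the n−1 denominator and is
  reported as 0 with an `n = 1` flag for singletons.
* **Percentages.** Computed before rounding, then rounded half away
  from zero at one decimal (`pct1()`), matching the printed style of
  claims-study tables; `round()`'s half-even rule would differ on
  boundary values.
* **Charlson index.** Deyo ICD-9 adaptation: 17 categories, weights
  (1×10, 2×4, 3, 6×2), one count per category, with the standard
  supersession rules (complicated diabetes over uncomplicated, severe
  liver disease over mild, metastatic tumour over primary malignancy).

Degenerate inputs are defined rather than accidental: no VOC claims →
empty episode table; zero cohort person-time → error; an empty episode
list flows through reporting as a zero block with an explicit
`rate_undefined` flag rather than a `NaN`.

# The synthetic generator: what it emulates, and what not

`simulate_claims()` exists so that every downstream stage has a
recoverable target. Its defaults *are* the stated world of the source
study, fixed once:

| parameter | default | origin |
|---|---|---|
| `voc_rate_mean` | 3.31 /person-year | published overall rate |
| `voc_rate_dispersion` | 0.24 | solves `P(N=0) = (1+mu/k)^-k = 0.523` at mu = 3.31, the published year-1 zero fraction |
| `setting_probs` | (1.06, 0.90, 0.51, 0.24, 0.09)/2.80 | published year-1 per-setting means |
| `p_complicated` | 0.297 | published complicated share |
| `category_probs` | (.259, .218, .162, .085, .082, .194) | published primary-only category shares; the unprinted remainder assigned to bone necrosis |
| `p_primary_reason_voc` | 0.85 | published share of acute visits with VOC primary |
| demographics | age/sex/race/region margins of the published baseline table | |
| `inpatient_los_days` | lognormal, meanlog log 5, sdlog 0.82 | median 5 and mean 7 days for VOC admissions |
| `claims_per_episode` | 1 + Poisson(0.7) | free parameter (no published fragmentation statistics); chosen so most episodes are 1–3 claims |
| `episode_duration_days` | 1 + Poisson(0.8), capped | free parameter; short ambulatory episodes |
| eligibility noise | 0 | clean by default; tests switch it on |
| `p_early_disenroll` | 0.1 | chosen once so mean follow-up lands near the published ~2.7 years given the identification window |

Construction guarantees, each covered by a test:

* within-episode claim gaps never exceed the merge threshold, and
  consecutive true episodes are separated by *more* than it, so the
  grouper can recover episode counts **exactly** on clean simulations;
* the first ("anchor") claim of an episode carries the true setting and
  all other claims strictly lower-priority settings, so hierarchy
  resolution is exact, and no stray ER/inpatient claims create phantom
  visits;
* complication codes appear only on claims inside complicated episodes'
  intervals;
* counts are Poisson given the patient's gamma rate and realized
  exposure, so the person-year rate estimator is unbiased for
  `voc_rate_mean` (episodes that no longer fit a crowded follow-up
  window are dropped, a truncation that only binds for extreme-rate
  patients);
* byte-identical output for identical `(params, seed)`.

What it does **not** emulate: cost and payment fields, pharmacy claims,
transfer chains between facilities, coding error and rule-out
diagnoses, state-level geography, and enrollment churn more complex
than a single injected gap. A green recovery test therefore establishes
the *algorithms* are faithful to their definitions — not that the
definitions themselves are robust to real-world coding noise. The
published headline counts (8,521 patients; 76,154 episodes) come from a
non-deposited national extract and are not reproducible at desk scale;
the acceptance layer instead checks the printed worked-example
arithmetic exactly and the generator-parameter recovery statistically
(three-standard-error bands across 20 seeds at 5,000 patients).

# Known limitations

* ICD-9-CM only; no ICD-10 bridge and no validity checking against an
  external ICD dictionary.
* The illustrative complication categories overlap real comorbidity
  codings imperfectly; results under the default categories are
  demonstrations, not clinical findings.
* The primary-reason attribution trusts the anchor claim's first-listed
  diagnosis; claims known to be miscoded will be mis-attributed.
* Rate summaries use 365.25-day person-years and attribute an episode
  to calendar position by its start date; episodes spanning the year-1
  boundary count in year 1 if they start there.

```{r demo}
cfg <- study_config()
res <- run_all(sim_params(n_patients = 300, seed = 1), cfg,
               file.path(tempdir(), "vignette-demo"))
res$report$episode_summary[c("total", "complicated", "rate_per_py")]
```
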