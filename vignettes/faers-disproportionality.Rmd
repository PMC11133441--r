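---
title: "Methods: disproportionality analysis of FAERS spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality analysis of FAERS spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous reporting systems such as FAERS collect voluntary reports of
suspected adverse drug events (ADEs). They have no denominator of exposed
patients, so absolute rates cannot be estimated; what can be asked is whether
a drug–event pair is reported *disproportionately* often relative to the
background of all other reports. `faersignal` implements that analysis for
FAERS-style quarterly ASCII extracts: ingestion, case deduplication,
primary-suspect cohort extraction, descriptive tables, and frequentist
disproportionality statistics (ROR and PRR) with the conventional signal
thresholds.

## Pipeline and counting units

1. **Parse** (`parse_faers_table`). The FAERS ASCII dialect is
   dollar-delimited with a header line and no quoting; files are read as
   Latin-1 (legacy extracts are not UTF-8 clean). Columns are located by
   header name, so layout revisions that add columns do not break parsing.
   Rows failing validation (malformed dates or numbers, unknown role or
   outcome codes, empty PTs, wrong field counts) are skipped and reported with
   line numbers, preserving the invariant
   `records + reported bad lines = data lines`.
2. **Deduplicate** (`deduplicate_demo`). FAERS carries multiple versions of
   the same case. The FDA-recommended rule is applied: per `CASE_ID` keep the
   largest `FDA_DT`, ties broken by the largest `PRIMARY_ID` (numeric
   comparison when every id in the table parses as a number; lexicographic
   otherwise, since a mixed table has no well-defined global numeric order).
3. **Cohort** (`build_cohort`). A report enters the target cohort when at
   least one drug row matches a search name (case-insensitive substring over
   both the verbatim name and the active-ingredient field — verbatim FAERS
   names carry doses and salts) **and** has the requested role code, by
   default primary suspect (PS). Secondary-suspect and concomitant mentions
   do not qualify.
4. **Events**. The unit of all downstream counting is the *event*: a distinct
   (report, normalized PT) pair. A PT repeated within one report counts once;
   PT matching is trim + whitespace-collapse + case-fold, while outputs show
   the most frequent verbatim casing. The background is formed by **all**
   other deduplicated reports in the extract, regardless of what their drugs
   are or which roles they carry — the 2×2 footnote convention "target event
   reports of other drugs" taken without restriction.

## The statistics

For each PT, with a/b/c/d as in the README's 2×2 layout:

* ROR = ad/(bc); 95% CI = exp(ln ROR ± z·√(1/a+1/b+1/c+1/d)) with z = 1.96.
  Any zero cell makes the estimate undefined (`NA`) rather than an error;
  setting `correction = TRUE` applies the Haldane–Anscombe +0.5 to all four
  cells instead. The correction affects only the ROR/CI: the PRR is left
  undefined at c = 0 regardless, because a corrected PRR would silently
  change the statistic being thresholded.
* PRR = [a/(a+b)]/[c/(c+d)]. This is the standard orientation under the cell
  labels above. (Published formula sheets sometimes print the transposed form
  [a/(a+c)]/[b/(b+d)], which compares within-event proportions and is
  inconsistent with the accompanying cell definitions; the standard
  orientation also reproduces the expected PRR ≤ ROR pattern for common
  events.)
* χ² is the uncorrected Pearson statistic, computed by its closed form; no
  Yates correction.
* Thresholds: ROR rule = (a ≥ 3) ∧ (CI lower bound > 1); PRR rule =
  (a ≥ 3) ∧ (PRR > 2) ∧ (χ² > 4). All inequalities are strict except the
  a-gate; undefined statistics never flag. No multiple-testing adjustment is
  applied — standard practice in this literature, flagged by a disclaimer in
  every run log, and the reason a flag is a hypothesis, not a finding.

Ranking (`rank_signals`) keeps rows where either rule fired and sorts by the
chosen key (ROR by default), ties broken by larger a, then PT alphabetically.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `z` | 1.96 | normal quantile of the CI (95%) |
| `min_a` | 1 | minimum a-cell for a row to appear in the signal table (the a ≥ 3 gate is applied inside the flags regardless) |
| `correction` | FALSE | Haldane–Anscombe +0.5 for the ROR with zero cells |
| `top_n` | 15 | row limit for PT/SOC/signal report tables |
| rounding | half-up | 1 decimal for demographic/outcome percentages, 2 for PT/SOC — the precisions these tables are conventionally printed at |

Percentages are computed in exact integer arithmetic
(`percent()`), so round-half-up decisions are never at the mercy of binary
floating point.

## Descriptive-table conventions

* Age bands are 18–64 and ≥65 years; ages are converted to years (MON/12,
  DY/365.25; other unit codes become missing). Reports with age under 18 have
  no band of their own in this table layout and are placed in N/A with a
  warning, rather than silently dropped.
* Weight bands are <80, 80–100 (closed on both ends — the only reading that
  partitions the line), >100 kg; only kilogram-coded weights are used as-is,
  LBS are converted at 0.453592 and GMS at 1/1000, other codes become
  missing.
* Severe outcomes count one instance per distinct (report, outcome code)
  pair; all seven FAERS outcome codes, including "Other", count as severe
  instances and form the denominator.
* SOC aggregation uses a user-supplied PT→SOC map (MedDRA is licensed and is
  not bundled). Events whose PT is absent from the map are excluded from the
  SOC denominator and counted separately — which is why a SOC total is
  typically smaller than the PT total for the same cohort.

## The synthetic generator

`generate_faers()` emulates the structural features the pipeline depends on:
multiple report versions per case (for dedup), role-coded drug mentions
including occasional non-PS target-drug mentions (for role filtering),
multi-PT reaction lists per case, outcome codes, and heavy demographic
missingness. Defaults are taken from the published selinexor cohort where it
states them:

* `events_per_case = 4.07` (17,894 events / 4,392 reports); the per-case PT
  count is `1 + Poisson(events_per_case − 1)`.
* `duplicate_prob = 0.26`, so deduplication removes ≈ 20.9% of DEMO rows
  (1,587,493 of 7,604,592 in the reference flow; removed/input = p/(1+p)).
* missingness: sex 69.7%, age 98%, weight 87.1%, occupation 1.2% — the
  reference demographics table's N/A shares; country missingness (5%) is not
  stated there and was fixed once at a realistic value.
* outcome weights proportional to the reference severe-outcome counts, with
  a "none" mass so that ≈ 59% of cases carry an outcome.
* reporting window July 2019 – June 2023; country and occupation drawn from
  small fixed vocabularies with the reference shares.
* scale: `n_cases = 5000` and `target_drug_prob = 0.05` by default — values
  the source does not state (its true target share is ~0.07% of six million
  reports, far too sparse to simulate efficiently); chosen once as a
  realistic extract-scale simulation and not tuned thereafter.

PTs within a case are drawn **without replacement** (distinct PTs), matching
the case-PT counting unit. Planted signals multiply the named PTs' sampling
weights by ρ within target-drug cases; under this re-weighting the implied
odds ratio equals ρ exactly, which is what `expected_contingency()` reports.
Its expected cell counts use the first-order rare-event approximation
(E[a] = n·q·E[K]·p_t etc.): exact inclusion probabilities under weighted
sampling without replacement have no closed form, and the approximation is
accurate precisely for rare PTs — for a common PT (per-draw probability
~0.1), saturation attenuates the observed ROR visibly below ρ. Tests
therefore plant signals on rare PTs.

Duplicate report versions are emitted in the DEMO table only, with identical
content apart from a smaller `fda_dt`/`primary_id`: that exercises exactly
the FDA dedup rule without creating dangling DRUG/REAC rows attached to
superseded versions. One root seed derives per-table streams (seed + k per
stage), so regenerating one table's logic never perturbs the others and the
whole dataset is byte-reproducible.

What the generator does **not** emulate: drug co-prescription structure,
reporting-trend drift over time, masking/competition bias, correlated PT
co-occurrence within a case. A green planted-signal test therefore
establishes that the pipeline recovers a known marginal reporting-rate
distortion — not that it is robust to those real-data phenomena.

## Numerical and degenerate-input choices

* Zero cells: undefined estimates (`NA`), never exceptions; undefined never
  flags. Division-by-zero percentages are explicit errors.
* Empty inputs: `n_cases = 0` yields seven header-only tables; an empty drug
  table yields an empty cohort with all events in the background; an empty
  PT→SOC map sends every event to the unmapped bucket.
* Tie-breaks are total and documented: dedup (fda_dt, then primary_id),
  frequency tables (count desc, then PT alphabetical), signal ranking (key
  desc, then a desc, then PT).
* The writer rejects fields containing the `$` delimiter (the dialect has no
  quoting), keeping `parse(write(x)) = x` an identity rather than a lossy
  escape scheme.

## Limitations

Spontaneous-report disproportionality inherits the usual caveats: reporting
bias, no causal interpretation, no exposure denominator. The package
deliberately excludes Bayesian shrinkage methods (BCPNN/IC, EBGM), fuzzy
duplicate detection beyond the FDA rule, and drug-name normalization against
ingredient dictionaries; verbatim substring matching can both over- and
under-select in extracts with unusual verbatim names.
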