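# faersignal

Pharmacovigilance signal detection on FAERS-style spontaneous adverse-event
reports.

The FDA Adverse Event Reporting System (FAERS) publishes quarterly extracts of
voluntary drug safety reports as seven dollar-delimited ASCII tables (DEMO,
DRUG, REAC, OUTC, INDI, THER, RPSR). Analysts mining these data for a drug's
adverse-event profile repeat the same pipeline every time: deduplicate report
versions, select the reports where the drug of interest is the primary
suspect, tabulate demographics and outcomes, and test each reported
MedDRA preferred term (PT) for disproportionate reporting. `faersignal`
packages that pipeline — originally assembled for a post-marketing safety
review of the XPO1 inhibitor selinexor — as reusable, tested R functions, plus
a synthetic-data generator so the whole pipeline can be validated without
downloading FAERS.

## The statistics

For each PT, events (distinct case–PT pairs) are cross-classified in a 2×2
table against the background of all other deduplicated reports:

|              | target PT | other PTs |
|--------------|-----------|-----------|
| target drug  | a         | b         |
| other drugs  | c         | d         |

* **Reporting odds ratio**: ROR = ad/(bc), with a Woolf-type 95% CI
  `exp(ln ROR ± 1.96·√(1/a + 1/b + 1/c + 1/d))`.
* **Proportional reporting ratio**: PRR = [a/(a+b)] / [c/(c+d)], with the
  uncorrected Pearson χ² = (ad−bc)²(a+b+c+d) / [(a+b)(c+d)(a+c)(b+d)].
* **Signal thresholds**: ROR rule — a ≥ 3 and CI lower bound > 1;
  PRR rule — a ≥ 3, PRR > 2 and χ² > 4. A flagged pair is a hypothesis for
  review, not evidence of causation; no multiple-testing correction is applied
  (the run log carries the disclaimer).

Case deduplication follows the FDA-recommended rule: for each CASE_ID keep
the version with the largest FDA_DT, ties broken by the largest PRIMARY_ID.

## Worked example

Simulate a FAERS-like extract with a planted drug–event association
(dehydration reported 10× more often under the target drug), then run the
detection stack:

```r
library(faersignal)

config <- synthetic_config(n_cases = 5000, seed = 2024,
                           planted_signals = c(Dehydration = 10))
tables <- generate_faers(config)

dedup <- deduplicate_demo(tables$DEMO)
#> FAERS deduplication: 6323 report versions -> 5000 cases (1323 removed)

cohort <- build_cohort(dedup, tables$DRUG, tables$REAC,
                       names = c("selinexor", "xpovio"), role = "PS")
#> FAERS cohort: 243 target reports; 1029 target events, 19253 background events

signals <- signal_table(cohort$events, min_a = 3)
rank_signals(signals, key = "ror", top_n = 5)
#>   pt                    a     b     c     d   ror ror_ci_low ror_ci_high   prr  chi2 ror_signal prr_signal
#> 1 Dehydration          87   942   218 19035  8.06       6.24       10.4   7.47 354.  TRUE       TRUE
#> 2 Background PT 082    12  1017   116 19137  1.95       1.07        3.54  1.94  4.95 TRUE       FALSE
#> 3 Background PT 010    12  1017   117 19136  1.93       1.06        3.51  1.92  4.82 TRUE       FALSE
```

The planted pair is recovered by both rules (observed ROR 8.06 against a
planted reporting-rate ratio of 10; the CI lower bound 6.24 is far above 1),
while the two borderline background terms show what chance disproportionality
looks like at a ≈ 12: flagged by the lenient ROR rule, rejected by the PRR
rule. Descriptive tables use the same event list, e.g.

```r
pt_frequency(cohort$events, top_n = 5)
#>   pt                               n percent
#> 1 Dehydration                     87    8.45
#> 2 Nausea                          68    6.61
#> 3 Fatigue                         58    5.64
#> 4 Anorexia or loss of appetite    47    4.57
#> 5 Vomiting                        39    3.79
```

`run_pipeline(input_dir, output_dir, ...)` executes the whole chain on a
directory of FAERS ASCII files and writes the report bundle (dedup summary,
event list, demographics, outcomes, PT/SOC frequencies, annual counts, signal
tables, run log, JSON summary). The same pipeline is available from a shell
via `inst/exec/faers-dispro` with `simulate`, `describe`, `signals` and
`full` subcommands.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch: it simulates a 20,000-case
FAERS-like dataset with a planted ρ = 10 signal under the given seed, writes
it to disk, runs parse → dedup → cohort → descriptives → disproportionality
through the installed package, checks that the stage counts reconcile, and
writes the results JSON to `--out`.
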