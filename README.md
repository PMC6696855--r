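# sbdhscreen

Screening electronic health records (EHRs) for social and behavioral
determinants of health (SBDH).

Most EHRs capture social circumstances — housing problems, social
isolation, financial resource strain — unevenly: partly in structured
fields, partly as ICD-10 "Z code" diagnoses, and largely inside
free-text clinical notes. Population-health teams who want to
prescreen a multi-million-patient population for immediate social needs
first have to answer a measurement question: *where does SBDH
information actually live in our EHR, and how complete is it?*

`sbdhscreen` is a pipeline for that assessment:

* **Structured screen** — per-field completeness rates
  (`completeness_rate()`; the share of unique patients with any
  non-missing value, where the explicit category `"Unknown"` counts as
  recorded), diagnosis-based cohort queries with ICD-9 legacy
  equivalents (`diagnosis_cohort()`), subtype-to-domain reconciliation
  (`domain_summary()`), and questionnaire completion rates.
* **Unstructured screen** — a rule-based text miner (`mine_notes()`):
  word-boundary, case-insensitive literal phrase matching over
  whitespace-normalised text with exact raw-text character spans,
  *SmartPhrase* question/answer detection (`Is Patient Homeless? No`),
  and a precedence-ordered context classifier (SmartPhrase → negation
  cue → other-referent cue → affirmative). Patient-level prevalence
  uses at-least-one semantics; results stratify by provider role and
  note type.
* **Annotation evaluation** — a manual-review scheme
  (`classify_note()`, `tally_annotations()`, `evaluate_miner()`) that
  classes notes as TP-only / FP-only / TN-only / conflicting from
  mention-level gold labels and scores the miner span-by-span.
* **Synthetic EHR generator** — `sim_config()` plus
  `generate_population()` / `generate_diagnoses()` /
  `generate_notes()` emulate the statistical structure of a large
  health-system extract (completeness rates, diagnosis and note-level
  prevalences, encounter ratios) with exact planted gold labels, so the
  full pipeline is testable without protected data.

All reported rates are computed as `percent(n, d)`: `100 * n / d`
rounded half-up to two decimals.

## Worked example

```r
library(sbdhscreen)

lex <- default_lexicon()
cfg <- sim_config(n_patients = 10000, seed = 1)
out <- run_pipeline(tempfile("sbdh"), cfg)

out$completeness
#> # A tibble: 6 x 4
#>   field              numerator denominator  rate
#>   <chr>                  <int>       <int> <dbl>
#> 1 address_or_zip          9467       10000 94.7
#> 2 race                    9031       10000 90.3
#> 3 ethnicity               5000       10000 50
#> 4 preferred_language      4983       10000 49.8
#> 5 alcohol_use              897       10000  8.97
#> 6 smoking_status          3190       10000 31.9

out$prevalence
#> # A tibble: 3 x 4
#>   domain            patients_flagged denominator   pct
#>   <chr>                        <int>       <int> <dbl>
#> 1 social_connection              253       10000  2.53
#> 2 housing                        277       10000  2.77
#> 3 financial_strain               106       10000  1.06
```

Reading this: of 10,000 simulated patients, 94.67% have a valid address
or zip on file but only 8.97% have coded alcohol use — demographics are
nearly complete while social-history fields are sparse. The note miner
flags 2.77% of patients as having at least one clinical note with an
affirmative housing-issue mention (the configured rate is 3.00%; the
estimate is a binomial draw, and the test suite checks calibration
against 99% binomial intervals across seeds). `out$table2` combines the
structured and unstructured counts per domain with subtype code rows,
and `out$tally` reports the annotation-corpus tally
(64/14/20/2 notes, 130 occurrences, mention precision 86/102).

The context classifier at work:

```r
matcher <- compile_matcher(lex)
note <- list(note_id = "n1", text = "Is Patient Homeless? No")
span <- match_mentions(note, matcher)
sp <- detect_smartphrase(note, lex$housing$smartphrase_templates)
classify_context(span[1, ], note, lex$housing, sp)
#> [1] "smartphrase_negative"
```

A boilerplate screening question answered "No" is located as a phrase
occurrence but classified as negative evidence, so it never flags the
patient.

## Vignette

`vignettes/sbdh-screening-methods.Rmd` documents the matching and
context-classification rules, the generator's parameters and what they
emulate (and do not), rounding and shared-code conventions, and known
limitations.
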