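---
title: "Methods: screening EHR data for social and behavioral determinants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening EHR data for social and behavioral determinants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(sbdhscreen)
```

## The screening problem

Social and behavioral determinants of health (SBDH) — housing problems,
social isolation, financial resource strain — drive utilization and
outcomes, but are captured unevenly in electronic health records. Some
determinants live in discrete structured fields (demographics, social
history), some in ICD-10 "Z code" diagnoses, and much of the rest only
in free-text clinical notes. `sbdhscreen` implements a screening
pipeline over all three layers:

1. **completeness metrics** for structured fields — what fraction of
   unique patients have *any* recorded value;
2. **diagnosis cohort queries** for coded SBDH (Z59.x housing, Z60/Z63/
   Z65/Z73/Z91/R45 social connection, Z59.5–Z59.8 financial strain),
   with ICD-9 legacy equivalents;
3. **rule-based text mining** of notes: literal phrase matching with
   word boundaries, plus a context classifier that separates affirmative
   statements from negations, third-party references, and EHR
   *SmartPhrase* screening questions answered "No";
4. **annotation evaluation** mirroring a manual review workflow: notes
   are classed as TP-only / FP-only / TN-only / conflicting from
   mention-level labels.

Because the underlying health-system extract cannot be redistributed,
the package ships a synthetic-EHR generator that reproduces the
*statistical shape* of such an extract, so every stage is exercised by
tests without any protected data.

## Phrase matching

A lexicon (`default_lexicon()`) carries, per domain, an ICD code
inventory and a literal phrase list. Matching is deliberately simple and
fully specified:

* **word-boundary literal matching**: a match may not begin or end
  inside an alphanumeric run, so `homeless` never fires inside
  `homelessness`. A boundary is any alphanumeric/non-alphanumeric
  transition or the text edge.
* **case-insensitive** by default — clinical notes mix cases freely.
* **whitespace normalisation**: runs of whitespace collapse to single
  spaces before matching, so multi-word phrases match across line
  breaks. `normalize_text()` keeps an invertible offset map, and every
  reported span refers to the *raw* note text (the invariant
  `matched_text == substring(text, start + 1, end)` is property-tested).

The phrase lists are a documented seed vocabulary drawn from the domain
definitions and the ICD label texts (the full institutional phrase
inventories behind the reference study are not public). The lexicon is
a YAML file (`save_lexicon()` / `load_lexicon()`), so sites can replace
the seed lists wholesale; validation enforces unique pattern ids, known
code systems, and syntactically valid codes.

## Context classification

The miner classifies every located mention, in strict precedence order:

1. **SmartPhrase**: if the span lies inside a detected template question
   (e.g. `Is Patient Homeless?`) or its answer window, the mention is
   `smartphrase_negative` or `smartphrase_affirmative` according to the
   detected `Yes`/`No` token. An unanswered question defaults to
   negative — boilerplate screening questions are not positive evidence.
   The answer window is 15 characters after the question: in templated
   text the answer immediately follows, and a wider window would start
   absorbing unrelated tokens.
2. **Negation**: a cue (`denies`, `no history of`, `not`, ...) ending
   within 40 characters before the span, inside the same sentence. The
   40-character same-sentence window is a NegEx-style heuristic: wide
   enough for "denies being currently homeless", narrow enough not to
   leak across clauses.
3. **Other referent**: a third-party cue (`brother`, `roommate`, ...)
   anywhere in the same sentence.
4. otherwise **affirmative**.

Sentences are delimited by `.`, `?`, or `!` followed by whitespace,
computed on the normalised text (newlines have already collapsed to
spaces, so note formatting does not move sentence boundaries). This is
deterministic and model-free; it does not attempt section detection,
temporality, or hedging — documented non-goals.

Note-level flags use *at-least-one* semantics: a note counts for a
domain iff it has ≥ 1 affirmative (or SmartPhrase-affirmative) mention;
a patient counts iff they have ≥ 1 flagged note. A raw-occurrence mode
(`note_flags(..., mode = "raw")`) is also exposed, because a screening
deployment may prefer to review every phrase hit; the reference
workflow's manual review suggests raw matching followed by human
adjudication, while the filtered mode is the automated analogue.

## Reporting conventions

All "n (%)" figures go through `percent()`: multiply by 100, round
**half-up** to 2 decimals. Published versions of such tables mix
conventions (some rows truncate, some round to whole percents); one
explicit rule beats mimicking inconsistency, and the half-up convention
matches the reference abstract's figures (e.g. 35,646 / 1,188,202 →
3.00). Where a published row visibly uses coarser rounding (whole-
percent questionnaire rates), the tests assert agreement at that coarser
precision rather than pretending two conventions are one.

The shared ICD-10 code **Z59.8** ("other problems related to housing and
economic circumstances") is catalogued under both housing and financial
strain, as coded-diagnosis inventories conventionally print it. Both
lexicon entries are flagged `shared_code`, and generated diagnosis
records carry a `domain` provenance column; `diagnosis_cohort()` uses it
to attribute shared-code records per-domain, which keeps the two domain
totals reconcilable. On real extracts, which have no provenance, the
query degrades to code-only matching and the two cohorts overlap on
Z59.8 carriers — an irreducible ambiguity of the code itself that users
should keep in mind.

The ICD-9 crosswalk (`icd9_equivalents()`) is a minimal, explicitly
approximate map (V60.x, V61.0, V62.4). Under ICD-9 recoding, V61.0 maps
back to Z63.0, so subtype attribution of Z63.5-origin legacy records
blurs into Z63.0; domain totals are unaffected.

## The synthetic-EHR generator

`sim_config()` defaults encode the study conditions of a large
multilevel health system:

| parameter | default | meaning |
|---|---|---|
| completeness: address_or_zip / race / ethnicity / language | 0.95 / 0.90 / 0.50 / 0.50 | probability a patient has any recorded value |
| completeness: alcohol_use / smoking_status | 0.0908 / 0.3201 | social-history coding rates |
| icd_prevalence: social / housing / financial | 0.0058 / 0.0019 / 0.0007 | coded-diagnosis patient prevalence |
| note_prevalence: social / housing / financial | 0.0260 / 0.0300 / 0.0100 | probability of ≥1 affirmative-mention note |
| notes_per_patient | 7.6 | shifted Poisson `1 + Pois(6.6)`; matches a 9.07M-encounter / 1.19M-patient ratio |
| structured / unstructured window | 2003-01-01..2018-06-26 / 2016-07-01..2018-05-31 | record date ranges |
| confounder_rate | 0.01 | per-patient, per-domain probability of a non-affirmative mention note |
| context_mixture | 0.59 / 0.205 / 0.205 | SmartPhrase-negative : negated : other-referent split of confounders, the ratio implied by a 20 : 14 true-negative-to-false-positive note split |
| provider_role / note_type mixtures | physician-, progress-note-dominant | qualitative only; the reference figures publish no numbers |

Positive patients receive exactly one subtype code per domain, drawn
proportionally to the reference subtype patient counts stored in the
lexicon (`reference_count`), so subtype counts sum exactly to domain
totals, and subtype cohorts are disjoint by construction. Smoking
statuses follow the reference status breakdown; recorded alcohol values
include zeros (a recorded 0 drinks/week is *present*), with the
≥1-drink fraction matching the reference ratio. The explicit
`"Unknown"` preferred-language value is generated as a present value,
distinct from missingness.

Note text is assembled from a filler-sentence vocabulary that is
verified at generation time to contain **no lexicon phrase**, so the
planted mentions are the complete, exact gold standard: the miner's
output can be compared to ground truth span-for-span, and tests assert
that equality. Sentence separators vary (` `, double space, newline) to
exercise offset mapping. What the generator does **not** emulate:
realistic clinical language, abbreviations, misspellings, section
headers, copy-forward text, or negation phrasings outside the cue
vocabulary. Passing tests therefore demonstrate the pipeline's internal
correctness and statistical calibration — not free-text recall on real
notes, which the rule-based approach itself cannot guarantee (no
false-negative measurement without large-scale manual annotation).

### The annotation fixture

`generate_annotation_fixture()` builds a 100-note corpus for the
homelessness subdomain whose composition is fixed by construction: 64
notes with only affirmative mentions, 14 with only false-positive
contexts (7 negated, 7 other-referent), 20 whose only mentions are
SmartPhrase questions answered "No", and 2 mixed notes. The target
token occurs exactly 130 times: the 30 occurrences beyond one-per-note
are 20 second affirmative mentions, 8 repeated SmartPhrase blocks, and
2 false-positive mentions in the mixed notes. The seed varies only the
surface filler text and note order. Mention-level precision of raw
matching on this corpus is 86/102 ≈ 0.843; precision and recall are
diagnostics here, not published quantities.

## Numerical and testing choices

* Problem sizes: unit tests simulate 200–1,000 patients; calibration
  tests use 10,000-patient populations across five seeds, which resolves
  the smallest prevalence parameter (0.0007, ~7 expected positives per
  draw, 35 pooled) while keeping the default suite to a few minutes.
* Parameter recovery is asserted two ways: the estimate pooled across
  the five seeds must fall inside the central 99% binomial interval at
  the pooled sample size (a bias-sensitive check), and per-draw misses
  of the individual 99% intervals are bounded by the count consistent
  with the nominal 1% tail rate. Requiring *every* draw inside its
  interval would fail a correct generator in roughly half of runs — 60
  draws each with a 1% miss rate — so the pooled formulation is the
  statistically meaningful reading of "recovery across ≥5 seeds".
* `round_half_up()` adds a 1e-9 guard before flooring so that values
  exactly representable at the target precision do not fall on the wrong
  side of representation error.
* Degenerate inputs are defined, not crashed on: zero denominators give
  `NA` rates with a warning; empty pattern sets give matchers that match
  nothing; `n_patients = 0` gives empty tables with intact schemas.
* Tie-break in note classification: a note mixing true-negative with
  exactly one other mention class resolves to that class's "only" label
  with a warning. The reference annotation's 100 notes occupy only the
  four pure/conflicting cells, so this cell is a documented completion,
  flagged at runtime precisely because it is a convention rather than an
  observed rule.

## Known limitations

* The seed phrase lists are a stand-in for institutional lexicons, not a
  reconstruction of them; recall on real notes depends entirely on the
  deployed lexicon.
* Negation handling is a 40-character cue heuristic; scoped or hedged
  negations ("unlikely to be homeless given...") are out of scope.
* The false-positive contexts the generator plants (negation,
  other-referent) are plausible stand-ins; the reference study does not
  describe what produced its false positives.
* Subdomain-level mining is intentionally absent: free-text mining
  reports domain-level flags only, matching how such results are
  conventionally reported.
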