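lex <- default_lexicon()

test_that("generator is deterministic given config and seed", {
  cfg <- sim_config(n_patients = 300, seed = 99)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  expect_identical(a, b)
  na <- generate_notes(cfg, a, lex)
  nb <- generate_notes(cfg, b, lex)
  expect_identical(na$notes$text, nb$notes$text)
  da <- generate_diagnoses(cfg, a, lex)
  db <- generate_diagnoses(cfg, b, lex)
  expect_identical(da, db)
})

test_that("empty population yields empty tables with intact schemas", {
  cfg <- sim_config(n_patients = 0)
  pop <- generate_population(cfg)
  expect_equal(nrow(pop$patients), 0)
  expect_named(pop$patients, c("patient_id", "address", "zip", "race",
                               "ethnicity", "preferred_language"))
  expect_equal(nrow(pop$encounters), 0)
  nt <- generate_notes(cfg, pop, lex)
  expect_equal(nrow(nt$notes), 0)
  expect_named(nt$notes, c("note_id", "patient_id", "encounter_id",
                           "note_type", "provider_role", "date", "text"))
  expect_error(sim_config(n_patients = -1), "n_patients")
})

test_that("config validation rejects malformed mixtures", {
  expect_error(sim_config(provider_role_mixture = c(physician = 0.5)),
               "sum to 1")
  expect_error(sim_config(note_type_mixture = numeric(0)), "non-empty")
  expect_error(sim_config(context_mixture = c(banana = 1)),
               "unknown context")
  expect_error(sim_config(icd_prevalence = c(housing = 1.5)), "\\[0, 1\\]")
})

test_that("field completeness lands in the 99% binomial interval", {
  cfg <- sim_config(n_patients = 10000, seed = 7)
  pop <- generate_population(cfg)
  ci <- sbdhscreen:::binom_interval99(0.90, 10000)
  got <- completeness_rate(pop$patients, "race")$numerator / 10000
  expect_gte(got, ci["lower"])
  expect_lte(got, ci["upper"])
})

test_that("planted diagnosis prevalence matches its parameter", {
  cfg <- sim_config(n_patients = 50000, seed = 3)
  pop <- generate_population(cfg)
  dx <- generate_diagnoses(cfg, pop, lex)
  frac <- sum(dx$structured_flags$domain == "housing") / 50000
  ci <- sbdhscreen:::binom_interval99(0.0019, 50000)
  expect_gte(frac, ci["lower"])
  expect_lte(frac, ci["upper"])
  # every flagged patient carries at least one code from the domain list
  flagged <- dx$structured_flags$patient_id[
    dx$structured_flags$domain == "housing"
  ]
  got <- diagnosis_cohort(dx$diagnoses, lex$housing$codes,
                          domain = "housing")
  expect_setequal(got, flagged)
})

test_that("zero prevalence produces no SBDH diagnoses", {
  cfg <- sim_config(
    n_patients = 500,
    icd_prevalence = c(social_connection = 0, housing = 0,
                       financial_strain = 0)
  )
  pop <- generate_population(cfg)
  dx <- generate_diagnoses(cfg, pop, lex)
  expect_equal(nrow(dx$diagnoses), 0)
})

test_that("every patient appears in the note table", {
  cfg <- sim_config(n_patients = 400, seed = 5)
  pop <- generate_population(cfg)
  nt <- generate_notes(cfg, pop, lex)
  expect_setequal(unique(nt$notes$patient_id), pop$patients$patient_id)
})

test_that("confounder-only corpora have matches but no gold flags", {
  cfg <- sim_config(
    n_patients = 300, seed = 21,
    note_prevalence = c(social_connection = 0, housing = 0,
                        financial_strain = 0),
    context_mixture = c(smartphrase_negative = 1, negated = 0,
                        other_referent = 0),
    confounder_rate = 0.5
  )
  pop <- generate_population(cfg)
  nt <- generate_notes(cfg, pop, lex)
  expect_equal(nrow(nt$patient_flags), 0)
  m <- mine_notes(nt$notes, lex)
  expect_gt(nrow(m), 0)
  expect_true(all(m$context_class == "smartphrase_negative"))
  expect_equal(nrow(note_flags(m)), 0)
})

test_that("planted gold spans point at their exact phrase text", {
  cfg <- sim_config(n_patients = 500, seed = 13, confounder_rate = 0.05)
  pop <- generate_population(cfg)
  nt <- generate_notes(cfg, pop, lex)
  txt <- nt$notes$text[match(nt$mentions$note_id, nt$notes$note_id)]
  expect_equal(
    substring(txt, nt$mentions$start + 1, nt$mentions$end),
    nt$mentions$phrase
  )
})

test_that("annotation fixture composition is fixed and seed-independent", {
  for (seed in c(1, 77)) {
    f <- generate_annotation_fixture(seed)
    expect_equal(nrow(f$notes), 100)
    expect_equal(sort(unique(f$notes$note_id)), sort(f$notes$note_id))
    tab <- table(f$note_class$class)
    expect_equal(as.integer(tab[c("tp_only", "fp_only", "tn_only",
                                  "conflicting")]),
                 c(64L, 14L, 20L, 2L))
    # every note mentions the target token at least once; 130 in total
    counts <- vapply(
      gregexpr("(?i)(?<![[:alnum:]])homeless(?![[:alnum:]])",
               f$notes$text, perl = TRUE),
      function(m) if (m[1] == -1L) 0L else length(m), integer(1)
    )
    expect_true(all(counts >= 1))
    expect_equal(sum(counts), 130L)
    expect_equal(nrow(f$gold), 130)
  }
})
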