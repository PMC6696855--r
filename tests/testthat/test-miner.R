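lex <- default_lexicon()
matcher <- compile_matcher(lex)

test_that("whitespace normalisation keeps an invertible offset map", {
  nt <- normalize_text("homeless\n\n  man")
  expect_equal(nt$text, "homeless man")
  # every normalised character maps back to the raw character it shows
  raw <- "homeless\n\n  man"
  norm_chars <- strsplit(nt$text, "")[[1]]
  raw_chars <- strsplit(raw, "")[[1]][nt$map]
  expect_equal(norm_chars[norm_chars != " "],
               raw_chars[norm_chars != " "])

  expect_equal(normalize_text(""), list(text = "", map = integer()))
  # idempotence
  once <- normalize_text("a\tb   c\n")$text
  expect_equal(normalize_text(once)$text, once)
})

test_that("mentions are located with raw-text offsets", {
  note <- list(note_id = "n1", text = "He has been homeless since June.")
  got <- match_mentions(note, matcher)
  expect_equal(nrow(got), 1)
  expect_equal(got$domain, "housing")
  expect_equal(got$start, 12L)
  expect_equal(got$matched_text, "homeless")

  none <- match_mentions(list(note_id = "n2", text = "Routine visit."),
                         matcher)
  expect_equal(nrow(none), 0)

  # spans survive messy whitespace: offsets refer to the raw string
  messy <- list(note_id = "n3",
                text = "Housing\n instability   noted.\nhomeless.")
  got <- match_mentions(messy, matcher)
  expect_equal(
    substring(messy$text, got$start + 1, got$end),
    got$matched_text
  )
  expect_setequal(tolower(got$matched_text),
                  c("housing\n instability", "homeless"))
})

test_that("overlapping phrases from different patterns are both reported", {
  m <- compile_matcher(toy_lexicon(c("housing instability", "instability")))
  got <- match_mentions(
    list(note_id = "n", text = "housing instability noted"), m
  )
  expect_equal(nrow(got), 2)
})

test_that("SmartPhrase detection finds the nearest in-window answer", {
  tpl <- lex$housing$smartphrase_templates
  no <- detect_smartphrase(
    list(note_id = "n", text = "Is Patient Homeless? No"), tpl
  )
  expect_equal(no$answer, "No")
  yes <- detect_smartphrase(
    list(note_id = "n", text = "Is patient homeless?  Yes, see note."), tpl
  )
  expect_equal(yes$answer, "Yes")
  absent <- detect_smartphrase(
    list(note_id = "n",
         text = "Is Patient Homeless? [assessment deferred today] No"),
    tpl
  )
  expect_true(is.na(absent$answer))
  expect_error(detect_smartphrase(list(note_id = "n", text = "x"), list()),
               "template")
})

test_that("context classification follows the precedence order", {
  hlex <- lex$housing
  classify <- function(text) {
    note <- list(note_id = "n", text = text)
    span <- match_mentions(note, matcher)[1, ]
    sp <- detect_smartphrase(note, hlex$smartphrase_templates)
    classify_context(span, note, hlex, sp)
  }
  expect_equal(classify("Is Patient Homeless? No"), "smartphrase_negative")
  expect_equal(classify("Is Patient Homeless? Yes"),
               "smartphrase_affirmative")
  # unanswered SmartPhrase questions are treated as negative screens
  expect_equal(classify("Is Patient Homeless?"), "smartphrase_negative")
  expect_equal(classify("Patient denies being homeless."), "negated")
  expect_equal(classify("Patient reports being homeless."), "affirmative")
  expect_equal(classify("Patient's brother is homeless."),
               "other_referent")
  # negation scope ends at the sentence boundary
  expect_equal(classify("Patient denies chest pain. He is homeless."),
               "affirmative")
  # and at the 40-character window
  far <- paste0("Patient denies chest pain radiating to the left arm ",
                "but remains homeless.")
  expect_equal(classify(far), "affirmative")
  expect_error(
    classify_context(list(start = 0L, end = 99L),
                     list(note_id = "n", text = "short"), hlex, NULL),
    "bounds"
  )
})

test_that("note flags require an affirmative mention unless mode is raw", {
  spans <- tibble::tibble(
    note_id = c("n1", "n1", "n2"),
    domain = "housing",
    pattern_id = "housing_01",
    start = c(0L, 10L, 0L), end = c(8L, 18L, 8L),
    matched_text = "homeless",
    context_class = c("affirmative", "other_referent",
                      "smartphrase_negative")
  )
  # mixed note flags true; SmartPhrase-negative-only note does not
  expect_equal(note_flags(spans)$note_id, "n1")
  expect_equal(note_flag(spans[spans$note_id == "n2", ]),
               c(social_connection = FALSE, housing = FALSE,
                 financial_strain = FALSE))
  # raw-occurrence mode counts any mention
  expect_setequal(note_flags(spans, mode = "raw")$note_id, c("n1", "n2"))
})

test_that("patient prevalence uses at-least-one semantics", {
  notes <- tibble::tibble(
    note_id = c("n1", "n2", "n3", "n4"),
    patient_id = c("p1", "p1", "p2", "p3")
  )
  flagged <- tibble::tibble(note_id = "n1", domain = "housing")
  got <- patient_prevalence(flagged, notes)
  h <- got[got$domain == "housing", ]
  expect_equal(h$patients_flagged, 1L)
  expect_equal(h$denominator, 3L)
  expect_equal(h$pct, 33.33)
  # an additional flagged note for the same patient changes nothing
  more <- rbind(flagged, tibble::tibble(note_id = "n2", domain = "housing"))
  expect_equal(patient_prevalence(more, notes), got)
  expect_warning(patient_prevalence(flagged, notes[0, ]), "empty")
})

test_that("adding notes never decreases flagged-patient counts", {
  cfg <- sim_config(n_patients = 200, seed = 31)
  pop <- generate_population(cfg)
  nt <- generate_notes(cfg, pop, lex)
  m <- mine_notes(nt$notes, lex)
  base <- patient_prevalence(note_flags(m), nt$notes)
  extra_note <- tibble::tibble(
    note_id = "extra1", patient_id = pop$patients$patient_id[1],
    encounter_id = "ex1", note_type = "progress_note",
    provider_role = "physician", date = as.Date("2017-01-01"),
    text = "Patient reports homelessness at this time."
  )
  notes2 <- rbind(nt$notes, extra_note)
  grown <- patient_prevalence(note_flags(mine_notes(notes2, lex)), notes2)
  expect_true(all(grown$patients_flagged >= base$patients_flagged))
})

test_that("strata counts conserve the flagged-note total", {
  cfg <- sim_config(n_patients = 300, seed = 17, confounder_rate = 0.05)
  pop <- generate_population(cfg)
  nt <- generate_notes(cfg, pop, lex)
  m <- mine_notes(nt$notes, lex)
  pairs <- nrow(dplyr::distinct(m[, c("note_id", "domain")]))
  for (by in c("provider_role", "note_type")) {
    st <- stratify(m, nt$notes, by)
    expect_equal(sum(st$notes), pairs)
  }
  # missing metadata falls into an explicit unknown stratum
  notes_na <- nt$notes
  notes_na$provider_role <- NA_character_
  st <- stratify(m, notes_na, "provider_role")
  expect_equal(unique(st$stratum), "unknown")
  expect_error(stratify(m, nt$notes, "facility"), "'arg' should be one of")
})

test_that("miner output equals planted gold on synthetic corpora", {
  cfg <- sim_config(n_patients = 1000, seed = 47, confounder_rate = 0.03)
  pop <- generate_population(cfg)
  nt <- generate_notes(cfg, pop, lex)
  m <- mine_notes(nt$notes, lex)
  key <- function(x) paste(x$note_id, x$start, x$end, x$context_class)
  expect_setequal(key(m), key(nt$mentions))
  # patient-level flags reproduce the gold flags exactly
  flagged <- merge(note_flags(m), nt$notes[, c("note_id", "patient_id")])
  pred <- unique(flagged[, c("patient_id", "domain")])
  expect_setequal(
    paste(pred$patient_id, pred$domain),
    paste(nt$patient_flags$patient_id, nt$patient_flags$domain)
  )
})
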