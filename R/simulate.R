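#' Simulation configuration for the synthetic EHR generator
#'
#' Builds a validated configuration whose defaults emulate the reference
#' health system: field completeness rates of the structured tables, coded
#' SBDH diagnosis prevalences, note-level SBDH patient prevalences, the
#' encounter-per-patient ratio, and qualitative provider-role / note-type
#' mixtures. Any parameter can be overridden with a (possibly partial)
#' named vector.
#'
#' @param n_patients Number of patients to simulate.
#' @param seed Integer seed; the generator is fully deterministic given
#'   the configuration and seed.
#' @param structured_window,unstructured_window Closed date intervals
#'   (length-2 character or Date vectors) for structured records and
#'   clinical notes.
#' @param completeness Named probabilities that a patient has a value for
#'   each structured field.
#' @param icd_prevalence Named per-domain probabilities of carrying at
#'   least one SBDH diagnosis code.
#' @param note_prevalence Named per-domain probabilities of having at
#'   least one note with an affirmative SBDH mention.
#' @param notes_per_patient Mean of the shifted-Poisson note count
#'   (`1 + Poisson(mean - 1)`), so every patient has at least one note.
#' @param encounters_per_patient Mean of the shifted-Poisson encounter
#'   count.
#' @param context_mixture Named weights over the non-affirmative mention
#'   contexts planted in confounder notes (`smartphrase_negative`,
#'   `negated`, `other_referent`); must sum to 1.
#' @param provider_role_mixture,note_type_mixture Named categorical
#'   weights for note metadata; must each sum to 1.
#' @param smoking_status_distribution Named weights over smoking status
#'   categories; must sum to 1.
#' @param confounder_rate Per-patient, per-domain probability of receiving
#'   a note with a non-affirmative (confounder) mention.
#' @param icd9_fraction Fraction of SBDH diagnosis records recoded to
#'   their approximate ICD-9 equivalents where one exists.
#' @return A validated list of class `sbdh_sim_config`.
#' @export
sim_config <- function(n_patients = 10000,
                       seed = 1L,
                       structured_window = c("2003-01-01", "2018-06-26"),
                       unstructured_window = c("2016-07-01", "2018-05-31"),
                       completeness = NULL,
                       icd_prevalence = NULL,
                       note_prevalence = NULL,
                       notes_per_patient = 7.6,
                       encounters_per_patient = 3,
                       context_mixture = NULL,
                       provider_role_mixture = NULL,
                       note_type_mixture = NULL,
                       smoking_status_distribution = NULL,
                       confounder_rate = 0.01,
                       icd9_fraction = 0.1) {
  merge_named <- function(defaults, x, what) {
    if (is.null(x)) {
      return(defaults)
    }
    bad <- setdiff(names(x), names(defaults))
    if (length(bad)) {
      stop("unknown ", what, " name(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    defaults[names(x)] <- x
    defaults
  }
  config <- structure(list(
    n_patients = n_patients,
    seed = as.integer(seed),
    structured_window = as.Date(structured_window),
    unstructured_window = as.Date(unstructured_window),
    completeness = merge_named(c(
      address_or_zip = 0.95, race = 0.90, ethnicity = 0.50,
      preferred_language = 0.50, alcohol_use = 0.0908,
      smoking_status = 0.3201
    ), completeness, "completeness field"),
    icd_prevalence = merge_named(c(
      social_connection = 0.0058, housing = 0.0019,
      financial_strain = 0.0007
    ), icd_prevalence, "icd_prevalence domain"),
    note_prevalence = merge_named(c(
      social_connection = 0.0260, housing = 0.0300,
      financial_strain = 0.0100
    ), note_prevalence, "note_prevalence domain"),
    notes_per_patient = notes_per_patient,
    encounters_per_patient = encounters_per_patient,
    context_mixture = if (is.null(context_mixture)) {
      c(smartphrase_negative = 0.59, negated = 0.205, other_referent = 0.205)
    } else {
      context_mixture
    },
    provider_role_mixture = if (is.null(provider_role_mixture)) {
      c(physician = 0.6, nurse = 0.2, social_worker = 0.1,
        case_manager = 0.05, other = 0.05)
    } else {
      provider_role_mixture
    },
    note_type_mixture = if (is.null(note_type_mixture)) {
      c(progress_note = 0.5, telephone = 0.15, discharge_summary = 0.1,
        ED_note = 0.1, other = 0.15)
    } else {
      note_type_mixture
    },
    smoking_status_distribution = if (is.null(smoking_status_distribution)) {
      # reference relative frequencies of the closed status enumeration
      prop.table(c(
        "current every day smoker" = 114566,
        "current some day smoker" = 28547,
        "former smoker" = 297099,
        "heavy tobacco smoker" = 3111,
        "light tobacco smoker" = 12857,
        "never assessed" = 302631,
        "never smoker" = 952636,
        "passive smoke exposure/never smoker" = 4274,
        "ever smoked/current status unknown" = 1133,
        "unknown if ever smoked" = 11915
      ))
    } else {
      smoking_status_distribution
    },
    confounder_rate = confounder_rate,
    icd9_fraction = icd9_fraction
  ), class = "sbdh_sim_config")
  validate_sim_config(config)
  config
}

validate_sim_config <- function(config) {
  if (is.na(config$n_patients) || config$n_patients < 0) {
    stop("n_patients must be >= 0", call. = FALSE)
  }
  probs <- c(config$completeness, config$icd_prevalence,
             config$note_prevalence, config$confounder_rate,
             config$icd9_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  for (nm in c("context_mixture", "provider_role_mixture",
               "note_type_mixture", "smoking_status_distribution")) {
    mix <- config[[nm]]
    if (length(mix) == 0) {
      stop(nm, " must be non-empty", call. = FALSE)
    }
    if (any(mix < 0)) {
      stop(nm, " has negative weights", call. = FALSE)
    }
    if (abs(sum(mix) - 1) > 1e-9) {
      stop(nm, " weights must sum to 1", call. = FALSE)
    }
  }
  bad_ctx <- setdiff(names(config$context_mixture),
                     c("smartphrase_negative", "negated", "other_referent"))
  if (length(bad_ctx)) {
    stop("unknown context class(es): ", paste(bad_ctx, collapse = ", "),
         call. = FALSE)
  }
  if (config$notes_per_patient < 1) {
    stop("notes_per_patient must be >= 1", call. = FALSE)
  }
  invisible(config)
}

sample_dates <- function(n, window) {
  days <- as.integer(window[2] - window[1])
  window[1] + sample.int(days + 1L, n, replace = TRUE) - 1L
}

shifted_poisson <- function(n, mean) {
  1L + stats::rpois(n, mean - 1)
}

#' Generate a synthetic patient population
#'
#' Draws patient demographics, encounters, and a social-history table.
#' Per-field missingness is independent across patients at
#' `1 - completeness[field]`. Addresses and zip codes are syntactically
#' valid when present, race allows multiple self-identified values,
#' and preferred language includes the explicit recorded value
#' `"Unknown"`, distinct from a missing entry.
#'
#' @param config An `sbdh_sim_config` from [sim_config()].
#' @return A list of tibbles: `patients`, `encounters`, `social_history`.
#' @export
generate_population <- function(config) {
  validate_sim_config(config)
  n <- config$n_patients
  set.seed(config$seed)
  comp <- config$completeness

  if (n == 0) {
    return(list(
      patients = tibble::tibble(
        patient_id = character(), address = character(), zip = character(),
        race = character(), ethnicity = character(),
        preferred_language = character()
      ),
      encounters = tibble::tibble(
        encounter_id = character(), patient_id = character(),
        date = as.Date(character()), facility_type = character()
      ),
      social_history = tibble::tibble(
        patient_id = character(), alcohol_drinks_per_week = numeric(),
        smoking_status = character(), smoking_quit_date = as.Date(character())
      )
    ))
  }

  patient_id <- sprintf("P%07d", seq_len(n))

  streets <- c("Main St", "Oak Ave", "Park Rd", "Lake Dr", "Hill Ct",
               "Cedar Ln", "Maple Ave", "North Blvd")
  addr_present <- stats::runif(n) < comp[["address_or_zip"]]
  has_street <- addr_present & stats::runif(n) < 0.97
  address <- ifelse(
    has_street,
    paste0(sample.int(9999, n, replace = TRUE), " ",
           sample(streets, n, replace = TRUE)),
    NA_character_
  )
  zip <- ifelse(addr_present,
                sprintf("%05d", sample.int(99999, n, replace = TRUE)),
                NA_character_)

  races <- c("White", "Black or African American", "Asian",
             "American Indian or Alaska Native",
             "Native Hawaiian or Pacific Islander", "Other")
  race_present <- stats::runif(n) < comp[["race"]]
  race_first <- sample(races, n, replace = TRUE)
  race_second <- sample(races, n, replace = TRUE)
  multi <- stats::runif(n) < 0.05 & race_second != race_first
  race <- ifelse(
    race_present,
    ifelse(multi, paste(race_first, race_second, sep = ";"), race_first),
    NA_character_
  )

  eth_present <- stats::runif(n) < comp[["ethnicity"]]
  ethnicity <- ifelse(
    eth_present,
    sample(c("Hispanic", "non-Hispanic"), n, replace = TRUE,
           prob = c(0.12, 0.88)),
    NA_character_
  )

  # language mixture among recorded values, including the explicit
  # "Unknown" category (a valid value, different from an empty record)
  lang_levels <- c("English", "Spanish", "Arabic", "Chinese/Mandarin",
                   "Korean", "Unknown")
  lang_weights <- c(2626379, 53446, 7317, 4036, 3168, 5936)
  lang_present <- stats::runif(n) < comp[["preferred_language"]]
  preferred_language <- ifelse(
    lang_present,
    sample(lang_levels, n, replace = TRUE,
           prob = lang_weights / sum(lang_weights)),
    NA_character_
  )

  patients <- tibble::tibble(
    patient_id = patient_id, address = address, zip = zip, race = race,
    ethnicity = ethnicity, preferred_language = preferred_language
  )

  k_enc <- shifted_poisson(n, config$encounters_per_patient)
  n_enc <- sum(k_enc)
  encounters <- tibble::tibble(
    encounter_id = sprintf("E%08d", seq_len(n_enc)),
    patient_id = rep(patient_id, k_enc),
    date = sample_dates(n_enc, config$structured_window),
    facility_type = sample(c("outpatient", "inpatient", "emergency"),
                           n_enc, replace = TRUE,
                           prob = c(0.6, 0.25, 0.15))
  )

  # alcohol use: fraction of recorded values reporting >= 1 drink/week
  # matches the reference ratio (a recorded 0 still counts as present)
  alc_present <- stats::runif(n) < comp[["alcohol_use"]]
  any_drinks <- stats::runif(n) < 178789 / 490348
  drinks <- ifelse(
    alc_present,
    ifelse(any_drinks, 1 + stats::rpois(n, 3), 0),
    NA_real_
  )
  smoke_present <- stats::runif(n) < comp[["smoking_status"]]
  smoking_status <- ifelse(
    smoke_present,
    sample(names(config$smoking_status_distribution), n, replace = TRUE,
           prob = config$smoking_status_distribution),
    NA_character_
  )
  quit <- !is.na(smoking_status) & smoking_status == "former smoker" &
    stats::runif(n) < 0.5
  quit_dates <- sample_dates(n, config$structured_window)
  smoking_quit_date <- as.Date(ifelse(quit, as.character(quit_dates),
                                      NA_character_))

  social_history <- tibble::tibble(
    patient_id = patient_id,
    alcohol_drinks_per_week = drinks,
    smoking_status = smoking_status,
    smoking_quit_date = smoking_quit_date
  )

  list(patients = patients, encounters = encounters,
       social_history = social_history)
}

# First ICD-9 equivalent for each mapped ICD-10 code (used when recoding
# a fraction of generated records to the legacy system).
icd10_to_icd9 <- function() {
  map <- icd9_equivalents()
  map[!duplicated(map$icd10), c("icd10", "icd9")]
}

#' Generate synthetic SBDH diagnosis records
#'
#' Each patient is SBDH-positive for a domain independently with
#' probability `icd_prevalence[domain]`. A positive patient receives
#' exactly one subtype code for that domain, drawn proportionally to the
#' reference subtype patient counts stored in the lexicon, so subtype
#' counts reconcile exactly to domain totals. A configurable fraction of
#' records is recoded to approximate ICD-9 equivalents. Records carry a
#' `domain` provenance tag so that the shared code Z59.8 (housing /
#' economic circumstances) can be attributed per-domain downstream.
#'
#' @param config An `sbdh_sim_config`.
#' @param population Output of [generate_population()].
#' @param lexicon_set An `sbdh_lexicon_set` supplying per-domain code
#'   inventories and reference subtype counts.
#' @return A list: `diagnoses` (tibble of diagnosis records) and
#'   `structured_flags` (tibble `patient_id`, `domain` of planted
#'   positives).
#' @export
generate_diagnoses <- function(config, population, lexicon_set) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  patients <- population$patients$patient_id
  n <- length(patients)
  to9 <- icd10_to_icd9()

  recs <- list()
  flags <- list()
  for (domain in names(config$icd_prevalence)) {
    lex <- lexicon_set[[domain]]
    if (is.null(lex) || nrow(lex$codes) == 0) {
      stop("lexicon has no codes for domain ", domain, call. = FALSE)
    }
    p <- config$icd_prevalence[[domain]]
    pos <- if (n > 0) which(stats::runif(n) < p) else integer()
    if (length(pos) == 0) next
    codes <- lex$codes
    idx <- sample.int(nrow(codes), length(pos), replace = TRUE,
                      prob = codes$reference_count)
    code <- codes$code[idx]
    system <- rep("ICD-10-CM", length(pos))
    legacy <- stats::runif(length(pos)) < config$icd9_fraction
    m <- match(code, to9$icd10)
    recode <- legacy & !is.na(m)
    code[recode] <- to9$icd9[m[recode]]
    system[recode] <- "ICD-9-CM"
    recs[[domain]] <- tibble::tibble(
      patient_id = patients[pos],
      encounter_id = sprintf("D%s%06d", substr(domain, 1, 1), seq_along(pos)),
      system = system,
      code = code,
      date = sample_dates(length(pos), config$structured_window),
      source = sample(c("problem_list", "billing", "encounter"),
                      length(pos), replace = TRUE),
      domain = domain
    )
    flags[[domain]] <- tibble::tibble(
      patient_id = patients[pos], domain = domain
    )
  }
  diagnoses <- dplyr::bind_rows(recs)
  if (nrow(diagnoses) == 0) {
    diagnoses <- tibble::tibble(
      patient_id = character(), encounter_id = character(),
      system = character(), code = character(), date = as.Date(character()),
      source = character(), domain = character()
    )
  }
  structured_flags <- dplyr::bind_rows(flags)
  if (nrow(structured_flags) == 0) {
    structured_flags <- tibble::tibble(
      patient_id = character(), domain = character()
    )
  }
  list(diagnoses = diagnoses, structured_flags = structured_flags)
}

# Filler sentence vocabulary; verified at generation time to contain no
# lexicon phrase, so planted gold labels are exact.
filler_vocabulary <- function() {
  c(
    "Vital signs stable and within normal limits.",
    "Medications reviewed and reconciled.",
    "Patient seen in clinic for routine follow up.",
    "Lungs clear to auscultation bilaterally.",
    "Follow up in two weeks.",
    "Labs ordered and pending review.",
    "Blood pressure well controlled on current regimen.",
    "No acute distress noted on examination.",
    "Continue current medications as prescribed.",
    "Diet and exercise counseling provided.",
    "Immunizations up to date.",
    "Patient tolerated the visit well.",
    "Heart rate regular without murmur.",
    "Reviewed imaging results during the visit.",
    "Plan discussed and agreed.",
    "Abdomen soft and nontender.",
    "Neurologic examination grossly intact.",
    "Encouraged adequate hydration and rest.",
    "Sleep pattern reported as adequate.",
    "Return precautions reviewed."
  )
}

assert_phrase_free <- function(sentences, matcher) {
  hits <- matcher_scan(matcher, gsub("\\s+", " ", sentences, perl = TRUE))
  if (nrow(hits) > 0) {
    stop("filler vocabulary contains lexicon phrase(s): ",
         paste(unique(hits$pattern_id), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# Build one planted sentence for a domain/context. Returns the sentence,
# the matched surface string, and its 0-based offset within the sentence.
planted_sentence <- function(domain, context, lexicon, matcher) {
  if (context == "smartphrase_negative") {
    tpl <- lexicon$smartphrase_templates[[1]]
    sentence <- paste0(tpl$question_text, " ", tpl$negative_token, ".")
    hit <- matcher_scan(matcher, sentence)
    hit <- hit[hit$domain == domain, ][1, ]
    return(list(
      sentence = sentence,
      surface = substring(sentence, hit$start + 1L, hit$end),
      offset = hit$start
    ))
  }
  phrase <- sample(lexicon$patterns$phrase, 1)
  if (context == "affirmative") {
    prefix <- "Patient reports "
    sentence <- paste0(prefix, phrase, " at this time.")
  } else if (context == "negated") {
    prefix <- "Patient denies "
    sentence <- paste0(prefix, phrase, ".")
  } else { # other_referent
    who <- sample(c("brother", "sister", "mother"), 1)
    prefix <- paste0("Patient's ", who, " has ")
    sentence <- paste0(prefix, phrase, ".")
  }
  list(sentence = sentence, surface = phrase, offset = nchar(prefix))
}

# Assemble a note from filler sentences plus planted sentences inserted at
# random positions, joined by randomly varied separators, and return the
# text with exact raw-character spans of each planted phrase.
assemble_note <- function(filler, planted, vary_seps = TRUE) {
  sentences <- as.list(filler)
  meta <- vector("list", length(filler))
  for (p in planted) {
    pos <- sample.int(length(sentences) + 1L, 1)
    sentences <- append(sentences, list(p$sentence), after = pos - 1L)
    meta <- append(meta, list(p), after = pos - 1L)
  }
  n_sent <- length(sentences)
  seps <- if (vary_seps && n_sent > 1) {
    sample(c(" ", "\n", "  "), n_sent - 1L, replace = TRUE,
           prob = c(0.8, 0.1, 0.1))
  } else {
    rep(" ", max(n_sent - 1L, 0L))
  }
  lens <- vapply(sentences, nchar, integer(1))
  starts <- cumsum(c(0L, lens[-n_sent] + nchar(seps)))
  text <- paste0(unlist(sentences),
                 c(seps, ""), collapse = "")
  mentions <- list()
  for (j in seq_len(n_sent)) {
    p <- meta[[j]]
    if (is.null(p)) next
    start <- starts[j] + p$offset
    mentions[[length(mentions) + 1L]] <- tibble::tibble(
      domain = p$domain,
      phrase = p$surface,
      start = start,
      end = start + nchar(p$surface),
      context_class = p$context
    )
  }
  list(text = text, mentions = dplyr::bind_rows(mentions))
}

#' Generate synthetic clinical notes with planted SBDH mentions
#'
#' Every patient receives at least one note (so every patient counts in
#' the unstructured denominator). For each text-mined domain a patient is
#' gold-positive with probability `note_prevalence[domain]`, in which case
#' one of their notes carries an affirmative planted mention of a domain
#' phrase. Independently, confounder mentions (SmartPhrase answered "No",
#' negated, or other-referent contexts, drawn from `context_mixture`) are
#' planted at `confounder_rate` without setting the gold flag. Filler text
#' is drawn from a vocabulary verified to contain no lexicon phrase, so
#' the planted spans are the complete gold standard.
#'
#' @param config An `sbdh_sim_config`.
#' @param population Output of [generate_population()].
#' @param lexicon_set An `sbdh_lexicon_set`.
#' @return A list: `notes` (tibble of note documents), `mentions` (gold
#'   mention spans with context classes), `patient_flags` (tibble
#'   `patient_id`, `domain` of gold-positive patients).
#' @export
generate_notes <- function(config, population, lexicon_set) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  patients <- population$patients$patient_id
  n <- length(patients)
  matcher <- compile_matcher(lexicon_set)
  vocab <- filler_vocabulary()
  assert_phrase_free(vocab, matcher)

  if (n == 0) {
    return(list(
      notes = tibble::tibble(
        note_id = character(), patient_id = character(),
        encounter_id = character(), note_type = character(),
        provider_role = character(), date = as.Date(character()),
        text = character()
      ),
      mentions = tibble::tibble(
        note_id = character(), domain = character(), phrase = character(),
        start = integer(), end = integer(), context_class = character()
      ),
      patient_flags = tibble::tibble(
        patient_id = character(), domain = character()
      )
    ))
  }

  k <- shifted_poisson(n, config$notes_per_patient)
  n_notes <- sum(k)
  note_id <- sprintf("N%08d", seq_len(n_notes))
  note_patient <- rep(seq_len(n), k)
  first_note <- cumsum(c(1L, k[-n]))

  provider_role <- sample(names(config$provider_role_mixture), n_notes,
                          replace = TRUE,
                          prob = config$provider_role_mixture)
  note_type <- sample(names(config$note_type_mixture), n_notes,
                      replace = TRUE, prob = config$note_type_mixture)
  dates <- sample_dates(n_notes, config$unstructured_window)

  # planted mention bookkeeping: note index -> list of planted sentences
  planted <- vector("list", n_notes)
  flags <- list()
  domains <- names(config$note_prevalence)
  for (domain in domains) {
    lex <- lexicon_set[[domain]]
    if (is.null(lex)) {
      stop("lexicon missing domain ", domain, call. = FALSE)
    }
    pos <- which(stats::runif(n) < config$note_prevalence[[domain]])
    if (length(pos)) {
      flags[[domain]] <- tibble::tibble(
        patient_id = patients[pos], domain = domain
      )
      for (i in pos) {
        j <- first_note[i] + sample.int(k[i], 1) - 1L
        p <- planted_sentence(domain, "affirmative", lex, matcher)
        p$domain <- domain
        p$context <- "affirmative"
        planted[[j]] <- c(planted[[j]], list(p))
      }
    }
    conf <- which(stats::runif(n) < config$confounder_rate)
    for (i in conf) {
      j <- first_note[i] + sample.int(k[i], 1) - 1L
      ctx <- sample(names(config$context_mixture), 1,
                    prob = config$context_mixture)
      p <- planted_sentence(domain, ctx, lex, matcher)
      p$domain <- domain
      p$context <- ctx
      planted[[j]] <- c(planted[[j]], list(p))
    }
  }

  n_fill <- sample(2:4, n_notes, replace = TRUE)
  has_planted <- !vapply(planted, is.null, logical(1))
  text <- character(n_notes)
  # filler-only notes: vectorised assembly with single-space separators
  plain <- which(!has_planted)
  if (length(plain)) {
    text[plain] <- vapply(plain, function(j) {
      paste(sample(vocab, n_fill[j], replace = TRUE), collapse = " ")
    }, character(1))
  }
  mention_rows <- list()
  for (j in which(has_planted)) {
    filler <- sample(vocab, n_fill[j], replace = TRUE)
    note <- assemble_note(filler, planted[[j]])
    text[j] <- note$text
    m <- note$mentions
    m$note_id <- note_id[j]
    mention_rows[[length(mention_rows) + 1L]] <- m
  }
  mentions <- dplyr::bind_rows(mention_rows)
  if (nrow(mentions) == 0) {
    mentions <- tibble::tibble(
      note_id = character(), domain = character(), phrase = character(),
      start = integer(), end = integer(), context_class = character()
    )
  } else {
    mentions <- mentions[, c("note_id", "domain", "phrase", "start",
                             "end", "context_class")]
  }
  patient_flags <- dplyr::bind_rows(flags)
  if (nrow(patient_flags) == 0) {
    patient_flags <- tibble::tibble(
      patient_id = character(), domain = character()
    )
  }

  list(
    notes = tibble::tibble(
      note_id = note_id,
      patient_id = patients[note_patient],
      encounter_id = sprintf("NE%07d", seq_len(n_notes)),
      note_type = note_type,
      provider_role = provider_role,
      date = dates,
      text = text
    ),
    mentions = mentions,
    patient_flags = patient_flags
  )
}

#' Generate the 100-note homelessness annotation fixture
#'
#' Builds a deterministic corpus emulating a manual annotation of 100
#' notes for the homelessness subdomain. The note-class composition is
#' fixed by construction and independent of the seed (the seed varies only
#' the surface filler text and note ordering):
#'
#' * 64 notes with only affirmative (true positive) mentions, 20 of which
#'   carry a second affirmative mention;
#' * 14 notes with only false-positive-context mentions (7 negated, 7
#'   other-referent);
#' * 20 notes whose only mentions are SmartPhrase questions answered
#'   negatively (`"Is Patient Homeless? No."`), 8 of which carry a second
#'   identical SmartPhrase block;
#' * 2 mixed notes with one affirmative and one false-positive-context
#'   mention each.
#'
#' The token `homeless` therefore occurs exactly 130 times across the
#' corpus (44 + 2*20 + 14 + 12 + 2*8 + 2*2), with the 30 occurrences beyond
#' one-per-note distributed 20 / 8 / 2 over the affirmative, SmartPhrase,
#' and mixed notes.
#'
#' @param seed Integer seed controlling surface text variation only.
#' @return A list: `notes` (100 note documents), `gold` (gold mention
#'   labels with spans and `gold_class` in true_positive / false_positive
#'   / true_negative), `note_class` (the planted note-level class).
#' @export
generate_annotation_fixture <- function(seed = 1L) {
  set.seed(as.integer(seed))
  vocab <- setdiff(filler_vocabulary(), character())

  tp_sentences <- c(
    "Patient is homeless and sleeping outside at night.",
    "Patient reports being homeless since last winter.",
    "He has been homeless for several months."
  )
  fp_negated <- "Patient denies being homeless."
  fp_referent <- "Patient's brother is homeless."
  tn_block <- "Is Patient Homeless? No."

  token_offset <- function(sentence) {
    m <- regexpr("(?i)(?<![[:alnum:]])homeless(?![[:alnum:]])",
                 sentence, perl = TRUE)
    as.integer(m) - 1L
  }

  make <- function(kind) {
    if (kind == "tp1" || kind == "tp2") {
      s <- sample(tp_sentences, if (kind == "tp2") 2 else 1)
      lapply(s, function(x) list(sentence = x, surface = "homeless",
                                 offset = token_offset(x),
                                 domain = "housing",
                                 context = "affirmative",
                                 gold = "true_positive"))
    } else if (kind == "fp_neg") {
      list(list(sentence = fp_negated, surface = "homeless",
                offset = token_offset(fp_negated), domain = "housing",
                context = "negated", gold = "false_positive"))
    } else if (kind == "fp_ref") {
      list(list(sentence = fp_referent, surface = "homeless",
                offset = token_offset(fp_referent), domain = "housing",
                context = "other_referent", gold = "false_positive"))
    } else if (kind == "tn1" || kind == "tn2") {
      reps <- if (kind == "tn2") 2 else 1
      lapply(seq_len(reps), function(i) {
        list(sentence = tn_block, surface = "Homeless",
             offset = token_offset(tn_block), domain = "housing",
             context = "smartphrase_negative", gold = "true_negative")
      })
    } else { # mixed: one affirmative + one negated false positive
      s <- sample(tp_sentences, 1)
      list(
        list(sentence = s, surface = "homeless", offset = token_offset(s),
             domain = "housing", context = "affirmative",
             gold = "true_positive"),
        list(sentence = fp_negated, surface = "homeless",
             offset = token_offset(fp_negated), domain = "housing",
             context = "negated", gold = "false_positive")
      )
    }
  }

  kinds <- sample(c(rep("tp1", 44), rep("tp2", 20), rep("fp_neg", 7),
                    rep("fp_ref", 7), rep("tn1", 12), rep("tn2", 8),
                    rep("mixed", 2)))
  class_of <- c(tp1 = "tp_only", tp2 = "tp_only", fp_neg = "fp_only",
                fp_ref = "fp_only", tn1 = "tn_only", tn2 = "tn_only",
                mixed = "conflicting")

  notes <- vector("list", 100)
  gold <- list()
  for (i in seq_len(100)) {
    planted <- make(kinds[i])
    filler <- sample(vocab, sample(2:3, 1), replace = TRUE)
    note <- assemble_note(filler, planted)
    nid <- sprintf("A%03d", i)
    notes[[i]] <- tibble::tibble(
      note_id = nid,
      patient_id = sprintf("AP%03d", i),
      encounter_id = sprintf("AE%03d", i),
      note_type = "progress_note",
      provider_role = "physician",
      date = as.Date("2017-01-01") + (i - 1L) %% 365,
      text = note$text
    )
    g <- note$mentions
    g$note_id <- nid
    g$gold_class <- vapply(
      seq_len(nrow(g)),
      function(r) {
        # mentions come back in document order; recover gold class by
        # matching context (each context maps to exactly one gold class)
        switch(g$context_class[r],
               affirmative = "true_positive",
               negated = "false_positive",
               other_referent = "false_positive",
               smartphrase_negative = "true_negative")
      },
      character(1)
    )
    gold[[i]] <- g[, c("note_id", "domain", "phrase", "start", "end",
                       "context_class", "gold_class")]
  }

  list(
    notes = dplyr::bind_rows(notes),
    gold = dplyr::bind_rows(gold),
    note_class = tibble::tibble(
      note_id = sprintf("A%03d", seq_len(100)),
      class = unname(class_of[kinds])
    )
  )
}

#' Generate a synthetic questionnaire table
#'
#' Scales the reference questionnaire registry to the simulated
#' population size: administered counts are scaled proportionally and
#' completed counts drawn binomially at each template's reference
#' completion rate.
#'
#' @param config An `sbdh_sim_config`.
#' @param reference_denominator Unique-patient denominator behind the
#'   registry counts.
#' @return A tibble like [questionnaire_registry()] with scaled counts.
#' @export
generate_questionnaires <- function(config,
                                    reference_denominator = 5401324) {
  validate_sim_config(config)
  set.seed(config$seed + 3L)
  reg <- questionnaire_registry()
  scale <- config$n_patients / reference_denominator
  administered <- pmax(1L, as.integer(round(reg$administered * scale)))
  rate <- reg$completed / reg$administered
  completed <- stats::rbinom(nrow(reg), administered, rate)
  tibble::tibble(
    domain = reg$domain,
    template = reg$template,
    content_area = reg$content_area,
    administered = administered,
    completed = completed
  )
}
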