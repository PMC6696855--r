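#' Completeness rate of a structured EHR field
#'
#' A patient counts toward the numerator when they have at least one
#' non-missing, non-empty value for the field anywhere in the table.
#' Missing means `NA`, an empty string, or whitespace only; the literal
#' category `"Unknown"` is a recorded value and counts as present (it is a
#' valid EHR value, distinct from an empty record). The composite field
#' `"address_or_zip"` counts a patient when either `address` or `zip` is
#' present. The result is invariant to row order and to duplicated rows
#' for the same patient.
#'
#' @param table A data frame with a `patient_id` column.
#' @param field_spec A column name in `table`, or `"address_or_zip"`.
#' @param denominator Number of unique patients the rate is computed
#'   against (defaults to the number of unique `patient_id`s in `table`).
#' @return A one-row tibble: `field`, `numerator`, `denominator`, `rate`
#'   (percentage, 2 decimals; `NA` with a warning when the denominator is
#'   zero).
#' @export
completeness_rate <- function(table, field_spec,
                              denominator = dplyr::n_distinct(table$patient_id)) {
  if (identical(field_spec, "address_or_zip")) {
    if (!all(c("address", "zip") %in% names(table))) {
      stop("composite field address_or_zip needs columns 'address' and 'zip'",
           call. = FALSE)
    }
    present <- !is_missing_value(table$address) | !is_missing_value(table$zip)
  } else {
    if (!field_spec %in% names(table)) {
      stop("unknown field: ", field_spec, call. = FALSE)
    }
    present <- !is_missing_value(table[[field_spec]])
  }
  numerator <- dplyr::n_distinct(table$patient_id[present])
  if (denominator == 0) {
    warning("denominator is zero; completeness rate undefined",
            call. = FALSE)
    rate <- NA_real_
  } else {
    rate <- percent(numerator, denominator)
  }
  tibble::tibble(
    field = field_spec,
    numerator = numerator,
    denominator = denominator,
    rate = rate
  )
}

#' Approximate ICD-9 equivalents of the SBDH ICD-10 codes
#'
#' A minimal crosswalk used to include legacy ICD-9-coded diagnoses in
#' cohort queries. The mapping is deliberately small and marked
#' approximate: V-code social circumstance categories do not align
#' one-to-one with the ICD-10 Z codes.
#'
#' @return A tibble with columns `icd9`, `icd10`, `approximate`.
#' @export
icd9_equivalents <- function() {
  tibble::tribble(
    ~icd9,   ~icd10,  ~approximate,
    "V60.0", "Z59.0", FALSE,
    "V60.1", "Z59.1", FALSE,
    "V60.2", "Z59.6", FALSE,
    "V60.8", "Z59.8", TRUE,
    "V60.9", "Z59.8", TRUE,
    "V62.4", "Z60.4", TRUE,
    "V61.0", "Z63.0", TRUE,
    "V61.0", "Z63.5", TRUE
  )
}

#' Diagnosis-based SBDH cohort query
#'
#' Returns the unique patients having at least one diagnosis matching the
#' supplied code entries within a date window, from any source (problem
#' list, billing, or encounter diagnosis). Each patient is counted once
#' regardless of how many qualifying encounters they have. When
#' `include_icd9 = TRUE`, ICD-9 records whose code maps to one of the
#' requested ICD-10 codes via [icd9_equivalents()] also qualify.
#'
#' @param diagnoses A data frame with columns `patient_id`, `system`,
#'   `code`, `date`, and optionally a `domain` provenance column (written
#'   by the synthetic generator).
#' @param code_entries A data frame with columns `system`, `code` (e.g. a
#'   lexicon's `codes` table, which may flag `shared_code` entries), or a
#'   character vector of ICD-10 codes.
#' @param window Length-2 vector of dates (closed interval); `NULL` for no
#'   date filter.
#' @param include_icd9 Include mapped ICD-9 equivalents (default `TRUE`).
#' @param domain When given and the diagnosis table carries a `domain`
#'   column, records matching a `shared_code` entry (Z59.8 belongs to both
#'   housing and economic circumstances) only qualify when their
#'   provenance matches this domain. On tables without provenance the
#'   query falls back to code-only matching, in which case shared codes
#'   cannot be disambiguated.
#' @return Character vector of unique patient ids.
#' @export
diagnosis_cohort <- function(diagnoses, code_entries, window = NULL,
                             include_icd9 = TRUE, domain = NULL) {
  if (is.character(code_entries)) {
    code_entries <- tibble::tibble(system = "ICD-10-CM", code = code_entries)
  }
  if (nrow(code_entries) == 0) {
    stop("empty code list", call. = FALSE)
  }
  icd10 <- code_entries$code[code_entries$system == "ICD-10-CM"]
  shared <- if ("shared_code" %in% names(code_entries)) {
    code_entries$code[code_entries$shared_code %in% TRUE]
  } else {
    character()
  }

  # resolve each record to an effective ICD-10 code
  eff <- ifelse(diagnoses$system == "ICD-10-CM", diagnoses$code,
                NA_character_)
  if (include_icd9) {
    map <- icd9_equivalents()
    is9 <- diagnoses$system == "ICD-9-CM"
    m <- match(diagnoses$code[is9], map$icd9)
    eff[is9] <- map$icd10[m]
  }
  hit <- !is.na(eff) & eff %in% icd10

  if (!is.null(domain) && "domain" %in% names(diagnoses) &&
      length(shared)) {
    is_shared <- !is.na(eff) & eff %in% shared
    hit <- hit & (!is_shared | diagnoses$domain %in% domain)
  }
  if (!is.null(window)) {
    d <- as.Date(diagnoses$date)
    hit <- hit & d >= as.Date(window[1]) & d <= as.Date(window[2])
  }
  unique(diagnoses$patient_id[hit])
}

#' Summarise subtype cohorts into a domain-level cohort result
#'
#' Reports each subtype code's unique patient count and the size of the
#' union of all subtype cohorts as the domain total. The domain percentage
#' is computed against the structured-data denominator; subtype rows carry
#' counts only, matching how coded-diagnosis inventories are conventionally
#' reported.
#'
#' @param subtype_cohorts Named list mapping subtype code to a vector of
#'   patient ids.
#' @param domain Domain identifier for the result.
#' @param denominator Unique-patient denominator for the percentage.
#' @return A list of class `sbdh_cohort_result`: `domain`, `subtypes`
#'   (tibble of `code`, `n`), `domain_total`, `pct`.
#' @export
domain_summary <- function(subtype_cohorts, domain = NA_character_,
                           denominator = NULL) {
  if (length(subtype_cohorts) == 0) {
    stop("no subtype cohorts supplied", call. = FALSE)
  }
  subtypes <- tibble::tibble(
    code = names(subtype_cohorts),
    n = unname(vapply(subtype_cohorts, function(x) length(unique(x)),
                      integer(1)))
  )
  total <- length(unique(unlist(subtype_cohorts, use.names = FALSE)))
  pct <- if (is.null(denominator)) NA_real_ else percent(total, denominator)
  structure(
    list(
      domain = domain,
      subtypes = subtypes,
      domain_total = total,
      pct = pct
    ),
    class = "sbdh_cohort_result"
  )
}

#' Questionnaire completion rates
#'
#' Computes, per questionnaire template, the percentage of administered
#' questionnaires whose SBDH-related questions were answered.
#'
#' @param records A data frame with columns `template`, `administered`,
#'   `completed` (and optionally `content_area`).
#' @return `records` with a `rate` column (percentage, 2 decimals; `NA`
#'   with a warning where `administered` is zero).
#' @export
questionnaire_completion <- function(records) {
  if (any(records$completed > records$administered)) {
    bad <- records$template[records$completed > records$administered]
    stop("completed exceeds administered for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(records$completed < 0)) {
    stop("negative completed count", call. = FALSE)
  }
  rate <- rep(NA_real_, nrow(records))
  ok <- records$administered > 0
  if (any(!ok)) {
    warning("administered is zero for some templates; rate undefined",
            call. = FALSE)
  }
  rate[ok] <- percent(records$completed[ok], records$administered[ok])
  out <- tibble::as_tibble(records)
  out$rate <- rate
  out
}

#' Reference questionnaire template registry
#'
#' The catalogue of EHR-embedded questionnaire templates touching the
#' selected SBDH domains, with administered and completed counts from the
#' reference health system. Used by the synthetic generator to scale a
#' questionnaire table and as a worked input for
#' [questionnaire_completion()].
#'
#' @return A tibble: `domain`, `template`, `content_area`, `administered`,
#'   `completed`.
#' @export
questionnaire_registry <- function() {
  tibble::tribble(
    ~domain, ~template, ~content_area, ~administered, ~completed,
    "social_connection", "Nursing assessment",
      "Psychological-social relationship", 1026988L, 944829L,
    "social_connection", "ED head-to-toe",
      "Psychological-social relationship", 237143L, 92486L,
    "social_connection", "ED nursing 1",
      "Psychological-social relationship", 217954L, 204877L,
    "social_connection", "ED nursing 2",
      "Psychological-social relationship", 278084L, 169631L,
    "social_connection", "ED pediatrics",
      "Psychological-social relationship", 131134L, 93105L,
    "social_connection", "ED social work suicide/homicide",
      "Relationship and social support status", 15101L, 14648L,
    "social_connection", "ED social work",
      "Support system's name and information", 14481L, 12743L,
    "social_connection", "OR and PACU flowsheet",
      "Psychological-social relationship", 147694L, 82709L,
    "social_connection", "OT new home setup",
      "Social support available at discharge", 131948L, 47501L,
    "social_connection", "Obstetrics postpartum assessment",
      "Recent loss or change in status", 135587L, 120672L,
    "social_connection", "Spiritual care interventions",
      "Spiritual/social network", 116719L, 68864L,
    "social_connection", "Pediatrics screening",
      "Personal-social relationship", 144659L, 85349L,
    "social_connection", "Social history SBIRT",
      "Marital status / social network", 2015L, 1995L,
    "housing", "Housing/utility voucher",
      "Housing assistance screening and referral", 217L, 97L,
    "housing", "Abuse/neglect screen",
      "Homelessness assessment", 12058L, 11575L,
    "housing", "Social history questionnaire",
      "Screening for assistance with finding housing", 1900L, 1824L,
    "housing", "ED triage abuse indicators",
      "Information on shelter, transportation, and clothing",
      713702L, 39254L,
    "housing", "Chemical dependence unit admission screen",
      "Homelessness", 15056L, 2258L,
    "housing", "Ambulatory priority access primary care screen",
      "Housing situation", 1116L, 78L,
    "housing", "Adult admission general intake form",
      "Homelessness", 77230L, 27030L,
    "housing", "Pediatric/newborn general intake form",
      "Homelessness", 1067L, 587L,
    "housing", "Psychiatry social work assessment",
      "Living arrangement", 4913L, 4422L
  )
}
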