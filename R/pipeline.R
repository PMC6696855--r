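#' Completeness report over the structured tables
#'
#' Computes the completeness rate of each screened structured field:
#' the composite `address_or_zip`, `race`, `ethnicity`, and
#' `preferred_language` from the patient table, and `alcohol_use`
#' (drinks per week) and `smoking_status` from the social-history table,
#' all against the unique-patient denominator of the patient table.
#'
#' @param patients Patient table.
#' @param social_history Social-history table.
#' @return A tibble with one row per field (see [completeness_rate()]).
#' @export
completeness_report <- function(patients, social_history) {
  denom <- dplyr::n_distinct(patients$patient_id)
  dplyr::bind_rows(
    completeness_rate(patients, "address_or_zip", denom),
    completeness_rate(patients, "race", denom),
    completeness_rate(patients, "ethnicity", denom),
    completeness_rate(patients, "preferred_language", denom),
    {
      x <- completeness_rate(
        dplyr::rename(social_history,
                      alcohol_use = "alcohol_drinks_per_week"),
        "alcohol_use", denom
      )
      x
    },
    completeness_rate(social_history, "smoking_status", denom)
  )
}

#' Diagnosis cohort report over all text-mined domains
#'
#' Runs [diagnosis_cohort()] per subtype code and [domain_summary()] per
#' domain, against the unique-patient denominator of the patient table.
#'
#' @param diagnoses Diagnosis table.
#' @param patients Patient table (denominator source).
#' @param lexicon_set An `sbdh_lexicon_set`.
#' @param window Structured date window (closed interval) or `NULL`.
#' @param include_icd9 Include mapped ICD-9 equivalents.
#' @return A named list of `sbdh_cohort_result`, one per domain.
#' @export
cohort_report <- function(diagnoses, patients, lexicon_set, window = NULL,
                          include_icd9 = TRUE) {
  denom <- dplyr::n_distinct(patients$patient_id)
  out <- list()
  for (domain in names(lexicon_set)) {
    codes <- lexicon_set[[domain]]$codes
    cohorts <- lapply(seq_len(nrow(codes)), function(i) {
      diagnosis_cohort(diagnoses, codes[i, ], window = window,
                       include_icd9 = include_icd9, domain = domain)
    })
    names(cohorts) <- codes$code
    out[[domain]] <- domain_summary(cohorts, domain = domain,
                                    denominator = denom)
  }
  out
}

cohort_results_to_tibble <- function(cohorts) {
  dplyr::bind_rows(lapply(cohorts, function(cr) {
    dplyr::bind_rows(
      tibble::tibble(
        domain = cr$domain, row_type = "domain", code = NA_character_,
        n = cr$domain_total, pct = cr$pct
      ),
      tibble::tibble(
        domain = cr$domain, row_type = "subtype", code = cr$subtypes$code,
        n = cr$subtypes$n, pct = NA_real_
      )
    )
  }))
}

#' Combined structured/unstructured SBDH table
#'
#' Renders one row per domain with the diagnosis-based cohort count and
#' percentage alongside the note-mining patient count and percentage,
#' followed by the per-code subtype rows (structured only — subtype rows
#' carry counts without percentages, and free-text mining does not
#' distinguish subtypes). A domain present in only one of the two reports
#' gets `NA` in the other's columns; an empty cohort report renders as
#' structured zeros.
#'
#' @param cohorts Output of [cohort_report()] (may be an empty list).
#' @param prevalence Output of [patient_prevalence()].
#' @return A tibble: `domain`, `row_type`, `code`, `structured_n`,
#'   `structured_pct`, `unstructured_n`, `unstructured_pct`.
#' @export
render_table2_like <- function(cohorts, prevalence) {
  domains <- union(names(cohorts), prevalence$domain)
  rows <- list()
  for (domain in domains) {
    cr <- cohorts[[domain]]
    pr <- prevalence[prevalence$domain == domain, ]
    if (is.null(cr) && length(cohorts) == 0) {
      s_n <- 0L
      s_pct <- 0
    } else if (is.null(cr)) {
      s_n <- NA_integer_
      s_pct <- NA_real_
    } else {
      s_n <- cr$domain_total
      s_pct <- cr$pct
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      domain = domain, row_type = "domain", code = NA_character_,
      structured_n = s_n, structured_pct = s_pct,
      unstructured_n = if (nrow(pr)) pr$patients_flagged else NA_integer_,
      unstructured_pct = if (nrow(pr)) pr$pct else NA_real_
    )
    if (!is.null(cr)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        domain = domain, row_type = "subtype", code = cr$subtypes$code,
        structured_n = cr$subtypes$n, structured_pct = NA_real_,
        unstructured_n = NA_integer_, unstructured_pct = NA_real_
      )
    }
  }
  dplyr::bind_rows(rows)
}

read_input <- function(path, what, reader) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  reader(path)
}

read_notes_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  out <- dplyr::bind_rows(lapply(lines, function(l) {
    tibble::as_tibble(jsonlite::fromJSON(l))
  }))
  if ("date" %in% names(out)) out$date <- as.Date(out$date)
  out
}

write_notes_jsonl <- function(notes, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(notes))) {
    row <- as.list(notes[i, ])
    row$date <- as.character(row$date)
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Run the full screening pipeline
#'
#' Orchestrates simulate, structured screen, note mining, annotation
#' evaluation, and report rendering. By default a synthetic EHR is
#' generated from `config` and written alongside the reports; existing
#' extracts can be supplied instead via the `*_path` arguments (a missing
#' file is an error naming the path). Identical `config` (including its
#' seed) reproduces byte-identical reports.
#'
#' Report files written to `out_dir`: `completeness_report.csv`,
#' `cohort_report.csv`, `prevalence_report.csv`, `strata_report.csv`,
#' `table2_like.csv`, `questionnaire_report.csv`, `tally_report.json`.
#'
#' @param out_dir Output directory (created if needed).
#' @param config An `sbdh_sim_config`; used for simulation and for the
#'   annotation-fixture seed.
#' @param lexicon_set Lexicon set (default [default_lexicon()]).
#' @param mode `"filtered"` (context-aware note flags) or `"raw"`.
#' @param include_icd9 Include ICD-9 equivalents in cohort queries.
#' @param patients_path,social_history_path,diagnoses_path,notes_path
#'   Optional paths to existing extracts (CSV / JSONL); when given, those
#'   stages use the files instead of the simulation.
#' @param write_data Also write the simulated tables (`patients.csv`,
#'   `encounters.csv`, `social_history.csv`, `diagnoses.csv`,
#'   `questionnaires.csv`, `notes.jsonl`, `ground_truth.jsonl`) to
#'   `out_dir`.
#' @return Invisibly, a list with the in-memory reports and the paths of
#'   every file written.
#' @export
run_pipeline <- function(out_dir,
                         config = sim_config(),
                         lexicon_set = default_lexicon(),
                         mode = c("filtered", "raw"),
                         include_icd9 = TRUE,
                         patients_path = NULL,
                         social_history_path = NULL,
                         diagnoses_path = NULL,
                         notes_path = NULL,
                         write_data = FALSE) {
  mode <- match.arg(mode)
  validate_lexicon(lexicon_set)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  read_csv_ <- function(path) {
    tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  }
  simulate <- is.null(patients_path) && is.null(notes_path) &&
    is.null(diagnoses_path)

  if (simulate) {
    pop <- generate_population(config)
    dx <- generate_diagnoses(config, pop, lexicon_set)
    nt <- generate_notes(config, pop, lexicon_set)
    qn <- generate_questionnaires(config)
    patients <- pop$patients
    social_history <- pop$social_history
    diagnoses <- dx$diagnoses
    notes <- nt$notes
    if (write_data) {
      utils::write.csv(patients, file.path(out_dir, "patients.csv"),
                       row.names = FALSE)
      utils::write.csv(pop$encounters, file.path(out_dir, "encounters.csv"),
                       row.names = FALSE)
      utils::write.csv(social_history,
                       file.path(out_dir, "social_history.csv"),
                       row.names = FALSE)
      utils::write.csv(diagnoses, file.path(out_dir, "diagnoses.csv"),
                       row.names = FALSE)
      utils::write.csv(qn, file.path(out_dir, "questionnaires.csv"),
                       row.names = FALSE)
      write_notes_jsonl(notes, file.path(out_dir, "notes.jsonl"))
      gt <- nt$mentions
      jsonlite::stream_out(gt, file(file.path(out_dir, "ground_truth.jsonl")),
                           verbose = FALSE)
    }
  } else {
    if (is.null(patients_path) || is.null(notes_path)) {
      stop("file-based runs need at least patients_path and notes_path",
           call. = FALSE)
    }
    patients <- read_input(patients_path, "patients", read_csv_)
    social_history <- if (is.null(social_history_path)) {
      tibble::tibble(patient_id = patients$patient_id,
                     alcohol_drinks_per_week = NA_real_,
                     smoking_status = NA_character_)
    } else {
      read_input(social_history_path, "social history", read_csv_)
    }
    diagnoses <- if (is.null(diagnoses_path)) {
      tibble::tibble(patient_id = character(), encounter_id = character(),
                     system = character(), code = character(),
                     date = as.Date(character()), source = character())
    } else {
      read_input(diagnoses_path, "diagnoses", read_csv_)
    }
    notes <- read_input(notes_path, "notes", read_notes_jsonl)
    qn <- questionnaire_registry()
  }

  message("screening structured data: ",
          dplyr::n_distinct(patients$patient_id), " patients, ",
          nrow(diagnoses), " diagnosis records")
  comp <- completeness_report(patients, social_history)
  cohorts <- cohort_report(diagnoses, patients, lexicon_set,
                           window = config$structured_window,
                           include_icd9 = include_icd9)
  qrep <- questionnaire_completion(qn)

  message("mining ", nrow(notes), " notes")
  mentions <- mine_notes(notes, lexicon_set)
  flagged <- note_flags(mentions, mode)
  prevalence <- patient_prevalence(flagged, notes)
  strata <- dplyr::bind_rows(
    dplyr::mutate(stratify(mentions, notes, "provider_role"),
                  by = "provider_role"),
    dplyr::mutate(stratify(mentions, notes, "note_type"),
                  by = "note_type")
  )
  table2 <- render_table2_like(cohorts, prevalence)

  fixture <- generate_annotation_fixture(config$seed)
  tally <- tally_annotations(fixture$gold, fixture$notes)

  paths <- list(
    completeness = file.path(out_dir, "completeness_report.csv"),
    cohort = file.path(out_dir, "cohort_report.csv"),
    questionnaire = file.path(out_dir, "questionnaire_report.csv"),
    prevalence = file.path(out_dir, "prevalence_report.csv"),
    strata = file.path(out_dir, "strata_report.csv"),
    table2 = file.path(out_dir, "table2_like.csv"),
    tally = file.path(out_dir, "tally_report.json")
  )
  utils::write.csv(comp, paths$completeness, row.names = FALSE)
  utils::write.csv(cohort_results_to_tibble(cohorts), paths$cohort,
                   row.names = FALSE)
  utils::write.csv(qrep, paths$questionnaire, row.names = FALSE)
  utils::write.csv(prevalence, paths$prevalence, row.names = FALSE)
  utils::write.csv(strata, paths$strata, row.names = FALSE)
  utils::write.csv(table2, paths$table2, row.names = FALSE)
  jsonlite::write_json(unclass(tally), paths$tally, auto_unbox = TRUE,
                       digits = NA)

  invisible(list(
    completeness = comp, cohorts = cohorts, questionnaires = qrep,
    mentions = mentions, prevalence = prevalence, strata = strata,
    table2 = table2, tally = tally, paths = paths
  ))
}
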