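#' Mine a note corpus for classified SBDH mentions
#'
#' Runs the full unstructured-data pipeline over a note table: normalise
#' each note, locate every lexicon phrase occurrence, detect SmartPhrase
#' question/answer blocks, and classify each mention's context. Scanning
#' is vectorised over the corpus; per-note offset mapping and context
#' classification run only for notes that contain at least one hit.
#'
#' @param notes A data frame of note documents with columns `note_id` and
#'   `text` (metadata columns are carried along by downstream ops).
#' @param lexicon_set An `sbdh_lexicon_set`.
#' @return A tibble of classified mention spans: `note_id`, `domain`,
#'   `pattern_id`, `start`, `end`, `matched_text`, `context_class`.
#' @export
mine_notes <- function(notes, lexicon_set) {
  matcher <- compile_matcher(lexicon_set)
  if (nrow(notes) == 0) {
    return(empty_mentions())
  }
  norm_texts <- gsub("\\s+", " ", notes$text, perl = TRUE)
  hits <- matcher_scan(matcher, norm_texts)
  if (nrow(hits) == 0) {
    return(empty_mentions())
  }
  out <- list()
  for (j in unique(hits$text_index)) {
    note <- list(note_id = notes$note_id[j], text = notes$text[j])
    nt <- normalize_text(note$text)
    h <- hits[hits$text_index == j, ]
    raw <- norm_span_to_raw(nt$map, h$start, h$end)
    spans <- tibble::tibble(
      note_id = note$note_id,
      domain = h$domain,
      pattern_id = h$pattern_id,
      start = raw$start,
      end = raw$end,
      matched_text = substring(note$text, raw$start + 1L, raw$end),
      context_class = NA_character_
    )
    for (domain in unique(spans$domain)) {
      lex <- lexicon_set[[domain]]
      sp_hits <- if (length(lex$smartphrase_templates)) {
        detect_smartphrase(note, lex$smartphrase_templates)
      } else {
        NULL
      }
      rows <- which(spans$domain == domain)
      for (r in rows) {
        spans$context_class[r] <- classify_context(
          spans[r, ], note, lex, sp_hits
        )
      }
    }
    out[[length(out) + 1L]] <- spans
  }
  dplyr::bind_rows(out)
}

#' Note-level SBDH flags
#'
#' A note is flagged for a domain when at least one of its mentions is
#' affirmative (`affirmative` or `smartphrase_affirmative`); notes whose
#' only mentions are negated, other-referent, or SmartPhrase-negative are
#' not positive evidence. A mixed note (affirmative plus non-affirmative
#' mentions of the same phrase) flags true. In `mode = "raw"` any mention
#' counts, regardless of context — the raw-occurrence view of the corpus.
#'
#' @param spans Classified mention spans (see [mine_notes()]).
#' @param mode `"filtered"` (default, context-aware) or `"raw"`.
#' @return A tibble `note_id`, `domain` with one row per flagged
#'   note-domain pair.
#' @export
note_flags <- function(spans, mode = c("filtered", "raw")) {
  mode <- match.arg(mode)
  if (nrow(spans) == 0) {
    return(tibble::tibble(note_id = character(), domain = character()))
  }
  keep <- if (mode == "raw") {
    rep(TRUE, nrow(spans))
  } else {
    spans$context_class %in% c("affirmative", "smartphrase_affirmative")
  }
  dplyr::distinct(spans[keep, c("note_id", "domain")])
}

#' @rdname note_flags
#' @param domains Domains to report (default: the three text-mined
#'   domains).
#' @return `note_flag()` returns a named logical vector over `domains`
#'   for the spans of a single note.
#' @export
note_flag <- function(spans, domains = sbdh_domains()$text_mined,
                      mode = c("filtered", "raw")) {
  mode <- match.arg(mode)
  flagged <- note_flags(spans, mode)
  stats::setNames(domains %in% flagged$domain, domains)
}

#' Patient-level SBDH prevalence from mined notes
#'
#' Counts, per domain, the unique patients having at least one flagged
#' note; the denominator is the number of unique patients appearing in
#' the note table ("at least one" semantics — no frequency weighting).
#'
#' @param flagged Output of [note_flags()].
#' @param notes The note table the flags were computed on (must carry
#'   `note_id` and `patient_id`).
#' @param domains Domains to report.
#' @return A tibble: `domain`, `patients_flagged`, `denominator`, `pct`
#'   (percentage, 2 decimals).
#' @export
patient_prevalence <- function(flagged, notes,
                               domains = sbdh_domains()$text_mined) {
  denominator <- dplyr::n_distinct(notes$patient_id)
  if (denominator == 0) {
    warning("empty note table; prevalence undefined", call. = FALSE)
  }
  joined <- merge(flagged, notes[, c("note_id", "patient_id")],
                  by = "note_id")
  counts <- unname(vapply(domains, function(d) {
    dplyr::n_distinct(joined$patient_id[joined$domain == d])
  }, integer(1)))
  pct <- if (denominator > 0) percent(counts, denominator) else NA_real_
  tibble::tibble(
    domain = domains,
    patients_flagged = counts,
    denominator = denominator,
    pct = pct
  )
}

#' Stratify mention-bearing notes by provider role or note type
#'
#' Counts, per domain and stratum, the notes containing at least one
#' located mention (any context). Strata therefore sum to the number of
#' distinct mention-bearing note-domain pairs; notes with missing
#' metadata are grouped under `"unknown"`.
#'
#' @param spans Mention spans (classified or not).
#' @param notes The note table with metadata columns.
#' @param by `"provider_role"` or `"note_type"`.
#' @return A tibble: `domain`, `stratum`, `notes`.
#' @export
stratify <- function(spans, notes, by = c("provider_role", "note_type")) {
  by <- match.arg(by)
  if (!by %in% names(notes)) {
    stop("note table has no column ", by, call. = FALSE)
  }
  pairs <- dplyr::distinct(spans[, c("note_id", "domain")])
  meta <- notes[, c("note_id", by)]
  names(meta)[2] <- "stratum"
  joined <- merge(pairs, meta, by = "note_id")
  joined$stratum[is.na(joined$stratum) | !nzchar(joined$stratum)] <- "unknown"
  out <- dplyr::count(joined, domain, stratum, name = "notes")
  tibble::as_tibble(out)
}
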