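#' Whitespace-normalise note text with an invertible offset map
#'
#' Collapses every run of whitespace (spaces, tabs, newlines) to a single
#' space so that multi-word phrases match regardless of formatting. Case is
#' left untouched; lowercasing is the matcher's concern. The returned map
#' makes every normalised offset traceable back to the raw text.
#'
#' @param text A single character string.
#' @return A list with `text` (the normalised string) and `map`, an integer
#'   vector where `map[i]` is the 1-based raw-text index of normalised
#'   character `i` (for a collapsed run, the index of its first character).
#' @export
normalize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || !nzchar(text)) {
    return(list(text = "", map = integer()))
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  ws <- grepl("\\s", chars, perl = TRUE)
  # keep every non-whitespace char and the first char of each whitespace run
  keep <- !ws | !c(FALSE, ws[-length(ws)])
  norm_chars <- ifelse(ws, " ", chars)[keep]
  list(
    text = paste(norm_chars, collapse = ""),
    map = which(keep)
  )
}

# Inverse of the normalisation map: raw 1-based index -> normalised 1-based
# index (collapsed whitespace chars map to their run's representative).
raw_to_norm_map <- function(map, n_raw) {
  r2n <- integer(n_raw)
  r2n[map] <- seq_along(map)
  cummax(r2n)
}

# Map normalised 0-based half-open spans back to raw offsets.
norm_span_to_raw <- function(map, start0, end0) {
  list(
    start = map[start0 + 1L] - 1L,
    end = map[end0]
  )
}

#' Locate lexicon phrase occurrences in a note
#'
#' Runs the compiled matcher over the whitespace-normalised note text and
#' reports every occurrence of every phrase exactly once, with spans mapped
#' back to raw-text character offsets (0-based, half-open). Overlapping
#' occurrences of different patterns are all reported. The returned
#' `context_class` column is `NA`; see [classify_context()].
#'
#' @param note A list or one-row data frame with at least `note_id` and
#'   `text`.
#' @param matcher An `sbdh_matcher` from [compile_matcher()].
#' @return A tibble of mention spans: `note_id`, `domain`, `pattern_id`,
#'   `start`, `end`, `matched_text`, `context_class`.
#' @export
match_mentions <- function(note, matcher) {
  stopifnot(inherits(matcher, "sbdh_matcher"))
  text <- note$text
  nt <- normalize_text(text)
  hits <- matcher_scan(matcher, nt$text)
  if (nrow(hits) == 0) {
    return(empty_mentions())
  }
  raw <- norm_span_to_raw(nt$map, hits$start, hits$end)
  tibble::tibble(
    note_id = note$note_id,
    domain = hits$domain,
    pattern_id = hits$pattern_id,
    start = raw$start,
    end = raw$end,
    matched_text = substring(text, raw$start + 1L, raw$end),
    context_class = NA_character_
  )
}

empty_mentions <- function() {
  tibble::tibble(
    note_id = character(), domain = character(), pattern_id = character(),
    start = integer(), end = integer(), matched_text = character(),
    context_class = character()
  )
}

#' Detect SmartPhrase question/answer blocks in a note
#'
#' SmartPhrases are auto-expanded boilerplate blocks of the form
#' `"Is Patient Homeless? Yes/No"`. For each template the note is searched
#' (case-insensitively, on whitespace-normalised text) for the question
#' text; the nearest answer token within `max_answer_distance` characters
#' after the question is taken as the provider's answer. When no answer
#' token falls inside the window the answer is reported as absent (`NA`).
#'
#' @param note A list or one-row data frame with `note_id` and `text`.
#' @param templates A list of SmartPhrase templates (see
#'   [default_lexicon()]), each with `question_text`, `affirmative_token`,
#'   `negative_token`, `max_answer_distance`.
#' @return A tibble with one row per question occurrence: `note_id`,
#'   `question_start`, `question_end`, `answer` (token or `NA`),
#'   `answer_start`, `answer_end`, `window_end` (raw offsets, 0-based
#'   half-open).
#' @export
detect_smartphrase <- function(note, templates) {
  if (length(templates) == 0) {
    stop("no SmartPhrase templates supplied", call. = FALSE)
  }
  text <- note$text
  nt <- normalize_text(text)
  out <- list()
  for (tpl in templates) {
    q_norm <- gsub("\\s+", " ", tpl$question_text, perl = TRUE)
    q_rx <- paste0("(?i)", regex_escape(q_norm))
    m <- gregexpr(q_rx, nt$text, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    q_len <- attr(m, "match.length")
    for (k in seq_along(m)) {
      q_start0 <- as.integer(m[k]) - 1L
      q_end0 <- q_start0 + q_len[k]
      win_end0 <- min(q_end0 + tpl$max_answer_distance, nchar(nt$text))
      window <- substring(nt$text, q_end0 + 1L, win_end0)
      ans <- find_answer_token(
        window, c(tpl$affirmative_token, tpl$negative_token)
      )
      q_raw <- norm_span_to_raw(nt$map, q_start0, q_end0)
      win_raw_end <- if (win_end0 > 0) nt$map[win_end0] else q_raw$end
      if (is.null(ans)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          note_id = note$note_id,
          question_start = q_raw$start, question_end = q_raw$end,
          answer = NA_character_,
          answer_start = NA_integer_, answer_end = NA_integer_,
          window_end = win_raw_end
        )
      } else {
        a_raw <- norm_span_to_raw(
          nt$map, q_end0 + ans$start, q_end0 + ans$end
        )
        out[[length(out) + 1L]] <- tibble::tibble(
          note_id = note$note_id,
          question_start = q_raw$start, question_end = q_raw$end,
          answer = ans$token,
          answer_start = a_raw$start, answer_end = a_raw$end,
          window_end = win_raw_end
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      note_id = character(), question_start = integer(),
      question_end = integer(), answer = character(),
      answer_start = integer(), answer_end = integer(),
      window_end = integer()
    ))
  }
  dplyr::bind_rows(out)
}

# Nearest word-boundary occurrence of any answer token inside `window`
# (a normalised-text excerpt). Returns NULL or list(token, start, end)
# with offsets relative to the window start (0-based half-open).
find_answer_token <- function(window, tokens) {
  best <- NULL
  for (tok in tokens) {
    rx <- paste0("(?i)(?<![[:alnum:]])", regex_escape(tok),
                 "(?![[:alnum:]])")
    m <- regexpr(rx, window, perl = TRUE)
    if (m[1] == -1L) next
    cand <- list(
      token = tok,
      start = as.integer(m) - 1L,
      end = as.integer(m) - 1L + attr(m, "match.length")
    )
    if (is.null(best) || cand$start < best$start) best <- cand
  }
  best
}

# Sentence index for each character of a normalised text. A sentence ends
# at '.', '?' or '!' followed by a space (newlines have already been
# collapsed to spaces during normalisation).
sentence_index <- function(norm_text) {
  n <- nchar(norm_text)
  if (n == 0) {
    return(integer())
  }
  m <- gregexpr("[.?!]+ ", norm_text, perl = TRUE)[[1]]
  starts <- 1L
  if (m[1] != -1L) {
    ends <- as.integer(m) + attr(m, "match.length") - 1L
    starts <- c(1L, ends[ends < n] + 1L)
  }
  findInterval(seq_len(n), starts)
}

#' Classify the context of a phrase mention
#'
#' Assigns each located phrase occurrence one of five context classes,
#' checked in strict precedence order:
#'
#' 1. the span lies inside a SmartPhrase question or its answer window:
#'    `smartphrase_affirmative` when the detected answer is the affirmative
#'    token, otherwise `smartphrase_negative` (a negative answer or no
#'    answer at all);
#' 2. a negation cue ends within the 40 characters preceding the span, in
#'    the same normalised sentence: `negated`;
#' 3. an other-referent cue (a family member or other third party) occurs
#'    anywhere in the same sentence: `other_referent`;
#' 4. otherwise `affirmative`.
#'
#' @param span A list or one-row data frame with `start` and `end`
#'   (raw-text offsets, 0-based half-open).
#' @param note A list or one-row data frame with `text`.
#' @param lexicon A single `sbdh_domain_lexicon` supplying
#'   `negation_cues` and `other_referent_cues`.
#' @param smartphrase_hits Output of [detect_smartphrase()] for this note
#'   (may have zero rows).
#' @param negation_window Characters before the span within which a
#'   negation cue triggers (default 40).
#' @return A single context-class string.
#' @export
classify_context <- function(span, note, lexicon, smartphrase_hits = NULL,
                             negation_window = 40L) {
  text <- note$text
  if (span$start < 0 || span$end > nchar(text) || span$start >= span$end) {
    stop("mention span outside note bounds", call. = FALSE)
  }
  if (!is.null(smartphrase_hits) && nrow(smartphrase_hits) > 0) {
    for (k in seq_len(nrow(smartphrase_hits))) {
      h <- smartphrase_hits[k, ]
      upper <- max(h$window_end, h$answer_end, na.rm = TRUE)
      if (span$start >= h$question_start && span$end <= upper) {
        ans <- h$answer
        if (!is.na(ans) && tolower(ans) == "yes") {
          return("smartphrase_affirmative")
        }
        return("smartphrase_negative")
      }
    }
  }
  nt <- normalize_text(text)
  r2n <- raw_to_norm_map(nt$map, nchar(text))
  n_start0 <- r2n[span$start + 1L] - 1L
  n_end0 <- r2n[span$end]
  sent <- sentence_index(nt$text)
  span_sent <- sent[n_start0 + 1L]

  cue_spans <- function(cues) {
    out <- list()
    for (cue in cues) {
      cue_n <- gsub("\\s+", " ", cue, perl = TRUE)
      rx <- paste0("(?i)(?<![[:alnum:]])", regex_escape(cue_n),
                   "(?![[:alnum:]])")
      m <- gregexpr(rx, nt$text, perl = TRUE)[[1]]
      if (m[1] == -1L) next
      out[[length(out) + 1L]] <- data.frame(
        start = as.integer(m) - 1L,
        end = as.integer(m) - 1L + attr(m, "match.length")
      )
    }
    do.call(rbind, out)
  }

  neg <- cue_spans(lexicon$negation_cues)
  if (!is.null(neg)) {
    same_sent <- sent[neg$start + 1L] == span_sent
    in_window <- neg$end <= n_start0 &
      (n_start0 - neg$end) <= negation_window
    if (any(same_sent & in_window)) {
      return("negated")
    }
  }
  ref <- cue_spans(lexicon$other_referent_cues)
  if (!is.null(ref)) {
    if (any(sent[ref$start + 1L] == span_sent)) {
      return("other_referent")
    }
  }
  "affirmative"
}
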