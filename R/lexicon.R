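#' SBDH domain identifiers
#'
#' The three text-mined domains (`social_connection`, `housing`,
#' `financial_strain`) are screened in both coded diagnoses and free text;
#' the remaining identifiers name structured-only fields whose completeness
#' is assessed but which carry no phrase lexicon.
#'
#' @return Named list with elements `text_mined` and `structured_only`.
#' @export
sbdh_domains <- function() {
  list(
    text_mined = c("social_connection", "housing", "financial_strain"),
    structured_only = c(
      "address", "ethnicity", "race", "preferred_language",
      "alcohol_use", "smoking_status"
    )
  )
}

code_systems <- c("ICD-10-CM", "ICD-9-CM")

new_domain_lexicon <- function(domain, codes, patterns, negation_cues,
                               other_referent_cues, smartphrase_templates) {
  structure(
    list(
      domain = domain,
      codes = codes,
      patterns = patterns,
      negation_cues = negation_cues,
      other_referent_cues = other_referent_cues,
      smartphrase_templates = smartphrase_templates
    ),
    class = "sbdh_domain_lexicon"
  )
}

code_tbl <- function(codes, labels, subdomains, counts, shared = FALSE) {
  tibble::tibble(
    system = "ICD-10-CM",
    code = codes,
    label = labels,
    subdomain = subdomains,
    shared_code = shared,
    reference_count = as.integer(counts)
  )
}

pattern_tbl <- function(domain, phrases) {
  tibble::tibble(
    pattern_id = paste0(domain, "_", sprintf("%02d", seq_along(phrases))),
    phrase = phrases,
    match_mode = "word_boundary_literal",
    case_sensitive = FALSE
  )
}

smartphrase_template <- function(question_text, affirmative_token = "Yes",
                                 negative_token = "No",
                                 max_answer_distance = 15L) {
  list(
    question_text = question_text,
    affirmative_token = affirmative_token,
    negative_token = negative_token,
    max_answer_distance = max_answer_distance
  )
}

# Negation cues shared across domains; NegEx-style pre-span triggers.
default_negation_cues <- c(
  "denies", "denied", "denying", "no evidence of", "no history of",
  "not", "without", "negative for", "ruled out"
)

# Cues indicating the phrase describes someone other than the patient.
default_other_referent_cues <- c(
  "mother", "father", "brother", "sister", "son", "daughter", "husband",
  "wife", "friend", "neighbor", "cousin", "roommate", "coworker"
)

#' Default SBDH lexicon set
#'
#' Builds the packaged lexicons for the three text-mined SBDH domains. Each
#' lexicon carries the domain's ICD-10 diagnosis code inventory (with the
#' reference patient count per subtype code, used by the synthetic-data
#' generator to weight subtype assignment), a seed list of literal phrase
#' patterns, negation and other-referent cue vocabularies, and the
#' SmartPhrase question/answer template for the domain.
#'
#' The code Z59.8 is legitimately catalogued under both housing ("other
#' housing problems") and financial strain ("other economic circumstances
#' problems"); the housing entry is primary and the financial entry is
#' flagged `shared_code = TRUE` so cohort queries can treat it per-domain.
#'
#' The phrase lists are a documented seed vocabulary drawn from the domain
#' definitions and ICD label text; the lexicon is serialisable
#' ([save_lexicon()]) precisely so sites can replace or extend it.
#'
#' @return An object of class `sbdh_lexicon_set`: a named list of
#'   `sbdh_domain_lexicon` objects.
#' @examples
#' lex <- default_lexicon()
#' lex$housing$codes
#' @export
default_lexicon <- function() {
  social <- new_domain_lexicon(
    domain = "social_connection",
    codes = code_tbl(
      codes = c(
        "Z60.2", "Z60.4", "Z63.0", "Z63.5", "Z63.8",
        "Z63.9", "Z65.9", "Z73.4", "Z91.89", "R45.8"
      ),
      labels = c(
        "problems related to living alone",
        "social exclusion and rejection",
        "relationship problems (with spouse/partner)",
        "family disruption (separation/divorce)",
        "other primary support group problems",
        "unspecified primary support group problem",
        "unspecified psychosocial circumstances",
        "inadequate social skills",
        "other specified personal risk factors",
        "other emotional state symptoms and signs"
      ),
      subdomains = c(
        "living_alone", "social_exclusion", "relationship_problems",
        "family_disruption", "support_group_problems",
        "support_group_problems", "psychosocial_circumstances",
        "social_skills", "personal_risk_factors", "emotional_state"
      ),
      counts = c(1222, 223, 852, 548, 2230, 3247, 938, 81, 18947, 3340)
    ),
    patterns = pattern_tbl("social", c(
      "social isolation", "socially isolated", "lives alone",
      "no social support", "lack of social support", "estranged",
      "no family support"
    )),
    negation_cues = default_negation_cues,
    other_referent_cues = default_other_referent_cues,
    smartphrase_templates = list(
      smartphrase_template("Is Patient Socially Isolated?")
    )
  )

  housing <- new_domain_lexicon(
    domain = "housing",
    codes = code_tbl(
      codes = c("Z59.0", "Z59.1", "Z59.8"),
      labels = c(
        "homelessness", "inadequate housing", "other housing problems"
      ),
      subdomains = c("homelessness", "inadequate_housing",
                     "housing_characteristics"),
      counts = c(7022, 120, 3291),
      shared = c(FALSE, FALSE, TRUE)
    ),
    patterns = pattern_tbl("housing", c(
      "homeless", "homelessness", "housing instability",
      "housing insecurity", "eviction", "shelter", "inadequate housing"
    )),
    negation_cues = default_negation_cues,
    other_referent_cues = default_other_referent_cues,
    smartphrase_templates = list(
      smartphrase_template("Is Patient Homeless?")
    )
  )

  financial <- new_domain_lexicon(
    domain = "financial_strain",
    codes = code_tbl(
      codes = c("Z59.5", "Z59.6", "Z59.7", "Z59.8"),
      labels = c(
        "extreme poverty", "low income",
        "insufficient social insurance and welfare",
        "other economic circumstances problems"
      ),
      subdomains = c("extreme_poverty", "low_income",
                     "insufficient_welfare", "economic_circumstances"),
      counts = c(68, 72, 46, 3357),
      shared = c(FALSE, FALSE, FALSE, TRUE)
    ),
    patterns = pattern_tbl("financial", c(
      "financial strain", "financial hardship", "cannot afford",
      "unable to afford", "poverty", "low income", "food stamps"
    )),
    negation_cues = default_negation_cues,
    other_referent_cues = default_other_referent_cues,
    smartphrase_templates = list(
      smartphrase_template("Does Patient Have Financial Hardship?")
    )
  )

  set <- structure(
    list(
      social_connection = social,
      housing = housing,
      financial_strain = financial
    ),
    class = "sbdh_lexicon_set"
  )
  validate_lexicon(set)
  set
}

icd10_code_rx <- "^[A-Z][0-9][0-9A-Z](\\.[0-9A-Z]{1,4})?$"
icd9_code_rx <- "^[VE]?[0-9]{2,3}(\\.[0-9]{1,2})?$"

#' Validate an SBDH lexicon set
#'
#' Enforces the structural invariants every lexicon must satisfy before it
#' can drive screening: known domain identifiers, recognised code systems,
#' syntactically valid codes, `(system, code)` unique within each domain,
#' globally unique pattern identifiers, non-empty trimmed phrases, at least
#' one phrase per text-mined domain, and distinct SmartPhrase answer
#' tokens.
#'
#' @param set An `sbdh_lexicon_set`.
#' @return `set`, invisibly, if valid; otherwise an error naming the
#'   offending entry.
#' @export
validate_lexicon <- function(set) {
  if (!inherits(set, "sbdh_lexicon_set")) {
    stop("not an sbdh_lexicon_set", call. = FALSE)
  }
  known <- sbdh_domains()$text_mined
  if (!all(names(set) %in% known)) {
    bad <- setdiff(names(set), known)
    stop("unknown domain(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  all_ids <- character()
  for (lex in set) {
    codes <- lex$codes
    if (nrow(codes)) {
      bad_sys <- setdiff(unique(codes$system), code_systems)
      if (length(bad_sys)) {
        stop("unknown code system: ", paste(bad_sys, collapse = ", "),
             call. = FALSE)
      }
      ok10 <- codes$system != "ICD-10-CM" | grepl(icd10_code_rx, codes$code)
      ok9 <- codes$system != "ICD-9-CM" | grepl(icd9_code_rx, codes$code)
      if (!all(ok10 & ok9)) {
        stop("malformed code(s) in domain ", lex$domain, ": ",
             paste(codes$code[!(ok10 & ok9)], collapse = ", "),
             call. = FALSE)
      }
      key <- paste(codes$system, codes$code)
      if (anyDuplicated(key)) {
        stop("duplicate (system, code) in domain ", lex$domain, ": ",
             paste(unique(key[duplicated(key)]), collapse = ", "),
             call. = FALSE)
      }
    }
    pats <- lex$patterns
    if (any(!nzchar(pats$phrase)) || any(pats$phrase != trimws(pats$phrase))) {
      stop("empty or untrimmed phrase in domain ", lex$domain, call. = FALSE)
    }
    if (!all(pats$match_mode == "word_boundary_literal")) {
      stop("unsupported match_mode in domain ", lex$domain, call. = FALSE)
    }
    all_ids <- c(all_ids, pats$pattern_id)
    for (tpl in lex$smartphrase_templates) {
      if (!nzchar(tpl$question_text)) {
        stop("empty SmartPhrase question in domain ", lex$domain,
             call. = FALSE)
      }
      if (identical(tpl$affirmative_token, tpl$negative_token)) {
        stop("SmartPhrase answer tokens must be distinct in domain ",
             lex$domain, call. = FALSE)
      }
    }
  }
  if (anyDuplicated(all_ids)) {
    stop("duplicate pattern_id: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "),
         call. = FALSE)
  }
  invisible(set)
}

#' Save / load a lexicon set as YAML
#'
#' The on-disk format has one top-level key per domain mirroring the
#' `sbdh_domain_lexicon` fields, with ICD codes stored under explicit
#' system tags. Loading validates the file with [validate_lexicon()], so a
#' save-then-load round trip is the identity on valid lexicons.
#'
#' @param set An `sbdh_lexicon_set`.
#' @param path File path.
#' @return `load_lexicon()` returns an `sbdh_lexicon_set`; `save_lexicon()`
#'   returns `path` invisibly.
#' @export
save_lexicon <- function(set, path) {
  validate_lexicon(set)
  out <- lapply(set, function(lex) {
    list(
      domain = lex$domain,
      codes = lapply(seq_len(nrow(lex$codes)), function(i) {
        as.list(lex$codes[i, ])
      }),
      patterns = lapply(seq_len(nrow(lex$patterns)), function(i) {
        as.list(lex$patterns[i, ])
      }),
      negation_cues = as.list(lex$negation_cues),
      other_referent_cues = as.list(lex$other_referent_cues),
      smartphrase_templates = lex$smartphrase_templates
    )
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname save_lexicon
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) {
    stop("lexicon file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  set <- structure(
    lapply(raw, function(lex) {
      codes <- dplyr::bind_rows(lapply(lex$codes, tibble::as_tibble))
      patterns <- dplyr::bind_rows(lapply(lex$patterns, tibble::as_tibble))
      new_domain_lexicon(
        domain = lex$domain,
        codes = codes,
        patterns = patterns,
        negation_cues = unlist(lex$negation_cues) %||% character(),
        other_referent_cues = unlist(lex$other_referent_cues) %||% character(),
        smartphrase_templates = lex$smartphrase_templates
      )
    }),
    class = "sbdh_lexicon_set"
  )
  names(set) <- vapply(set, function(x) x$domain, character(1))
  validate_lexicon(set)
  set
}

#' Compile a lexicon set into a phrase matcher
#'
#' Each phrase is compiled to a literal word-boundary pattern: a match may
#' not begin or end inside a longer alphanumeric run, so `homeless` does not
#' match inside `homelessness`. Matching is case-insensitive unless a
#' pattern sets `case_sensitive = TRUE`, and multi-word phrases match across
#' single spaces (note text is whitespace-normalised before matching).
#'
#' @param set An `sbdh_lexicon_set`.
#' @return An object of class `sbdh_matcher`.
#' @export
compile_matcher <- function(set) {
  validate_lexicon(set)
  rows <- lapply(set, function(lex) {
    if (nrow(lex$patterns) == 0) {
      return(NULL)
    }
    tibble::tibble(
      domain = lex$domain,
      pattern_id = lex$patterns$pattern_id,
      phrase = gsub("\\s+", " ", lex$patterns$phrase, perl = TRUE),
      case_sensitive = lex$patterns$case_sensitive
    )
  })
  tab <- dplyr::bind_rows(rows)
  if (nrow(tab) == 0) {
    tab <- tibble::tibble(
      domain = character(), pattern_id = character(), phrase = character(),
      case_sensitive = logical()
    )
  }
  tab$regex <- paste0(
    ifelse(tab$case_sensitive, "", "(?i)"),
    "(?<![[:alnum:]])", regex_escape(tab$phrase), "(?![[:alnum:]])"
  )
  structure(list(patterns = tab), class = "sbdh_matcher")
}

# Scan already-normalised texts with a compiled matcher. Returns one row
# per occurrence with 0-based half-open offsets into the normalised text.
matcher_scan <- function(matcher, norm_texts) {
  tab <- matcher$patterns
  out <- list()
  for (i in seq_len(nrow(tab))) {
    hits <- gregexpr(tab$regex[i], norm_texts, perl = TRUE)
    for (j in seq_along(hits)) {
      m <- hits[[j]]
      if (m[1] == -1L) next
      len <- attr(m, "match.length")
      out[[length(out) + 1L]] <- tibble::tibble(
        text_index = j,
        domain = tab$domain[i],
        pattern_id = tab$pattern_id[i],
        start = as.integer(m) - 1L,
        end = as.integer(m) - 1L + len
      )
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(
      text_index = integer(), domain = character(), pattern_id = character(),
      start = integer(), end = integer()
    ))
  }
  res[order(res$text_index, res$start, res$pattern_id), ]
}
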