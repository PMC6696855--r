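# Independent brute-force oracle for phrase matching: lowercases the
# whitespace-normalised text and tests every phrase at every character
# position, with explicit word-boundary checks. Deliberately naive and
# kept free of the package's matcher machinery.
oracle_scan <- function(phrases, text) {
  norm <- gsub("\\s+", " ", text, perl = TRUE)
  low <- tolower(norm)
  n <- nchar(low)
  chars <- strsplit(low, "", fixed = TRUE)[[1]]
  alnum <- grepl("[[:alnum:]]", chars)
  out <- list()
  for (ph in unique(tolower(gsub("\\s+", " ", phrases, perl = TRUE)))) {
    len <- nchar(ph)
    if (len == 0 || len > n) next
    for (s in seq_len(n - len + 1)) {
      if (substr(low, s, s + len - 1) != ph) next
      before_ok <- s == 1 || !alnum[s - 1]
      after_ok <- (s + len - 1) == n || !alnum[s + len]
      if (before_ok && after_ok) {
        out[[length(out) + 1L]] <- data.frame(
          phrase = ph, start = s - 1L, end = s - 1L + len
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(phrase = character(), start = integer(),
                      end = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end, res$phrase), ]
}

# Random note text mixing target words, near-miss superstrings, varied
# case, punctuation and messy whitespace.
random_note_text <- function(n_tokens = 20) {
  words <- c(
    "homeless", "Homeless", "HOMELESS", "homelessness", "shelter",
    "sheltered", "eviction", "evictions", "poverty", "antipoverty",
    "housing", "instability", "housing instability", "the", "patient",
    "is", "was", "not", "reports", "denies", "lives alone", "alone",
    "income", "low income", "lowincome"
  )
  seps <- c(" ", "  ", "\n", " \t ", ". ", ", ", "? ")
  tokens <- sample(words, n_tokens, replace = TRUE)
  joins <- sample(seps, n_tokens - 1, replace = TRUE,
                  prob = c(0.5, 0.1, 0.1, 0.05, 0.1, 0.1, 0.05))
  paste0(paste0(tokens[-n_tokens], joins, collapse = ""), tokens[n_tokens])
}

# Minimal single-domain lexicon built around the housing phrase list,
# for tests that need full control of the pattern inventory.
toy_lexicon <- function(phrases = c("homeless", "housing instability"),
                        domain = "housing") {
  lex <- default_lexicon()
  keep <- lex[domain]
  class(keep) <- "sbdh_lexicon_set"
  keep[[domain]]$patterns <- tibble::tibble(
    pattern_id = paste0("toy_", seq_along(phrases)),
    phrase = phrases,
    match_mode = "word_boundary_literal",
    case_sensitive = FALSE
  )
  keep
}
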