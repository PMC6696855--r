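test_that("default lexicon carries the expected domain code inventories", {
  lex <- default_lexicon()
  expect_setequal(names(lex), c("social_connection", "housing",
                                "financial_strain"))

  housing <- lex$housing$codes
  expect_setequal(housing$code, c("Z59.0", "Z59.1", "Z59.8"))
  expect_equal(housing$subdomain[housing$code == "Z59.0"], "homelessness")

  social <- lex$social_connection$codes
  expect_true("Z60.2" %in% social$code)
  expect_length(social$code, 10)

  financial <- lex$financial_strain$codes
  expect_setequal(financial$code, c("Z59.5", "Z59.6", "Z59.7", "Z59.8"))

  # Z59.8 is the only code catalogued in two domains; both entries are
  # flagged as shared so cohort queries can attribute it per-domain
  all_codes <- dplyr::bind_rows(lapply(lex, function(l) l$codes))
  dup <- all_codes$code[duplicated(all_codes$code)]
  expect_equal(dup, "Z59.8")
  expect_true(financial$shared_code[financial$code == "Z59.8"])
  expect_true(housing$shared_code[housing$code == "Z59.8"])
  expect_true(all(!all_codes$shared_code[all_codes$code != "Z59.8"]))
})

test_that("default lexicon satisfies structural invariants", {
  lex <- default_lexicon()
  ids <- unlist(lapply(lex, function(l) l$patterns$pattern_id))
  expect_equal(anyDuplicated(ids), 0L)
  for (l in lex) {
    expect_gt(nrow(l$patterns), 0)
    expect_true(all(nzchar(l$patterns$phrase)))
    expect_true(all(l$patterns$phrase == trimws(l$patterns$phrase)))
  }
})

test_that("lexicon YAML serialization round-trips to an equal set", {
  lex <- default_lexicon()
  path <- withr::local_tempfile(fileext = ".yaml")
  save_lexicon(lex, path)
  expect_equal(load_lexicon(path), lex)
})

test_that("lexicon validation rejects malformed files with named errors", {
  lex <- default_lexicon()
  path <- withr::local_tempfile(fileext = ".yaml")

  bad <- lex
  bad$housing$patterns$pattern_id[2] <- bad$housing$patterns$pattern_id[1]
  expect_error(save_lexicon(bad, path),
               regexp = bad$housing$patterns$pattern_id[1], fixed = TRUE)

  bad <- lex
  bad$housing$codes$system[1] <- "ICD-11"
  expect_error(save_lexicon(bad, path), "ICD-11")

  bad <- lex
  bad$housing$patterns$phrase[1] <- ""
  expect_error(save_lexicon(bad, path), "phrase")

  # the same failures must be caught on load of a hand-edited file
  save_lexicon(lex, path)
  y <- yaml::read_yaml(path)
  y[[2]]$patterns[[2]]$pattern_id <- y[[2]]$patterns[[1]]$pattern_id
  yaml::write_yaml(y, path)
  expect_error(load_lexicon(path), "duplicate pattern_id")
})

test_that("compiled matcher enforces word boundaries and case folding", {
  m <- compile_matcher(toy_lexicon("homeless"))

  scan <- function(text) {
    match_mentions(list(note_id = "n", text = text), m)
  }
  # no match inside a longer alphanumeric token
  expect_equal(nrow(scan("chronic homelessness documented")), 0)
  # boundary at punctuation and text edges
  hit <- scan("Patient is homeless.")
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start, 11L)
  expect_equal(hit$end, 19L)
  expect_equal(hit$matched_text, "homeless")
  # case-insensitive by default
  for (v in c("HOMELESS", "Homeless", "homeless")) {
    expect_equal(scan(v)$matched_text, v)
  }
})

test_that("matcher with no patterns reports no spans on any text", {
  lex <- toy_lexicon(character(0))
  m <- compile_matcher(lex)
  expect_equal(nrow(match_mentions(
    list(note_id = "n", text = "Patient is homeless."), m
  )), 0)
})

test_that("compiled matcher agrees with the brute-force scan oracle", {
  set.seed(2024)
  phrases <- c("homeless", "homelessness", "housing instability",
               "lives alone", "low income")
  m <- compile_matcher(toy_lexicon(phrases))
  pattern_phrase <- setNames(m$patterns$phrase, m$patterns$pattern_id)
  for (i in 1:200) {
    text <- random_note_text(sample(5:30, 1))
    norm <- gsub("\\s+", " ", text, perl = TRUE)
    got <- sbdhscreen:::matcher_scan(m, norm)
    got_key <- sort(paste(tolower(pattern_phrase[got$pattern_id]),
                          got$start, got$end))
    want <- oracle_scan(phrases, text)
    want_key <- sort(paste(want$phrase, want$start, want$end))
    expect_equal(got_key, want_key, info = paste("corpus note", i))
  }
})
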