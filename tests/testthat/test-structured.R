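test_that("percent applies half-up rounding at two decimals", {
  expect_equal(percent(35646, 1188202), 3.00)
  expect_equal(percent(30893, 1188202), 2.60)
  expect_equal(percent(490348, 5401324), 9.08)
  expect_equal(percent(1, 3), 33.33)
  expect_equal(percent(0, 7), 0.00)
  expect_equal(percent(1, 8, decimals = 1), 12.5)
  # half-up, not half-to-even
  expect_equal(percent(125, 1000, decimals = 1), 12.5)
  expect_equal(percent(1005, 100000), 1.01)
  expect_error(percent(1, 0), "denominator")
  expect_error(percent(-1, 10), "numerator")
})

toy_patients <- function() {
  tibble::tibble(
    patient_id = sprintf("p%02d", 1:10),
    address = c(rep("1 Main St", 6), NA, NA, "", "  "),
    zip = c(rep("21201", 6), "21202", NA, NA, NA),
    race = c(rep("White", 9), NA),
    ethnicity = c(rep("Hispanic", 5), rep(NA, 5)),
    preferred_language = c(rep("English", 3), "Unknown", rep(NA, 6))
  )
}

test_that("completeness counts unique patients with any non-missing value", {
  p <- toy_patients()
  expect_equal(completeness_rate(p, "race")$rate, 90.00)
  # "Unknown" is a recorded value, not a missing one
  lang <- completeness_rate(p, "preferred_language")
  expect_equal(lang$numerator, 4L)
  expect_equal(lang$rate, 40.00)
  # composite: address OR zip present
  addr <- completeness_rate(p, "address_or_zip")
  expect_equal(addr$numerator, 7L)
  # empty and whitespace-only strings are missing
  expect_equal(completeness_rate(p, "address")$numerator, 6L)
  expect_error(completeness_rate(p, "no_such_field"), "unknown field")
  expect_warning(
    out <- completeness_rate(p[0, ], "race", denominator = 0),
    "denominator"
  )
  expect_true(is.na(out$rate))
})

test_that("completeness is invariant to row order and duplicated rows", {
  p <- toy_patients()
  shuffled <- p[sample(nrow(p)), ]
  duplicated <- rbind(p, p[c(1, 1, 3), ])
  denom <- 10
  for (f in c("race", "preferred_language", "address_or_zip")) {
    base <- completeness_rate(p, f, denom)
    expect_equal(completeness_rate(shuffled, f, denom), base)
    expect_equal(completeness_rate(duplicated, f, denom), base)
  }
})

test_that("diagnosis cohorts deduplicate patients and honor the window", {
  dx <- tibble::tibble(
    patient_id = c("a", "a", "b", "c", "d"),
    encounter_id = paste0("e", 1:5),
    system = c("ICD-10-CM", "ICD-10-CM", "ICD-10-CM", "ICD-9-CM",
               "ICD-10-CM"),
    code = c("Z59.0", "Z59.0", "Z59.0", "V60.0", "Z59.0"),
    date = as.Date(c("2010-01-01", "2012-05-05", "2015-03-03",
                     "2016-02-02", "2002-01-01")),
    source = c("problem_list", "billing", "encounter", "billing",
               "problem_list")
  )
  window <- as.Date(c("2003-01-01", "2018-06-26"))
  # patient "a" has two qualifying encounters but counts once;
  # "d" falls outside the window; "c" enters via the ICD-9 crosswalk
  got <- diagnosis_cohort(dx, "Z59.0", window = window)
  expect_setequal(got, c("a", "b", "c"))
  expect_setequal(
    diagnosis_cohort(dx, "Z59.0", window = window, include_icd9 = FALSE),
    c("a", "b")
  )
  expect_error(diagnosis_cohort(dx, character(0)), "empty code list")
})

test_that("shared Z59.8 records are attributed per-domain via provenance", {
  lex <- default_lexicon()
  dx <- tibble::tibble(
    patient_id = c("h1", "f1"),
    encounter_id = c("e1", "e2"),
    system = "ICD-10-CM",
    code = "Z59.8",
    date = as.Date("2015-01-01"),
    source = "billing",
    domain = c("housing", "financial_strain")
  )
  housing <- diagnosis_cohort(dx, lex$housing$codes,
                              domain = "housing")
  financial <- diagnosis_cohort(dx, lex$financial_strain$codes,
                                domain = "financial_strain")
  expect_equal(housing, "h1")
  expect_equal(financial, "f1")
  # without provenance the query degrades to code-only matching
  expect_setequal(
    diagnosis_cohort(dx[, -7], lex$financial_strain$codes,
                     domain = "financial_strain"),
    c("h1", "f1")
  )
})

test_that("domain summary reports subtype counts and the union total", {
  cohorts <- list(
    "Z59.0" = sprintf("p%05d", 1:7022),
    "Z59.1" = sprintf("q%05d", 1:120),
    "Z59.8" = sprintf("r%05d", 1:3291)
  )
  s <- domain_summary(cohorts, domain = "housing", denominator = 5401324)
  expect_equal(s$domain_total, 10433L)
  expect_equal(s$pct, 0.19)
  expect_equal(sum(s$subtypes$n), s$domain_total)

  # overlapping subtype cohorts: union semantics
  overlap <- list(a = c("x", "y"), b = c("y", "z"))
  expect_equal(domain_summary(overlap)$domain_total, 3L)
  expect_error(domain_summary(list()), "no subtype cohorts")
})

test_that("domain total equals the brute-force union size on random input", {
  set.seed(11)
  for (i in 1:20) {
    k <- sample(1:5, 1)
    cohorts <- lapply(seq_len(k), function(j) {
      sample(sprintf("p%03d", 1:50), sample(0:30, 1))
    })
    names(cohorts) <- paste0("c", seq_len(k))
    expect_equal(
      domain_summary(cohorts)$domain_total,
      length(Reduce(union, cohorts))
    )
  }
})

test_that("questionnaire completion rates match the reference arithmetic", {
  reg <- questionnaire_registry()
  out <- questionnaire_completion(reg)
  nursing <- out[out$template == "Nursing assessment", ]
  expect_equal(nursing$rate, 92.00)
  expect_equal(out$rate[out$template == "ED nursing 1"], 94.00)
  expect_equal(out$rate[out$template == "ED triage abuse indicators"], 5.50)

  toy <- tibble::tibble(template = c("t1", "t2"),
                        administered = c(10L, 10L),
                        completed = c(0L, 10L))
  expect_equal(questionnaire_completion(toy)$rate, c(0, 100))
  expect_error(
    questionnaire_completion(
      tibble::tibble(template = "t", administered = 10L, completed = 11L)
    ),
    "exceeds administered"
  )
  expect_warning(
    und <- questionnaire_completion(
      tibble::tibble(template = "t", administered = 0L, completed = 0L)
    ),
    "undefined"
  )
  expect_true(is.na(und$rate))
})
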