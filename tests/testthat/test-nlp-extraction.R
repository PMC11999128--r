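lex <- default_lexicon()

test_that("preprocessing applies the stated normalisation rules", {
  expect_equal(preprocess("", lex), character(0))
  expect_equal(preprocess(NA_character_, lex), character(0))
  expect_equal(preprocess("Visit http://x.co ENALAPRIL 20mg!!", lex), "enalapril")
  toks <- preprocess("67 YEAR OLD PATIENT WITH HBP", lex)
  expect_true("hbp" %in% toks)
  expect_false(any(grepl("67", toks)))
  # accents fold to ASCII
  expect_equal(preprocess("hipertensión arterial", lex),
               c("hipertension", "arterial"))
})

test_that("preprocessing is idempotent on its own output", {
  set.seed(3)
  gen <- generate_cohort(cohort_config(n_patients = 20, seed = 3))
  for (note in gen$records$note_text[1:20]) {
    t1 <- preprocess(note, lex)
    t2 <- preprocess(paste(t1, collapse = " "), lex)
    expect_identical(t1, t2)
  }
})

test_that("spelling correction maps unique distance-1 neighbours and no others", {
  expect_equal(correct_spelling("metformna", lex), "metformina")
  expect_equal(correct_spelling("metformina", lex), "metformina")   # identity
  expect_equal(correct_spelling("omeprazol", lex), "omeprazol")     # exact wins
  expect_equal(correct_spelling("enalaprip", lex), "enalapril")
  # tie between empagliflozin (deletion) and empagliflozina (substitution)
  expect_equal(correct_spelling("empagliflozins", lex), "empagliflozins")
  expect_equal(correct_spelling("xyzzy", lex), "xyzzy")             # no neighbour
})

test_that("greedy search reproduces the printed worked example", {
  e <- extract_record(note_81719, lex)
  expect_equal(e$drugs, drugs_81719)
  expect_equal(e$conditions, "hypertension")
  expect_equal(e$adherence, "unstated")
  e2 <- extract_record(note_10015, lex)
  expect_equal(e2$drugs, "enalapril")
  expect_equal(e2$conditions, "hypertension")
  expect_equal(e2$adherence, "non_compliant")
})

test_that("longest match wins over overlapping shorter candidates", {
  sp <- simple_search(c("insulin", "glargine"), lex)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$canonical, "insulin glargine")
  expect_equal(nrow(simple_search(c("zz", "qq"), lex)), 0)
  expect_equal(nrow(simple_search(character(0), lex)), 0)
})

test_that("greedy search equals brute-force maximal matching on random streams", {
  set.seed(101)
  for (rep in 1:60) {
    toks <- random_tokens(sample(5:50, 1), lex)
    got <- simple_search(toks, lex)
    want <- bf_simple_search(toks, lex)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(unname(cbind(got$start, got$end)), unname(want))
    }
  }
})

test_that("bag-of-words counts accumulate over canonical entities", {
  expect_true(all(bow_vector(character(0), lex) == 0))
  v <- bow_vector(c("metformina", "metformina"), lex)
  expect_equal(unname(v["metformin"]), 2)
  expect_true(sum(v) <= 2)
  v2 <- bow_vector(preprocess(note_10015, lex), lex)
  expect_true(v2["enalapril"] > 0)
  expect_true(v2["hypertension"] > 0)
  expect_true(v2["non_adherence"] > 0)
})

test_that("adherence classification follows pattern polarity and negation", {
  cls <- function(txt) {
    toks <- preprocess(txt, lex)
    classify_adherence(toks, lexicon = lex)
  }
  expect_equal(cls("control rutinario sin novedades"), "unstated")
  expect_equal(cls("buena adherencia al tratamiento"), "compliant")
  expect_equal(cls("no hay buena adherencia al tratamiento"), "unstated")
  expect_equal(cls("mala adherencia al tratamiento"), "non_compliant")
  # negative patterns take precedence over positive ones
  expect_equal(cls("buena adherencia previa pero ahora no adherencia"),
               "non_compliant")
})

test_that("structured fields win conflicts and NLP fills the gaps", {
  row <- data.frame(drugs_structured = "", patient_compliance = NA,
                    rec_nutrition = NA, rec_physical = NA, rec_alcohol = NA,
                    rec_tobacco = NA, stringsAsFactors = FALSE)
  e <- extract_record(note_81719, lex)
  m <- merge_structured(row, e)
  expect_equal(sort(strsplit(m$row$drugs, ";")[[1]]), drugs_81719)
  expect_true("drugs" %in% m$provenance)
  # extraction empty: row unchanged
  m0 <- merge_structured(data.frame(drugs_structured = "metformin"),
                         extract_record("", lex))
  expect_equal(m0$row$drugs, "metformin")
  expect_equal(nrow(m0$conflicts), 0)
  # structured says compliant, text says non-compliant: structured wins, logged
  row2 <- data.frame(drugs_structured = "", patient_compliance = TRUE)
  m2 <- merge_structured(row2, extract_record(note_10015, lex))
  expect_true(m2$row$patient_compliance)
  expect_true("patient_compliance" %in% m2$conflicts$field)
  expect_error(merge_structured(data.frame(x = 1), e), "schema")
})

test_that("empty notes give empty results with all flags down", {
  e <- extract_record("", lex)
  expect_length(e$drugs, 0)
  expect_length(e$conditions, 0)
  expect_equal(e$adherence, "unstated")
  expect_false(any(e$recommendations))
})

test_that("extraction scoring matches hand counts and handles degenerates", {
  gen <- generate_cohort(cohort_config(
    n_patients = 120, seed = 8,
    note_noise = list(misspelling_rate = 0, abbreviation_rate = 0,
                      distractor_rate = 0)))
  lab <- label_cohort(gen$records, lex)
  q <- evaluate_extraction(lab$extractions, gen$truth)
  expect_true(all(q$precision == 1))
  expect_true(all(q$recall == 1))
  # 8 of 10 found plus 2 spurious: precision = recall = 0.8
  truth <- data.frame(patient_id = 1, year = 2018,
                      drugs = paste(sprintf("d%02d", 1:10), collapse = ";"),
                      conditions = "", adherence = "unstated",
                      rec_nutrition = FALSE, rec_physical = FALSE,
                      rec_alcohol = FALSE, rec_tobacco = FALSE)
  res <- list("1:2018" = structure(list(
    drugs = c(sprintf("d%02d", 1:8), "x1", "x2"), conditions = character(0),
    adherence = "unstated",
    recommendations = c(nutrition = FALSE, physical = FALSE, alcohol = FALSE,
                        tobacco = FALSE)), class = "extraction_result"))
  q2 <- evaluate_extraction(res, truth)
  expect_equal(q2$precision[q2$category == "drug"], 0.8)
  expect_equal(q2$recall[q2$category == "drug"], 0.8)
  # empty result set vs non-empty truth: recall 0, precision flagged 0
  res0 <- list("1:2018" = structure(list(
    drugs = character(0), conditions = character(0), adherence = "unstated",
    recommendations = c(nutrition = FALSE, physical = FALSE, alcohol = FALSE,
                        tobacco = FALSE)), class = "extraction_result"))
  q3 <- evaluate_extraction(res0, truth)
  drow <- q3[q3$category == "drug", ]
  expect_equal(drow$recall, 0)
  expect_equal(drow$precision, 0)
  expect_equal(drow$precision_undefined, 1)
  expect_error(evaluate_extraction(list(), truth), "missing")
})

test_that("spelling correction restores recall under misspelling noise", {
  noisy <- cohort_config(n_patients = 80, seed = 14,
                         note_noise = list(misspelling_rate = 0.2,
                                           abbreviation_rate = 0,
                                           distractor_rate = 0))
  gen <- generate_cohort(noisy)
  with_corr <- evaluate_extraction(label_cohort(gen$records, lex)$extractions,
                                   gen$truth)
  # correction disabled
  ext0 <- lapply(seq_len(nrow(gen$records)), function(i)
    extract_record(gen$records$note_text[i], lex, correct = FALSE))
  names(ext0) <- paste(gen$records$patient_id, gen$records$year, sep = ":")
  no_corr <- evaluate_extraction(ext0, gen$truth)
  rc <- function(q) q$recall[q$category == "drug"]
  expect_gte(rc(with_corr), 0.95)
  expect_lt(rc(no_corr), rc(with_corr))
})
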