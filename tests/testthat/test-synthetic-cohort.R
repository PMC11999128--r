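test_that("the empty and degenerate-matrix cases behave as specified", {
  gen <- generate_cohort(cohort_config(n_patients = 0))
  expect_equal(nrow(gen$records), 0)
  expect_equal(nrow(gen$truth), 0)
  # all mass on the diagonal: every patient keeps its initial stage
  eye <- diag(4); dimnames(eye) <- list(stage_levels(), stage_levels())
  gen <- generate_cohort(cohort_config(n_patients = 100, seed = 2,
                                       transition_matrix_1y = eye,
                                       render_notes = FALSE))
  by_p <- split(gen$truth$stage, gen$truth$patient_id)
  expect_true(all(vapply(by_p, function(s) length(unique(s)) == 1, logical(1))))
})

test_that("invalid transition matrices are rejected at configuration", {
  m <- reference_transition_matrix(1)
  m[2, 2] <- m[2, 2] + 0.05
  expect_error(cohort_config(10, transition_matrix_1y = m), "OUT-NOT")
  m2 <- reference_transition_matrix(1); m2[4, 1] <- 0.2; m2[4, 4] <- m2[4, 4] - 0.2
  expect_error(cohort_config(10, transition_matrix_1y = m2), "structural zero")
  expect_error(cohort_config(10, initial_stage_probs = c(1, 1, 0, 0)),
               "probability")
})

test_that("identical configurations generate identical cohorts", {
  cfg <- cohort_config(n_patients = 60, seed = 77,
                       note_noise = list(misspelling_rate = 0.2,
                                         abbreviation_rate = 0.3,
                                         distractor_rate = 0.3))
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$records, g2$records)
  expect_identical(g1$truth, g2$truth)
})

test_that("complication indicators are absorbing and HbA1c respects the goal", {
  gen <- generate_cohort(cohort_config(n_patients = 600, seed = 13,
                                       render_notes = FALSE))
  tr <- gen$truth[order(gen$truth$patient_id, gen$truth$year), ]
  comp <- tr$complications != ""
  for (ix in split(seq_len(nrow(tr)), tr$patient_id))
    expect_true(all(diff(comp[ix]) >= 0))
  rec <- gen$records[order(gen$records$patient_id, gen$records$year), ]
  on <- tr$stage %in% c("ON-NOT", "ON-YES")
  expect_true(all(rec$hba1c[on] < tr$goal_threshold[on]))
  expect_true(all(rec$hba1c[!on] >= tr$goal_threshold[!on]))
})

test_that("stage paths reproduce the configured one-step distribution", {
  P <- rbind(c(0.6, 0.2, 0.15, 0.05),
             c(0.3, 0.4, 0.1, 0.2),
             c(0, 0, 0.7, 0.3),
             c(0, 0, 0.45, 0.55))
  dimnames(P) <- list(stage_levels(), stage_levels())
  set.seed(42)
  n <- 10000
  firsts <- draws <- character(n)
  for (i in seq_len(n)) draws[i] <- sample_stage_path("ON-NOT", P, 1)[2]
  emp <- as.numeric(table(factor(draws, stage_levels()))) / n
  se <- sqrt(P["ON-NOT", ] * (1 - P["ON-NOT", ]) / n)
  expect_true(all(abs(emp - P["ON-NOT", ]) < 4 * se + 1e-12))
  # absorbing start: every state stays in a complication stage
  set.seed(1)
  p <- sample_stage_path("ON-YES", P, 10)
  expect_true(all(p %in% c("ON-YES", "OUT-YES")))
  # matrix concentrated on one column pins the path
  Q <- matrix(0, 4, 4, dimnames = dimnames(P)); Q[, 4] <- 1
  Q <- Q / rowSums(Q)
  expect_equal(sample_stage_path("OUT-NOT", Q, 3),
               c("OUT-NOT", "OUT-YES", "OUT-YES", "OUT-YES"))
})

test_that("notes embed every ground-truth entity and honour the noise dials", {
  lex <- default_lexicon()
  tpl <- dmtransit:::default_note_templates()
  zero <- list(misspelling_rate = 0, abbreviation_rate = 0, distractor_rate = 0)
  st <- list(age = 67, conditions = "hypertension", drugs = "enalapril",
             adherence = "non_compliant",
             recommendations = list(nutrition = FALSE, physical = FALSE,
                                    alcohol = FALSE, tobacco = FALSE))
  set.seed(5)
  note <- render_note(st, tpl, zero, lex)
  expect_match(note, "HYPERTENSION")
  expect_match(note, "ENALAPRIL")
  e <- extract_record(note, lex)
  expect_equal(e$conditions, "hypertension")
  expect_equal(e$drugs, "enalapril")
  expect_equal(e$adherence, "non_compliant")
  # abbreviation rate 1 forces the abbreviated surface of the condition
  set.seed(6)
  ab <- render_note(st, tpl, list(misspelling_rate = 0, abbreviation_rate = 1,
                                  distractor_rate = 0), lex)
  expect_match(ab, "HBP|HTA")
  # adherence phrasing appears iff stated
  st$adherence <- "unstated"
  set.seed(7)
  un <- render_note(st, tpl, zero, lex)
  expect_equal(extract_record(un, lex)$adherence, "unstated")
  # missing template section is a generation error
  expect_error(render_note(st, list(skeletons = "x"), zero, lex), "missing")
})

test_that("the realised misspelling fraction matches the configured rate", {
  lex <- default_lexicon()
  tpl <- dmtransit:::default_note_templates()
  noise <- list(misspelling_rate = 0.2, abbreviation_rate = 0, distractor_rate = 0)
  st <- list(age = 60, conditions = c("hypertension", "dyslipidemia"),
             drugs = c("metformin", "enalapril", "rosuvastatin"),
             adherence = "unstated",
             recommendations = list(nutrition = TRUE, physical = FALSE,
                                    alcohol = FALSE, tobacco = FALSE))
  set.seed(11)
  miss <- ment <- 0
  for (i in 1:1000) {
    nt <- render_note(st, tpl, noise, lex)
    miss <- miss + attr(nt, "misspelled"); ment <- ment + attr(nt, "mentions")
  }
  expect_equal(miss / ment, 0.2, tolerance = 0.03 / 0.2)
})

test_that("per-stage summaries recover configured moments and hand arithmetic", {
  # fixed 7.5 goal keeps the within-goal truncation negligible for the ON rows
  cfg <- cohort_config(n_patients = 20000, seed = 19, render_notes = FALSE,
                       goal_policy = fixed_goal_policy(7.5))
  gen <- generate_cohort(cfg)
  sm <- summarize_cohort(gen$records, gen$truth)
  expect_equal(sm$hba1c_mean[sm$stage == "ON-NOT"], 6.37, tolerance = 0.05 / 6.37)
  expect_equal(sm$hba1c_sd[sm$stage == "ON-NOT"], 0.49, tolerance = 0.1)
  # age is drawn once per patient at baseline, so its per-stage moments are
  # checked on the baseline year (later years age by +1 and mix switchers)
  base <- gen$records$year == 2018
  smb <- summarize_cohort(gen$records[base, ], gen$truth[base, ])
  expect_lt(abs(smb$age_mean[smb$stage == "OUT-NOT"] - 64.96), 0.5)
  # hand-computed means of a 5-record cohort
  rec <- data.frame(patient_id = 1:5, year = 2018,
                    age = c(60, 62, 64, 66, 68), sex = c("F", "M", "F", "F", "M"),
                    ldl = c(90, 100, 110, 95, 105), egfr = 80, creatinine = 1,
                    bmi = 28, weight = 75, height = 1.6, dbp = 75, sbp = 120,
                    hba1c = c(6, 6.5, 7, 7.5, 8),
                    patient_compliance = c(TRUE, FALSE, TRUE, FALSE, FALSE),
                    hba1c_guide = TRUE, cholesterol_guide = FALSE,
                    rec_nutrition = TRUE, rec_physical = TRUE,
                    rec_alcohol = FALSE, rec_tobacco = FALSE)
  tru <- data.frame(patient_id = 1:5, year = 2018, stage = "OUT-NOT")
  sm2 <- summarize_cohort(rec, tru)
  expect_equal(sm2$age_mean, 64)
  expect_equal(sm2$ldl_mean, 100)
  expect_equal(sm2$hba1c_mean, 7)
  expect_equal(sm2$patient_compliance_prev, 0.4)
  expect_equal(sm2$female_prev, 0.6)
  # single-record stage: SD reported as 0 with a warning
  expect_warning(sm3 <- summarize_cohort(rec[1, ], tru[1, ]), "single")
  expect_equal(sm3$hba1c_sd, 0)
})
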