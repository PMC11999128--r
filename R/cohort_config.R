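## Per-stage emission parameters. Means/SDs and prevalences are the published
## baseline characteristics of the reference HMO cohort (pooled 2018-2020),
## one column per stage in stage_levels() order.
default_biomarker_params <- function() {
  # rows: mean, sd; columns: ON-NOT, OUT-NOT, ON-YES, OUT-YES
  tab <- list(
    age        = list(mean = c(69.34, 64.96, 70.41, 65.91), sd = c(11.95, 11.97, 11.75, 12.08)),
    ldl        = list(mean = c(93.31, 96.33, 93.87, 96.56), sd = c(38.01, 40.88, 37.81, 39.73)),
    egfr       = list(mean = c(76.83, 81.04, 77.55, 82.80), sd = c(20.23, 21.26, 20.23, 21.99)),
    creatinine = list(mean = c(0.93, 0.91, 0.92, 0.90),     sd = c(0.39, 0.39, 0.38, 0.40)),
    bmi        = list(mean = c(28.84, 28.81, 28.80, 28.91), sd = c(4.79, 4.76, 4.79, 4.78)),
    weight     = list(mean = c(74.33, 75.30, 73.98, 75.20), sd = c(14.47, 14.79, 14.50, 14.57)),
    height     = list(mean = c(1.60, 1.61, 1.60, 1.61),     sd = c(0.09, 0.09, 0.09, 0.10)),
    dbp        = list(mean = c(75.29, 76.04, 75.23, 75.89), sd = c(7.64, 7.64, 7.51, 7.63)),
    sbp        = list(mean = c(122.8, 123.5, 122.7, 123.4), sd = c(11.47, 12.03, 11.38, 11.93)),
    hba1c      = list(mean = c(6.37, 8.66, 6.43, 8.53),     sd = c(0.49, 1.57, 0.46, 1.49))
  )
  lapply(tab, function(v) {
    names(v$mean) <- names(v$sd) <- stage_levels(); v
  })
}

default_label_prevalences <- function() {
  s <- stage_levels()
  prev <- list(
    female            = c(0.60, 0.55, 0.59, 0.55),
    patient_compliance = c(0.12, 0.14, 0.15, 0.17),
    cholesterol_guide = c(0.00, 0.01, 0.00, 0.01),
    hba1c_guide       = c(0.73, 0.41, 0.64, 0.48),
    rec_physical      = c(0.79, 0.81, 0.78, 0.82),
    rec_nutrition     = c(0.85, 0.89, 0.85, 0.91),
    rec_tobacco       = c(0.07, 0.07, 0.05, 0.06),
    rec_alcohol       = c(0.45, 0.48, 0.42, 0.47),
    analgesic         = c(0.16, 0.10, 0.16, 0.11),
    antacid           = c(0.16, 0.13, 0.16, 0.14),
    # adherence explicitly documented as absent: chosen rate, see vignette
    non_compliance_stated = c(0.10, 0.10, 0.10, 0.10)
  )
  lapply(prev, function(p) { names(p) <- s; p })
}

default_treatment_means <- function() {
  s <- stage_levels()
  m <- list(
    antihypertensive = c(1.11, 0.88, 1.17, 0.96),
    hypoglycemic     = c(0.82, 1.30, 0.89, 1.49),
    lipid_lowering   = c(0.01, 0.01, 0.01, 0.01)
  )
  lapply(m, function(p) { names(p) <- s; p })
}

#' Synthetic cohort configuration
#'
#' Bundles and validates every knob of the synthetic EHR generator. Defaults
#' reproduce the published reference cohort: initial 2018 stage occupancies
#' (8685 / 6858 / 4375 / 3884 patients), stage-conditional biomarker moments,
#' per-stage prevalences of compliance/adherence/recommendation flags, and the
#' published 1-year transition matrix. A 2-year matrix may be supplied (the
#' published 2-year panel is not the square of the 1-year panel); when present
#' it drives the first-to-last-year endpoints directly.
#'
#' @param n_patients Number of patients (>= 0).
#' @param years Ordered calendar years (default 2018:2020).
#' @param seed Integer RNG seed.
#' @param initial_stage_probs Length-4 probability vector over
#'   [stage_levels()]; default from the reference 2018 stage counts.
#' @param transition_matrix_1y Row-stochastic 4x4 matrix (1-year dynamics).
#' @param transition_matrix_2y Optional row-stochastic 4x4 matrix used for the
#'   2-step endpoint; `NULL` means two chained 1-year draws.
#' @param biomarker_params Per-variable list of per-stage `mean`/`sd` vectors.
#' @param label_prevalences Per-flag list of per-stage prevalences in `[0,1]`.
#' @param treatment_means Per-class mean prescribed-drug counts by stage.
#' @param goal_policy A [goal_policy()] used both to draw stage-consistent
#'   HbA1c values and later to re-stage the cohort.
#' @param note_noise List with `misspelling_rate`, `abbreviation_rate`,
#'   `distractor_rate`, all in `[0,1]`.
#' @param render_notes Emit free-text notes? Turning this off skips the note
#'   templating pass, e.g. for large transition-calibration runs.
#' @param structured_drug_missing_rate Probability that a truly prescribed
#'   drug is absent from the structured drug field (recoverable from the
#'   note), emulating incomplete structured EHR fields.
#' @param hba1c_missing_rate Probability that a patient-year HbA1c is missing
#'   (`NA`), exercising the inclusion filter.
#' @param effect_params Optional planted covariate effects: list with numeric
#'   vectors `goal` and/or `complication`, named by flag column, giving
#'   log-odds shifts of the per-step transition probabilities.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          years = c(2018L, 2019L, 2020L),
                          seed = 1L,
                          initial_stage_probs = c(8685, 6858, 4375, 3884) / 23802,
                          transition_matrix_1y = reference_transition_matrix(1),
                          transition_matrix_2y = NULL,
                          biomarker_params = default_biomarker_params(),
                          label_prevalences = default_label_prevalences(),
                          treatment_means = default_treatment_means(),
                          goal_policy = dmtransit::goal_policy(),
                          note_noise = list(misspelling_rate = 0,
                                            abbreviation_rate = 0.25,
                                            distractor_rate = 0.3),
                          render_notes = TRUE,
                          structured_drug_missing_rate = 0.3,
                          hba1c_missing_rate = 0,
                          effect_params = NULL) {
  if (n_patients < 0) stopf("n_patients must be >= 0")
  if (length(years) < 1 || is.unsorted(years, strictly = TRUE))
    stopf("years must be strictly increasing")
  if (abs(sum(initial_stage_probs) - 1) > 1e-9 || any(initial_stage_probs < 0))
    stopf("initial_stage_probs must be a probability 4-vector")
  validate_transition_matrix(transition_matrix_1y)
  if (!is.null(transition_matrix_2y)) validate_transition_matrix(transition_matrix_2y)
  for (v in names(biomarker_params)) {
    if (any(biomarker_params[[v]]$sd < 0))
      stopf("biomarker '%s' has a negative SD", v)
  }
  for (v in names(label_prevalences)) {
    p <- label_prevalences[[v]]
    if (any(p < 0 | p > 1)) stopf("prevalence '%s' outside [0,1]", v)
  }
  for (r in c("misspelling_rate", "abbreviation_rate", "distractor_rate")) {
    if (is.null(note_noise[[r]]) || note_noise[[r]] < 0 || note_noise[[r]] > 1)
      stopf("note_noise$%s must be in [0,1]", r)
  }
  structure(list(
    n_patients = as.integer(n_patients), years = as.integer(years),
    seed = as.integer(seed),
    initial_stage_probs = initial_stage_probs,
    transition_matrix_1y = transition_matrix_1y,
    transition_matrix_2y = transition_matrix_2y,
    biomarker_params = biomarker_params,
    label_prevalences = label_prevalences,
    treatment_means = treatment_means,
    goal_policy = goal_policy,
    note_noise = note_noise,
    render_notes = render_notes,
    structured_drug_missing_rate = structured_drug_missing_rate,
    hba1c_missing_rate = hba1c_missing_rate,
    effect_params = effect_params
  ), class = "cohort_config")
}
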