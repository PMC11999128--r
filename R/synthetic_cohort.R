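## Stage-path machinery -------------------------------------------------------

clamp_p <- function(p, eps = 1e-9) pmin(pmax(p, eps), 1 - eps)

## vectorised one-step draw: cur is a character vector of stages
draw_next_stage <- function(cur, P) {
  s <- stage_levels()
  nxt <- character(length(cur))
  for (st in unique(cur)) {
    ix <- which(cur == st)
    nxt[ix] <- sample(s, length(ix), replace = TRUE, prob = P[st, ])
  }
  nxt
}

## effect-adjusted one-step draw: per-patient log-odds shifts on the
## complication-onset and goal-loss sub-probabilities implied by the row
draw_next_stage_effects <- function(cur, P, xb_goal, xb_comp) {
  s <- stage_levels()
  n <- length(cur)
  nxt <- character(n)
  comp_now <- is_complication_stage(cur)
  row <- P[match(cur, s), , drop = FALSE]
  # complication branch (only meaningful for NOT starters)
  p_comp <- clamp_p(row[, 3] + row[, 4])
  p_comp <- stats::plogis(stats::qlogis(p_comp) + xb_comp)
  p_comp[comp_now] <- 1
  to_comp <- stats::runif(n) < p_comp
  # goal branch, conditional on the complication branch
  denom_yes <- row[, 3] + row[, 4]
  p_out_yes <- ifelse(denom_yes > 0, row[, 4] / denom_yes, 0.5)
  denom_not <- row[, 1] + row[, 2]
  p_out_not <- ifelse(denom_not > 0, row[, 2] / denom_not, 0.5)
  p_out <- ifelse(to_comp, p_out_yes, p_out_not)
  p_out <- stats::plogis(stats::qlogis(clamp_p(p_out)) + xb_goal)
  out <- stats::runif(n) < p_out
  nxt[to_comp & !out] <- "ON-YES"
  nxt[to_comp & out] <- "OUT-YES"
  nxt[!to_comp & !out] <- "ON-NOT"
  nxt[!to_comp & out] <- "OUT-NOT"
  nxt
}

#' Sample one stage path from the progression Markov chain
#'
#' Draws a discrete-time path of the four-stage model. The absorbing
#' complication structure is inherited from the transition matrix's structural
#' zeros, so a path can never step from a YES-complication stage back to a
#' NOT-complication stage.
#'
#' @param initial Initial stage label.
#' @param matrix Validated 4x4 transition matrix.
#' @param n_steps Number of transitions.
#' @return Character vector of `n_steps + 1` stage labels. Uses the current
#'   RNG state.
#' @export
sample_stage_path <- function(initial, matrix, n_steps) {
  validate_transition_matrix(matrix)
  stopifnot(initial %in% stage_levels(), n_steps >= 0)
  path <- character(n_steps + 1)
  path[1] <- initial
  for (k in seq_len(n_steps)) path[k + 1] <- draw_next_stage(path[k], matrix)
  path
}

## Emission helpers -----------------------------------------------------------

## distinct draws from a pool via a rotated index so no per-record sample();
## steps coprime with the pool size guarantee distinctness
rotated_pick <- function(pool, n_items, count) {
  m <- length(pool)
  cop <- which(vapply(seq_len(m - 1), function(s) {
    all(unique((s * seq_len(m - 1)) %% m) != 0)
  }, logical(1)))
  base <- sample.int(m, n_items, replace = TRUE)
  step <- cop[sample.int(length(cop), n_items, replace = TRUE)]
  cols <- lapply(seq_len(max(count, 1)), function(j) {
    out <- pool[((base + (j - 1) * step) %% length(pool)) + 1]
    out[count < j] <- ""
    out
  })
  do.call(cbind, cols)
}

## join non-empty strings row-wise with ";"
join_rows <- function(mat) {
  apply(mat, 1, function(r) paste(r[nzchar(r)], collapse = ";"))
}

complication_code_map <- function() {
  c(ckd = "N183", retinopathy = "H360", cerebrovascular = "I639")
}
complication_condition_map <- function() {
  c(ckd = "chronic kidney disease", retinopathy = "retinopathy",
    cerebrovascular = "cerebrovascular disease")
}

## Note rendering -------------------------------------------------------------

## one random single-character edit (insert/delete/substitute): edit distance 1
misspell_word <- function(w) {
  letters_pool <- letters
  op <- sample(3, 1)
  pos <- sample(nchar(w), 1)
  if (op == 1 && nchar(w) > 2) {            # delete
    paste0(substr(w, 1, pos - 1), substr(w, pos + 1, nchar(w)))
  } else if (op == 2) {                     # insert
    paste0(substr(w, 1, pos), sample(letters_pool, 1), substr(w, pos + 1, nchar(w)))
  } else {                                  # substitute
    repl <- sample(setdiff(letters_pool, substr(w, pos, pos)), 1)
    paste0(substr(w, 1, pos - 1), repl, substr(w, pos + 1, nchar(w)))
  }
}

## choose the rendered surface for a canonical entity
render_surface <- function(canonical, lexicon, noise) {
  e <- lexicon$entries
  rows <- which(e$canonical == canonical)
  if (length(rows) == 0) stopf("no lexicon surface for entity '%s'", canonical)
  abbr_rows <- rows[e$abbreviation[rows]]
  use <- if (length(abbr_rows) > 0 &&
             stats::runif(1) < noise$abbreviation_rate) {
    abbr_rows[sample.int(length(abbr_rows), 1)]
  } else rows[1]  # preferred surface: first listed
  surface <- e$surface[use]
  misspelled <- FALSE
  if (stats::runif(1) < noise$misspelling_rate) {
    words <- strsplit(surface, " ", fixed = TRUE)[[1]]
    k <- sample.int(length(words), 1)
    words[k] <- misspell_word(words[k])
    surface <- paste(words, collapse = " ")
    misspelled <- TRUE
  }
  list(text = toupper(surface), misspelled = misspelled)
}

#' Render one synthetic clinical note
#'
#' Produces a templated free-text note that embeds a surface form for every
#' ground-truth entity of the patient-year: conditions, drugs, an adherence
#' phrase iff the adherence status is stated, and one phrase per active
#' lifestyle-recommendation flag. Noise is applied per entity mention:
#' abbreviation surfaces with probability `abbreviation_rate`, a single-
#' character misspelling with probability `misspelling_rate`, and distractor
#' fragments with probability `distractor_rate`.
#'
#' @param state List with `age`, `conditions`, `drugs` (canonical names),
#'   `adherence` status, `recommendations` (named logical).
#' @param templates Template list, see [default_note_templates()].
#' @param noise List of the three noise rates.
#' @param lexicon A `lexicon`.
#' @return Character string; attribute `misspelled` carries the number of
#'   misspelled entity mentions and `mentions` the number of entity mentions.
#' @export
render_note <- function(state, templates = default_note_templates(),
                        noise = list(misspelling_rate = 0,
                                     abbreviation_rate = 0,
                                     distractor_rate = 0),
                        lexicon = default_lexicon()) {
  for (f in c("skeletons", "adherence", "recommendations"))
    if (is.null(templates[[f]])) stopf("note templates missing '%s'", f)
  n_miss <- 0L; n_ment <- 0L
  rend <- function(canon) {
    r <- render_surface(canon, lexicon, noise)
    n_ment <<- n_ment + 1L
    if (r$misspelled) n_miss <<- n_miss + 1L
    r$text
  }
  conds <- if (length(state$conditions) > 0) {
    paste(vapply(state$conditions, rend, character(1)), collapse = " AND ")
  } else sample(templates$empty_conditions, 1)
  drugs <- if (length(state$drugs) > 0) {
    doses <- paste0(sample(c(10, 20, 50, 100, 500, 850), length(state$drugs),
                           replace = TRUE), "MG X1")
    paste(paste(vapply(state$drugs, rend, character(1)), doses),
          collapse = " ")
  } else sample(templates$empty_drugs, 1)
  adh <- if (state$adherence %in% names(templates$adherence)) {
    ph <- templates$adherence[[state$adherence]]
    ph[sample.int(length(ph), 1)]
  } else ""
  recs <- character(0)
  for (f in names(templates$recommendations)) {
    if (isTRUE(state$recommendations[[f]])) {
      ph <- templates$recommendations[[f]]
      recs <- c(recs, ph[sample.int(length(ph), 1)])
    }
  }
  skel <- templates$skeletons[sample.int(length(templates$skeletons), 1)]
  note <- skel
  note <- sub("{age}", as.character(round(state$age)), note, fixed = TRUE)
  note <- sub("{conditions}", conds, note, fixed = TRUE)
  note <- sub("{drugs}", drugs, note, fixed = TRUE)
  note <- sub("{adherence}", adh, note, fixed = TRUE)
  note <- sub("{recommendations}", paste(recs, collapse = " "), note, fixed = TRUE)
  if (stats::runif(1) < noise$distractor_rate) {
    note <- paste(note, sample(templates$distractors, 1))
  }
  note <- gsub("[[:space:]]+", " ", trimws(note))
  structure(note, misspelled = n_miss, mentions = n_ment)
}

## Main generator -------------------------------------------------------------

empty_cohort <- function() {
  list(records = data.frame(patient_id = integer(0), year = integer(0)),
       truth = data.frame(patient_id = integer(0), year = integer(0)))
}

#' Generate a synthetic EHR cohort with ground truth
#'
#' Simulates an EHR-like diabetes cohort from a discrete-time four-stage
#' Markov model with stage-conditional emission of biomarkers, prescriptions,
#' flags and templated clinical notes. Every patient-year carries matching
#' ground-truth annotations, so extraction, staging and modelling stages are
#' testable without any external data. Identical configurations (including
#' the seed) produce identical cohorts.
#'
#' @param config A [cohort_config()].
#' @param lexicon A `lexicon` used for note surface forms.
#' @param templates Note templates, see [default_note_templates()].
#' @return List with `records` (one row per patient-year; structured fields
#'   plus `note_text`) and `truth` (ground-truth annotations aligned by
#'   `patient_id`/`year`).
#' @export
generate_cohort <- function(config, lexicon = default_lexicon(),
                            templates = default_note_templates()) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_patients == 0) return(empty_cohort())
  set.seed(config$seed)
  n <- config$n_patients
  years <- config$years
  ny <- length(years)
  s <- stage_levels()
  prev <- config$label_prevalences
  bio <- config$biomarker_params

  ## patient-level attributes: baseline stage first, then flags (planted
  ## covariate effects act on the transitions, so flags must exist before the
  ## rest of the path is drawn)
  stage0 <- sample(s, n, replace = TRUE, prob = config$initial_stage_probs)
  flags <- data.frame(row.names = seq_len(n))
  adh_u <- stats::runif(n)
  p_comp <- prev$patient_compliance[stage0]
  p_non <- prev$non_compliance_stated[stage0]
  adherence <- ifelse(adh_u < p_comp, "compliant",
                      ifelse(adh_u < p_comp + p_non, "non_compliant", "unstated"))
  flags$patient_compliance <- adherence == "compliant"
  for (f in c("hba1c_guide", "cholesterol_guide", "rec_nutrition",
              "rec_physical", "rec_alcohol", "rec_tobacco", "analgesic",
              "antacid")) {
    flags[[f]] <- stats::runif(n) < prev[[f]][stage0]
  }
  sex <- ifelse(stats::runif(n) < prev$female[stage0], "F", "M")
  age0 <- round(rtruncnorm(n, bio$age$mean[stage0], bio$age$sd[stage0],
                           lower = 30, upper = 100))

  ## stage paths
  stages <- if (ny > 1) {
    sample_stage_paths(config, stage0, flags)
  } else matrix(stage0, n, 1)

  ## complication onsets
  comp <- matrix(vapply(seq_len(ny), function(k) is_complication_stage(stages[, k]),
                        logical(n)), n, ny)
  onset_year <- apply(comp, 1, function(r) if (any(r)) which(r)[1] else NA_integer_)
  ctype <- rep(NA_character_, n)
  has_any <- !is.na(onset_year)
  ctype[has_any] <- sample(names(complication_code_map()), sum(has_any),
                           replace = TRUE, prob = c(0.5, 0.3, 0.2))

  ## long format assembly
  idx_p <- rep(seq_len(n), each = ny)
  idx_y <- rep(seq_len(ny), times = n)
  stage_py <- as.character(t(stages))
  comp_py <- as.logical(t(comp))
  age_py <- age0[idx_p] + (idx_y - 1L)
  thr_py <- personal_goal(age_py, comp_py, config$goal_policy)
  nrec <- n * ny

  draw_bio <- function(var, lower = -Inf, upper = Inf) {
    p <- bio[[var]]
    rtruncnorm(nrec, p$mean[stage_py], p$sd[stage_py], lower, upper)
  }
  ldl <- draw_bio("ldl", lower = 20)
  egfr <- draw_bio("egfr", lower = 5)
  creat <- draw_bio("creatinine", lower = 0.2)
  bmi <- draw_bio("bmi", lower = 14)
  weight <- draw_bio("weight", lower = 30)
  height <- draw_bio("height", lower = 1.2, upper = 2.1)
  dbp <- draw_bio("dbp", lower = 40)
  sbp <- draw_bio("sbp", lower = 70)

  ## HbA1c consistent with the true stage: strictly below the personal goal in
  ## ON stages, at/above it in OUT stages
  hm <- bio$hba1c$mean[stage_py]; hs <- bio$hba1c$sd[stage_py]
  on <- is_on_goal_stage(stage_py)
  hba1c <- numeric(nrec)
  hba1c[on] <- rtruncnorm(sum(on), hm[on], hs[on], lower = 3.5,
                          upper = thr_py[on] - 1e-6)
  hba1c[!on] <- rtruncnorm(sum(!on), hm[!on], hs[!on], lower = thr_py[!on],
                           upper = 18)
  ## round to lab precision without letting rounding cross the goal boundary
  hba1c <- round(hba1c, 2)
  hba1c[on] <- pmin(hba1c[on], thr_py[on] - 0.01)
  hba1c[!on] <- pmax(hba1c[!on], thr_py[!on])
  if (config$hba1c_missing_rate > 0) {
    hba1c[stats::runif(nrec) < config$hba1c_missing_rate] <- NA_real_
  }

  ## prescriptions
  tm <- config$treatment_means
  n_anti <- pmin(stats::rpois(nrec, tm$antihypertensive[stage_py]), 3L)
  n_hypo <- pmin(stats::rpois(nrec, tm$hypoglycemic[stage_py]), 3L)
  lipid <- stats::runif(nrec) < pmin(tm$lipid_lowering[stage_py], 1)
  analgesic <- flags$analgesic[idx_p]
  antacid <- flags$antacid[idx_p]

  anti_mat <- rotated_pick(c("enalapril", "losartan", "amlodipine", "metoprolol"),
                           nrec, n_anti)
  insulin_on <- n_hypo > 0 & stats::runif(nrec) <
    ifelse(is_on_goal_stage(stage_py), 0.10, 0.35)
  n_oral <- pmax(n_hypo - insulin_on, 0L)
  met_first <- n_oral > 0 & stats::runif(nrec) < 0.85
  n_second <- pmax(n_oral - met_first, 0L)
  second_mat <- rotated_pick(c("empagliflozin", "sitagliptin", "dapagliflozin",
                               "glibenclamide"), nrec, n_second)
  ins_pick <- c("insulin glargine", "insulin aspart",
                "insulin nph")[sample.int(3, nrec, replace = TRUE)]
  lip_pick <- c("atorvastatin", "rosuvastatin")[sample.int(2, nrec, replace = TRUE)]
  ana_pick <- c("acetaminophen", "ibuprofen")[sample.int(2, nrec, replace = TRUE)]
  ant_pick <- c("omeprazole", "ranitidine")[sample.int(2, nrec, replace = TRUE)]

  pieces <- cbind(ifelse(met_first, "metformin", ""), second_mat,
                  ifelse(insulin_on, ins_pick, ""),
                  anti_mat,
                  ifelse(lipid, lip_pick, ""),
                  ifelse(analgesic, ana_pick, ""),
                  ifelse(antacid, ant_pick, ""))
  drugs_true <- join_rows(pieces)
  keep <- matrix(stats::runif(length(pieces)) >=
                   config$structured_drug_missing_rate,
                 nrow(pieces), ncol(pieces))
  pieces_struct <- ifelse(keep, pieces, "")
  drugs_struct <- join_rows(pieces_struct)

  ## conditions: hypertension iff on antihypertensives; dyslipidemia iff on
  ## lipid-lowering; plus the (absorbing) staging complication
  cond_list <- cbind(ifelse(n_anti > 0, "hypertension", ""),
                     ifelse(lipid, "dyslipidemia", ""),
                     ifelse(comp_py, complication_condition_map()[ctype[idx_p]], ""))
  cond_list[is.na(cond_list)] <- ""
  conds_true <- join_rows(cond_list)
  icd <- ifelse(comp_py, complication_code_map()[ctype[idx_p]], "")
  icd[is.na(icd)] <- ""

  records <- data.frame(
    patient_id = idx_p, year = years[idx_y],
    age = age_py, sex = sex[idx_p],
    ldl = round(ldl, 1), egfr = round(egfr, 1), creatinine = round(creat, 2),
    bmi = round(bmi, 1), weight = round(weight, 1), height = round(height, 2),
    dbp = round(dbp), sbp = round(sbp), hba1c = hba1c,
    icd10_codes = icd, drugs_structured = drugs_struct,
    treat_antihypertensive = n_anti, treat_hypoglycemic = n_hypo,
    treat_lipid = as.integer(lipid),
    analgesic = analgesic, antacid = antacid,
    patient_compliance = flags$patient_compliance[idx_p],
    hba1c_guide = flags$hba1c_guide[idx_p],
    cholesterol_guide = flags$cholesterol_guide[idx_p],
    rec_nutrition = flags$rec_nutrition[idx_p],
    rec_physical = flags$rec_physical[idx_p],
    rec_alcohol = flags$rec_alcohol[idx_p],
    rec_tobacco = flags$rec_tobacco[idx_p],
    stringsAsFactors = FALSE
  )

  truth <- data.frame(
    patient_id = idx_p, year = years[idx_y],
    stage = stage_py,
    complications = ifelse(comp_py, ctype[idx_p], ""),
    drugs = drugs_true, conditions = conds_true,
    adherence = adherence[idx_p],
    rec_nutrition = flags$rec_nutrition[idx_p],
    rec_physical = flags$rec_physical[idx_p],
    rec_alcohol = flags$rec_alcohol[idx_p],
    rec_tobacco = flags$rec_tobacco[idx_p],
    goal_threshold = thr_py,
    stringsAsFactors = FALSE
  )

  if (config$render_notes) {
    tdrugs <- unpack_list(drugs_true)
    tconds <- unpack_list(conds_true)
    notes <- character(nrec)
    recnames <- c("nutrition", "physical", "alcohol", "tobacco")
    for (i in seq_len(nrec)) {
      st <- list(age = age_py[i], conditions = tconds[[i]], drugs = tdrugs[[i]],
                 adherence = adherence[idx_p[i]],
                 recommendations = stats::setNames(as.list(
                   c(flags$rec_nutrition[idx_p[i]], flags$rec_physical[idx_p[i]],
                     flags$rec_alcohol[idx_p[i]], flags$rec_tobacco[idx_p[i]])),
                   recnames))
      notes[i] <- render_note(st, templates, config$note_noise, lexicon)
    }
    records$note_text <- notes
  }
  list(records = records, truth = truth)
}

## internal: full stage-path matrix given a fixed baseline column; with an
## explicit 2-year matrix the endpoints follow it exactly and the middle year
## is a bridge draw from the 1-year row restricted to complication-compatible
## states (a NOT endpoint forbids a YES detour)
sample_stage_paths <- function(config, stage0, flags) {
  n <- config$n_patients
  ny <- length(config$years)
  P1 <- config$transition_matrix_1y
  s <- stage_levels()
  m <- matrix(character(0), n, ny)
  m[, 1] <- stage0
  eff <- config$effect_params
  if (!is.null(eff)) {
    xb <- function(beta) {
      if (is.null(beta) || length(beta) == 0) return(numeric(n))
      miss <- setdiff(names(beta), names(flags))
      if (length(miss) > 0) stopf("effect_params references unknown flag '%s'", miss[1])
      as.numeric(as.matrix(flags[, names(beta), drop = FALSE]) %*% beta)
    }
    xb_goal <- xb(eff$goal); xb_comp <- xb(eff$complication)
    for (k in 2:ny)
      m[, k] <- draw_next_stage_effects(m[, k - 1], P1, xb_goal, xb_comp)
    return(m)
  }
  P2 <- config$transition_matrix_2y
  if (!is.null(P2) && ny == 3) {
    validate_transition_matrix(P2)
    m[, 3] <- draw_next_stage(m[, 1], P2)
    for (st0 in unique(m[, 1])) {
      for (endnot in c(TRUE, FALSE)) {
        ix <- which(m[, 1] == st0 & (!is_complication_stage(m[, 3])) == endnot)
        if (length(ix) == 0) next
        row <- P1[st0, ]
        if (endnot) row[c("ON-YES", "OUT-YES")] <- 0
        if (sum(row) <= 0) { m[ix, 2] <- st0; next }
        m[ix, 2] <- sample(s, length(ix), replace = TRUE, prob = row / sum(row))
      }
    }
  } else {
    for (k in 2:ny) m[, k] <- draw_next_stage(m[, k - 1], P1)
  }
  m
}

#' Per-stage summary of a synthetic cohort
#'
#' One row per stage with the mean and SD of each biomarker and the prevalence
#' of each binary characteristic, computed over patient-years grouped by true
#' stage; used to check generator calibration against published per-stage
#' baseline characteristics.
#'
#' @param records Cohort records from [generate_cohort()].
#' @param truth Matching ground truth.
#' @return Data frame with columns `stage`, `n`, then `<var>_mean`,
#'   `<var>_sd` per biomarker and `<flag>_prev` per flag.
#' @export
summarize_cohort <- function(records, truth) {
  if (nrow(records) == 0) stopf("summarize_cohort: empty cohort")
  stopifnot(nrow(records) == nrow(truth))
  num_vars <- c("age", "ldl", "egfr", "creatinine", "bmi", "weight", "height",
                "dbp", "sbp", "hba1c")
  flag_vars <- c("patient_compliance", "hba1c_guide", "cholesterol_guide",
                 "rec_nutrition", "rec_physical", "rec_alcohol", "rec_tobacco")
  out <- lapply(stage_levels(), function(st) {
    ix <- truth$stage == st
    if (!any(ix)) return(NULL)
    row <- data.frame(stage = st, n = sum(ix), stringsAsFactors = FALSE)
    if (sum(ix) == 1)
      warning(sprintf("stage %s has a single observation; SD reported as 0", st))
    for (v in num_vars) {
      x <- records[[v]][ix]
      row[[paste0(v, "_mean")]] <- mean(x, na.rm = TRUE)
      sdv <- stats::sd(x, na.rm = TRUE)
      row[[paste0(v, "_sd")]] <- if (is.na(sdv)) 0 else sdv
    }
    row$female_prev <- mean(records$sex[ix] == "F")
    for (v in flag_vars) row[[paste0(v, "_prev")]] <- mean(records[[v]][ix])
    row
  })
  do.call(rbind, out)
}
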