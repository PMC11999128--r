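#' The twelve nested binary prediction tasks
#'
#' The four-stage outcome is decomposed into two nested binary questions per
#' starting stage and horizon: will the patient be out of HbA1c goals at the
#' horizon (asked from all four stages), and will the patient have developed a
#' chronic complication (asked only from the two complication-free stages,
#' since complications are absorbing). With horizons of one and two years
#' that yields exactly twelve tasks.
#'
#' @return Data frame with columns `id`, `horizon`, `initial_stage`,
#'   `outcome` (`"out_goal"` or `"complication"`).
#' @export
build_tasks <- function() {
  s <- stage_levels()
  rows <- list()
  for (h in c(1L, 2L)) {
    for (st in s)
      rows[[length(rows) + 1]] <- data.frame(
        id = sprintf("%dy_%s_goal", h, st), horizon = h,
        initial_stage = st, outcome = "out_goal", stringsAsFactors = FALSE)
    for (st in c("ON-NOT", "OUT-NOT"))
      rows[[length(rows) + 1]] <- data.frame(
        id = sprintf("%dy_%s_comp", h, st), horizon = h,
        initial_stage = st, outcome = "complication", stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

model_feature_names <- function() {
  c("age", "female", "ldl", "egfr", "creatinine", "bmi", "weight", "height",
    "dbp", "sbp", "hba1c", "treat_antihypertensive", "treat_hypoglycemic",
    "treat_lipid", "analgesic", "antacid", "patient_compliance",
    "hba1c_guide", "cholesterol_guide", "rec_nutrition", "rec_physical",
    "rec_alcohol", "rec_tobacco")
}

#' Build the dataset of one prediction task
#'
#' Restricts the staged cohort to patient-years in the task's initial stage
#' whose stage `horizon` years later is observed, and builds the baseline
#' feature matrix (demographics, biomarkers, treatment counts,
#' adherence/recommendation flags — never anything measured at the horizon)
#' and the binary outcome label.
#'
#' @param staged Staged cohort (from [stage_cohort()], with the generator's
#'   structured columns).
#' @param task One row of [build_tasks()].
#' @return List with `x` (numeric feature data frame), `y` (0/1 integer
#'   vector), `task`.
#' @export
make_dataset <- function(staged, task) {
  h <- task$horizon
  years <- sort(unique(staged$year))
  base_years <- years[(years + h) %in% years]
  if (length(base_years) == 0)
    stopf("cohort does not span horizon %d", h)
  base <- staged[staged$year %in% base_years & staged$stage == task$initial_stage, ]
  if (nrow(base) == 0)
    stopf("no patients in initial condition %s at horizon %d",
          task$initial_stage, h)
  key <- paste(staged$patient_id, staged$year, sep = ":")
  fut <- staged$stage[match(paste(base$patient_id, base$year + h, sep = ":"), key)]
  keep <- !is.na(fut)
  base <- base[keep, ]; fut <- fut[keep]
  if (nrow(base) == 0)
    stopf("no patients in initial condition %s observed %d year(s) later",
          task$initial_stage, h)
  y <- if (task$outcome == "out_goal") {
    as.integer(fut %in% c("OUT-NOT", "OUT-YES"))
  } else {
    if (is_complication_stage(task$initial_stage))
      stopf("complication outcome undefined for complication starters")
    as.integer(is_complication_stage(fut))
  }
  x <- base
  x$female <- as.numeric(x$sex == "F")
  feats <- intersect(model_feature_names(), names(x))
  x <- x[, feats, drop = FALSE]
  x[] <- lapply(x, as.numeric)
  list(x = x, y = y, task = task)
}
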