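#' Personalised HbA1c goal policies
#'
#' A goal policy maps patient characteristics (age, staging complications) to a
#' personalised HbA1c target threshold. Diabetes standards personalise the
#' glycemic target to <6.5, <7.0 or <7.5 percent; the mapping shipped as the
#' default is an assumption of this package, not guideline text: younger
#' patients (<45) without complications get the strict 6.5 target, ages 45-64
#' get 7.0, and age 65+ or any staging complication relaxes the target to 7.5.
#'
#' @param rules A list of rules, each a list with elements `max_age` (exclusive
#'   upper age bound, `Inf` allowed), `complications` (`"any"`, `"none"`, or
#'   `NA` for don't-care) and `threshold` (one of the allowed thresholds).
#'   Rules are evaluated in order; the first match wins.
#' @param default_threshold Threshold used when no rule matches.
#' @param allowed Numeric vector of permitted thresholds.
#' @return An object of class `goal_policy`.
#' @export
goal_policy <- function(rules = NULL, default_threshold = 7.0,
                        allowed = c(6.5, 7.0, 7.5)) {
  if (is.null(rules)) {
    rules <- list(
      list(max_age = 45,  complications = "none", threshold = 6.5),
      list(max_age = 65,  complications = NA,     threshold = 7.0),
      list(max_age = Inf, complications = NA,     threshold = 7.5)
    )
  }
  for (r in rules) {
    if (!r$threshold %in% allowed)
      stopf("goal_policy: threshold %s not in allowed set", r$threshold)
  }
  structure(list(rules = rules, default_threshold = default_threshold,
                 allowed = allowed),
            class = "goal_policy")
}

#' Fixed-threshold goal policy
#'
#' Convenience constructor for a policy that assigns the same HbA1c target to
#' every patient, used e.g. when calibrating the generator against published
#' per-stage HbA1c moments.
#'
#' @param threshold The single HbA1c threshold (percent).
#' @return A `goal_policy`.
#' @export
fixed_goal_policy <- function(threshold = 7.0) {
  goal_policy(rules = list(list(max_age = Inf, complications = NA,
                                threshold = threshold)),
              default_threshold = threshold, allowed = threshold)
}

#' Personal HbA1c goal threshold
#'
#' @param age Age in years (> 0).
#' @param has_complication Logical; does the patient have any staging
#'   complication (retinopathy, cerebrovascular disease, CKD)?
#' @param policy A [goal_policy()].
#' @return The HbA1c threshold (percent) for this patient.
#' @export
#' @examples
#' personal_goal(40, FALSE, goal_policy())  # 6.5
#' personal_goal(70, TRUE, goal_policy())   # 7.5
personal_goal <- function(age, has_complication, policy = goal_policy()) {
  stopifnot(length(age) == length(has_complication))
  if (any(age <= 0)) stopf("personal_goal: age must be positive")
  out <- numeric(length(age))
  for (i in seq_along(age)) {
    thr <- policy$default_threshold
    for (r in policy$rules) {
      comp_ok <- is.na(r$complications) ||
        (r$complications == "any" && has_complication[i]) ||
        (r$complications == "none" && !has_complication[i])
      if (age[i] < r$max_age && comp_ok) { thr <- r$threshold; break }
    }
    out[i] <- thr
  }
  out
}

#' Assign a patient-year to a progression stage
#'
#' A patient is ON-goal iff HbA1c is strictly below the personal threshold
#' (targets are stated as "< threshold", so a value exactly at the threshold is
#' out of goal), and in a complication stage iff any staging complication is
#' present.
#'
#' @param hba1c HbA1c in percent (> 0). Vectorised.
#' @param threshold Personal goal threshold in percent.
#' @param has_complication Logical.
#' @return Character vector of stage labels (see [stage_levels()]).
#' @export
#' @examples
#' assign_stage(6.37, 7.0, FALSE)  # "ON-NOT"
#' assign_stage(7.0, 7.0, FALSE)   # "OUT-NOT": boundary is out of goal
assign_stage <- function(hba1c, threshold, has_complication) {
  if (any(hba1c <= 0)) stopf("assign_stage: hba1c must be positive")
  on <- hba1c < threshold
  ifelse(on & !has_complication, "ON-NOT",
         ifelse(!on & !has_complication, "OUT-NOT",
                ifelse(on, "ON-YES", "OUT-YES")))
}

#' Default ICD-10 code prefixes for the staging complications
#'
#' Standard code blocks for the three staging complications. The original
#' study used an audited institutional code list; this shipped list is a
#' documented, user-replaceable stand-in covering the standard blocks.
#'
#' @return Named list of character vectors of ICD-10 code prefixes.
#' @export
staging_icd10_codes <- function() {
  list(
    retinopathy     = c("H360", "E103", "E113"),
    cerebrovascular = c("I63", "I64", "I69", "G45"),
    ckd             = c("N18", "E112")
  )
}

#' Per-year absorbing complication status for one patient
#'
#' Scans a patient's ICD-10 codes year by year; the complication indicator
#' turns true in the first year any staging code appears and stays true
#' afterwards (complications are chronic and absorbing).
#'
#' @param codes_by_year List (ordered by year) of character vectors of ICD-10
#'   codes recorded in each year.
#' @param icd10_map Named list of code prefixes, as [staging_icd10_codes()].
#' @return Logical vector, one element per year.
#' @export
complication_status <- function(codes_by_year, icd10_map = staging_icd10_codes()) {
  prefixes <- unlist(icd10_map, use.names = FALSE)
  hit <- vapply(codes_by_year, function(codes) {
    if (length(codes) == 0) return(FALSE)
    any(vapply(codes, function(cd) {
      any(startsWith(toupper(gsub("[^A-Za-z0-9]", "", cd)), prefixes))
    }, logical(1)))
  }, logical(1))
  as.logical(cummax(hit))
}

#' Validate the no-recovery constraint on a stage sequence
#'
#' Complications are absorbing: a transition from a YES-complication stage back
#' to a NOT-complication stage is structurally impossible, and observing one in
#' data indicates an upstream coding problem.
#'
#' @param stages Character vector of stage labels, in year order.
#' @return The sequence, invisibly unchanged, if valid.
#' @export
enforce_monotone <- function(stages) {
  if (length(stages) == 0) stopf("enforce_monotone: empty stage sequence")
  comp <- is_complication_stage(stages)
  if (length(stages) > 1) {
    bad <- which(comp[-length(comp)] & !comp[-1])
    if (length(bad) > 0)
      stopf("forbidden complication recovery at step (%d,%d): %s -> %s",
            bad[1], bad[1] + 1, stages[bad[1]], stages[bad[1] + 1])
  }
  invisible(stages)
}
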