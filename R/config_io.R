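## Readers for the shipped JSON/YAML configuration formats. Every loader
## returns the same objects the in-code constructors produce, so file-driven
## and programmatic use are interchangeable.

null_to_inf <- function(x, neg = FALSE) {
  if (is.null(x)) (if (neg) -Inf else Inf) else x
}

#' Read a goal policy from JSON
#' @param path JSON file with `rules`, `default_threshold`, `allowed`.
#' @return A [goal_policy()].
#' @export
read_goal_policy <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  rules <- lapply(j$rules, function(r) list(
    max_age = null_to_inf(r$max_age),
    complications = if (is.null(r$complications)) NA else r$complications,
    threshold = r$threshold))
  goal_policy(rules, default_threshold = j$default_threshold %||% 7.0,
              allowed = unlist(j$allowed %||% c(6.5, 7.0, 7.5)))
}

#' Read a guideline rule from JSON
#' @param path JSON file with a `bands` array.
#' @return A [guideline_rule()].
#' @export
read_guideline_rule <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  guideline_rule(lapply(j$bands, function(b) list(
    hba1c_max = null_to_inf(b$hba1c_max),
    egfr_min = null_to_inf(b$egfr_min, neg = TRUE),
    egfr_max = null_to_inf(b$egfr_max),
    class = b$class)))
}

#' Read a staging ICD-10 code list from JSON
#' @param path JSON object mapping complication name to code-prefix array.
#' @return Named list of character vectors, as [staging_icd10_codes()].
#' @export
read_staging_codes <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Read a cohort configuration from YAML
#'
#' Fields absent from the file fall back to the [cohort_config()] defaults;
#' transition matrices may be given as 4x4 row-major numeric arrays.
#'
#' @param path YAML file.
#' @return A [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  as_mat <- function(m) {
    if (is.null(m)) return(NULL)
    matrix(unlist(m), 4, 4, byrow = TRUE,
           dimnames = list(stage_levels(), stage_levels()))
  }
  args <- list(n_patients = y$n_patients, seed = y$seed %||% 1L)
  if (!is.null(y$years)) args$years <- as.integer(unlist(y$years))
  if (!is.null(y$initial_stage_probs))
    args$initial_stage_probs <- unlist(y$initial_stage_probs)
  if (!is.null(y$transition_matrix_1y))
    args$transition_matrix_1y <- as_mat(y$transition_matrix_1y)
  if (!is.null(y$transition_matrix_2y))
    args$transition_matrix_2y <- as_mat(y$transition_matrix_2y)
  for (f in c("note_noise", "render_notes", "structured_drug_missing_rate",
              "hba1c_missing_rate"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  do.call(cohort_config, args)
}
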