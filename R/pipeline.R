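#' Inclusion filter for longitudinal modelling
#'
#' Mirrors the study-cohort funnel: patients are kept only if they have an
#' HbA1c value in every study year (first rule) and no missing modelled
#' predictor (second rule); no imputation is performed.
#'
#' @param records Cohort records (one row per patient-year).
#' @param years Study years that must all be present; default all years in
#'   the data.
#' @return List with `records` (filtered) and `log` (data frame of per-rule
#'   removal counts).
#' @export
filter_cohort <- function(records, years = NULL) {
  years <- years %||% sort(unique(records$year))
  n0 <- length(unique(records$patient_id))
  by_p <- split(records, records$patient_id)
  has_all_hba1c <- vapply(by_p, function(d) {
    all(years %in% d$year) && !anyNA(d$hba1c[d$year %in% years])
  }, logical(1))
  keep1 <- names(by_p)[has_all_hba1c]
  rec1 <- records[as.character(records$patient_id) %in% keep1, ]
  n1 <- length(unique(rec1$patient_id))
  pred_cols <- intersect(setdiff(model_feature_names(), "female"), names(rec1))
  pred_cols <- c(pred_cols, "sex")
  ok_row <- stats::complete.cases(rec1[, pred_cols, drop = FALSE])
  bad_p <- unique(rec1$patient_id[!ok_row])
  rec2 <- rec1[!(rec1$patient_id %in% bad_p), ]
  n2 <- length(unique(rec2$patient_id))
  list(records = rec2,
       log = data.frame(
         rule = c("input", "hba1c_all_years", "complete_predictors"),
         patients = c(n0, n1, n2),
         removed = c(0L, n0 - n1, n1 - n2), stringsAsFactors = FALSE))
}

#' Label a cohort's notes and backfill structured fields
#'
#' Runs the extraction pipeline over every note and merges the results into
#' the structured rows; returns the completed table plus the per-note
#' extraction results for auditing.
#'
#' @param records Cohort records with a `note_text` column.
#' @param lexicon A `lexicon`.
#' @return List with `records` (completed: merged `drugs`, `conditions`,
#'   adherence/recommendation backfill), `extractions` (named list keyed
#'   `patient_id:year`).
#' @export
label_cohort <- function(records, lexicon = default_lexicon()) {
  if (!"note_text" %in% names(records))
    stopf("records have no note_text column")
  ext <- vector("list", nrow(records))
  names(ext) <- paste(records$patient_id, records$year, sep = ":")
  drugs <- conds <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    e <- extract_record(records$note_text[i], lexicon)
    ext[[i]] <- e
    m <- merge_structured(records[i, ], e)
    drugs[i] <- m$row$drugs
    conds[i] <- m$row$conditions
  }
  records$drugs <- drugs
  records$conditions <- conds
  list(records = records, extractions = ext)
}

#' Pipeline configuration
#'
#' @param cohort A [cohort_config()].
#' @param lexicon A `lexicon`.
#' @param policy A [goal_policy()].
#' @param rule A [guideline_rule()].
#' @param train A [train_config()].
#' @param horizons Transition horizons to summarise.
#' @param train_models Fit the twelve transition models?
#' @param label_notes Run NLP labelling (requires rendered notes)?
#' @param output_dir Optional directory for artifacts (CSV/JSON).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(cohort, lexicon = default_lexicon(),
                            policy = goal_policy(), rule = guideline_rule(),
                            train = train_config(), horizons = c(1, 2),
                            train_models = TRUE, label_notes = FALSE,
                            output_dir = NULL) {
  stopifnot(inherits(cohort, "cohort_config"))
  structure(list(cohort = cohort, lexicon = lexicon, policy = policy,
                 rule = rule, train = train, horizons = horizons,
                 train_models = train_models, label_notes = label_notes,
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full progression-analysis pipeline
#'
#' simulate -> (label) -> filter -> stage -> transitions -> adherence ->
#' train. Reruns with the same configuration produce identical reports.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report`: per-stage row counts, filter log, extraction
#'   quality (when labelling ran), transition matrices, adherence cross-tab,
#'   per-task model metrics and marginal effects, and the config echo.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  gen <- generate_cohort(config$cohort, config$lexicon)
  if (nrow(gen$records) == 0)
    stopf("staging failed: generated cohort is empty (n_patients = 0)")
  counts <- list(generated = nrow(gen$records))

  quality <- NULL
  records <- gen$records
  if (config$label_notes) {
    lab <- label_cohort(records, config$lexicon)
    records <- lab$records
    quality <- evaluate_extraction(lab$extractions, gen$truth)
  }

  filt <- filter_cohort(records, config$cohort$years)
  records <- filt$records
  counts$after_filter <- nrow(records)
  if (nrow(records) == 0) stopf("staging failed: no patients pass the filter")

  staged <- stage_cohort(records, config$policy)
  counts$staged <- nrow(staged)
  transitions <- summarize_transitions(staged, config$horizons)

  ## guideline adherence on treated patient-years
  drugs <- if ("drugs" %in% names(staged)) staged$drugs else staged$drugs_structured
  dl <- unpack_list(drugs)
  actual <- vapply(dl, actual_treatment, character(1), lexicon = config$lexicon)
  ideal <- ideal_treatment(staged$hba1c, staged$egfr, config$rule)
  treated <- actual != "none"
  crosstab <- if (any(treated)) cross_tab(ideal[treated], actual[treated]) else NULL

  models <- NULL; metrics <- NULL
  if (config$train_models) {
    tasks <- build_tasks()
    tasks <- tasks[tasks$horizon %in% config$horizons, ]
    models <- list()
    for (i in seq_len(nrow(tasks))) {
      ds <- make_dataset(staged, tasks[i, ])
      models[[tasks$id[i]]] <- train_and_select(ds$x, ds$y, config$train,
                                                task = tasks[i, ])
    }
    metrics <- do.call(rbind, lapply(models, function(fr) {
      data.frame(task = fr$task$id, family = fr$family, cutoff = fr$cutoff,
                 accuracy = fr$metrics_test$accuracy, f1 = fr$metrics_test$f1,
                 auc = fr$metrics_test$auc, tpr = fr$metrics_test$tpr,
                 fpr = fr$metrics_test$fpr, tnr = fr$metrics_test$tnr,
                 fnr = fr$metrics_test$fnr, stringsAsFactors = FALSE)
    }))
    rownames(metrics) <- NULL
  }

  report <- structure(list(counts = counts, filter_log = filt$log,
                           extraction_quality = quality,
                           transitions = transitions, crosstab = crosstab,
                           models = models, model_metrics = metrics,
                           seed = config$cohort$seed,
                           staged = staged),
                      class = "run_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$staged, file.path(dir, "staged_cohort.csv"),
                   row.names = FALSE)
  for (h in names(report$transitions)) {
    tm <- report$transitions[[h]]
    utils::write.csv(as.data.frame(tm$proportions),
                     file.path(dir, sprintf("transitions_%sy.csv", h)))
  }
  if (!is.null(report$model_metrics)) {
    jsonlite::write_json(report$model_metrics,
                         file.path(dir, "model_metrics.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run report\n")
  cat("  rows generated:", x$counts$generated,
      "| after filter:", x$counts$after_filter, "\n")
  for (h in names(x$transitions))
    cat(sprintf("  %s-year transitions over %d pairs\n", h, x$transitions[[h]]$n))
  if (!is.null(x$model_metrics)) {
    cat("  fitted tasks:", nrow(x$model_metrics), "\n")
  }
  invisible(x)
}
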