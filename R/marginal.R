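#' Average marginal effects on the predicted transition probability
#'
#' For a binary feature (all observed values in {0, 1}) the effect is the
#' mean over the sample of `p(x | feature = 1) - p(x | feature = 0)`; for a
#' continuous feature it is the mean of `p(x + 1 SD) - p(x)`. Effects are
#' reported in percentage points of transition probability.
#'
#' @param fit A fitted learner (`dmt_learner`) or any object accepted by
#'   [predict_prob()].
#' @param x Feature data frame the effects are averaged over (typically the
#'   training data).
#' @return Data frame with `feature`, `type` ("binary"/"continuous") and
#'   `effect_pp`, sorted by decreasing absolute effect.
#' @export
marginal_effects <- function(fit, x) {
  feats <- if (inherits(fit, "dmt_learner")) fit$features else names(x)
  x <- x[, feats, drop = FALSE]
  base <- predict_prob(fit, x)
  out <- lapply(feats, function(f) {
    v <- x[[f]]
    if (all(v %in% c(0, 1))) {
      x1 <- x; x1[[f]] <- 1
      x0 <- x; x0[[f]] <- 0
      eff <- mean(predict_prob(fit, x1) - predict_prob(fit, x0))
      type <- "binary"
    } else {
      x1 <- x; x1[[f]] <- v + stats::sd(v)
      eff <- mean(predict_prob(fit, x1) - base)
      type <- "continuous"
    }
    data.frame(feature = f, type = type, effect_pp = 100 * eff,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(-abs(out$effect_pp)), ]
}

#' Four-stage transition probabilities for one patient (the calculator)
#'
#' Combines the two nested binary models of the patient's current stage into
#' a probability vector over the four stages at the horizon. For
#' complication-free starters the goal-outcome and complication-outcome
#' probabilities are combined as independent (outer product); for starters
#' with complications all mass stays on the two complication stages, since
#' complications are absorbing.
#'
#' @param bundle Named list of [train_and_select()] results keyed by task id
#'   (as in [build_tasks()]).
#' @param patient One-row data frame of features; must also allow staging
#'   (columns `hba1c`, `age` and either `has_complication` or `icd10_codes`).
#' @param horizon 1 or 2.
#' @param policy A [goal_policy()] used to determine the current stage.
#' @return Named numeric 4-vector over [stage_levels()], summing to 1.
#' @export
predict_stage_probabilities <- function(bundle, patient, horizon = 1,
                                        policy = goal_policy()) {
  stopifnot(horizon %in% c(1, 2))
  need <- c("hba1c", "age")
  miss <- setdiff(need, names(patient))
  if (length(miss) > 0)
    stopf("patient is missing required feature(s): %s",
          paste(miss, collapse = ", "))
  comp <- if ("has_complication" %in% names(patient)) {
    isTRUE(patient$has_complication)
  } else if ("icd10_codes" %in% names(patient)) {
    complication_status(unpack_list(patient$icd10_codes), staging_icd10_codes())
  } else stopf("patient needs 'has_complication' or 'icd10_codes'")
  thr <- personal_goal(patient$age, comp, policy)
  stage <- assign_stage(patient$hba1c, thr, comp)

  get_p <- function(outcome) {
    id <- sprintf("%dy_%s_%s", horizon, stage, outcome)
    fr <- bundle[[id]]
    if (is.null(fr)) stopf("bundle has no fitted model for task '%s'", id)
    miss <- setdiff(fr$features, names(patient))
    if (length(miss) > 0)
      stopf("patient is missing model feature(s): %s", paste(miss, collapse = ", "))
    predict_prob(fr$fit, patient)
  }
  p_out <- get_p("goal")
  if (is_complication_stage(stage)) {
    v <- c(0, 0, 1 - p_out, p_out)
  } else {
    p_comp <- get_p("comp")
    v <- c((1 - p_out) * (1 - p_comp), p_out * (1 - p_comp),
           (1 - p_out) * p_comp, p_out * p_comp)
  }
  stats::setNames(v / sum(v), stage_levels())
}
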