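#' Published one- and two-year stage transition matrices
#'
#' Row-stochastic 4x4 matrices of stage-transition proportions reported for a
#' large Colombian HMO diabetes cohort, used as the default dynamics of the
#' synthetic cohort generator. Rows are initial stage, columns final stage, in
#' [stage_levels()] order; entries are proportions (rows sum to 1). The
#' complication rows carry structural zeros in the NOT columns.
#'
#' @param horizon 1 or 2 (years).
#' @return A 4x4 numeric matrix with dim names.
#' @export
reference_transition_matrix <- function(horizon = 1) {
  s <- stage_levels()
  if (horizon == 1) {
    m <- rbind(
      c(47.75, 10.10, 34.62,  7.52),
      c(16.11, 40.82, 11.97, 31.11),
      c( 0.00,  0.00, 81.84, 18.16),
      c( 0.00,  0.00, 26.94, 73.06)) / 100
  } else if (horizon == 2) {
    m <- rbind(
      c(26.86,  6.73, 52.04, 14.37),
      c(11.57, 21.03, 22.33, 45.06),
      c( 0.00,  0.00, 80.99, 19.01),
      c( 0.00,  0.00, 32.98, 67.02)) / 100
  } else stopf("horizon must be 1 or 2")
  dimnames(m) <- list(s, s)
  m / rowSums(m)  # remove the <=0.02pp rounding slack of the printed rows
}

#' Validate a stage transition matrix
#'
#' Checks row-stochasticity (each row sums to 1 within tolerance),
#' non-negativity, and the structural zeros implied by absorbing
#' complications (YES rows cannot place mass on NOT columns).
#'
#' @param m 4x4 numeric matrix in [stage_levels()] order.
#' @param tol Row-sum tolerance.
#' @return The matrix, invisibly, with dim names set.
#' @export
validate_transition_matrix <- function(m, tol = 1e-9) {
  s <- stage_levels()
  if (!is.matrix(m) || any(dim(m) != 4))
    stopf("transition matrix must be 4x4 in order %s", paste(s, collapse = ", "))
  if (any(m < 0)) stopf("transition matrix has a negative entry")
  rs <- rowSums(m)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad) > 0)
    stopf("transition matrix row '%s' sums to %.12f, not 1", s[bad[1]], rs[bad[1]])
  for (i in c(3L, 4L)) for (j in c(1L, 2L)) {
    if (m[i, j] != 0)
      stopf("structural zero violated: row '%s' has mass %g on '%s'",
            s[i], m[i, j], s[j])
  }
  dimnames(m) <- list(s, s)
  invisible(m)
}

#' Empirical transition matrix between two aligned stage vectors
#'
#' Counts patients by (initial stage, final stage) and row-normalises. The
#' structural constraint of absorbing complications is enforced: an observed
#' YES-to-NOT transition raises an error rather than being silently dropped.
#'
#' @param states_t0,states_th Character vectors of stage labels, aligned by
#'   patient (same length).
#' @param horizon Years between the two observations (metadata only).
#' @return An object of class `transition_matrix` with elements `counts`,
#'   `proportions` (rows with zero count are `NA`), `horizon_years`, `n`.
#' @export
transition_matrix <- function(states_t0, states_th, horizon = 1) {
  if (length(states_t0) != length(states_th))
    stopf("state vectors must be aligned (lengths %d vs %d)",
          length(states_t0), length(states_th))
  s <- stage_levels()
  f0 <- factor(states_t0, levels = s)
  fh <- factor(states_th, levels = s)
  if (anyNA(f0) || anyNA(fh)) stopf("unknown stage label in input")
  bad <- is_complication_stage(states_t0) & !is_complication_stage(states_th)
  if (any(bad))
    stopf("%d observed transition(s) recover from complications (first at index %d); data violate the absorbing-complication model",
          sum(bad), which(bad)[1])
  counts <- table(f0, fh)
  counts <- matrix(as.integer(counts), 4, 4, dimnames = list(s, s))
  props <- counts / rowSums(counts)
  props[rowSums(counts) == 0, ] <- NA_real_
  structure(list(counts = counts, proportions = props,
                 horizon_years = horizon, n = length(states_t0)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("%d-year transition matrix (n = %d)\n", x$horizon_years, x$n))
  print(round(100 * x$proportions, digits = digits))
  invisible(x)
}

#' One- and two-year transition matrices of a staged cohort
#'
#' Computes the empirical transition matrices of a staged longitudinal cohort.
#' The 1-year matrix pools every adjacent-year pair (e.g. 2018 to 2019 and
#' 2019 to 2020); the 2-year matrix uses first-to-last year pairs two years
#' apart.
#'
#' @param staged Data frame with columns `patient_id`, `year`, `stage`.
#' @param horizons Integer vector of horizons to compute (subset of 1:2).
#' @return Named list of [transition_matrix()] objects, one per horizon
#'   (names `"1"`, `"2"`).
#' @export
summarize_transitions <- function(staged, horizons = c(1, 2)) {
  stopifnot(all(c("patient_id", "year", "stage") %in% names(staged)))
  staged <- staged[order(staged$patient_id, staged$year), ]
  years <- sort(unique(staged$year))
  out <- list()
  for (h in horizons) {
    pairs_from <- years[seq_len(length(years) - h)]
    if (length(pairs_from) == 0)
      stopf("cohort spans %d year(s); need at least %d for horizon %d",
            length(years), h + 1, h)
    from <- character(0); to <- character(0)
    for (y0 in pairs_from) {
      a <- staged[staged$year == y0, c("patient_id", "stage")]
      b <- staged[staged$year == y0 + h, c("patient_id", "stage")]
      idx <- match(a$patient_id, b$patient_id)
      keep <- !is.na(idx)
      from <- c(from, a$stage[keep])
      to <- c(to, b$stage[idx[keep]])
    }
    if (length(from) == 0) stopf("no year pairs at horizon %d", h)
    out[[as.character(h)]] <- transition_matrix(from, to, horizon = h)
  }
  out
}

#' Stage a labelled cohort table
#'
#' Adds per-row personal goal threshold, absorbing complication flag (from the
#' ICD-10 code column) and stage label to a cohort table. Rows must carry
#' `patient_id`, `year`, `age`, `hba1c` and an `icd10_codes` column of
#' semicolon-separated codes.
#'
#' @param cohort Cohort data frame.
#' @param policy A [goal_policy()].
#' @param icd10_map Staging-code list, as [staging_icd10_codes()].
#' @return The cohort with added columns `has_complication`, `goal_threshold`,
#'   `stage`.
#' @export
stage_cohort <- function(cohort, policy = goal_policy(),
                         icd10_map = staging_icd10_codes()) {
  stopifnot(all(c("patient_id", "year", "age", "hba1c", "icd10_codes") %in%
                  names(cohort)))
  cohort <- cohort[order(cohort$patient_id, cohort$year), ]
  codes <- unpack_list(cohort$icd10_codes)
  comp <- logical(nrow(cohort))
  for (ix in split(seq_len(nrow(cohort)), cohort$patient_id)) {
    comp[ix] <- complication_status(codes[ix], icd10_map)
  }
  cohort$has_complication <- comp
  cohort$goal_threshold <- personal_goal(cohort$age, cohort$has_complication,
                                         policy)
  cohort$stage <- assign_stage(cohort$hba1c, cohort$goal_threshold,
                               cohort$has_complication)
  for (p in split(cohort$stage, cohort$patient_id)) enforce_monotone(p)
  cohort
}
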