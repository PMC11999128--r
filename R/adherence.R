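#' Classify the actually-prescribed hypoglycemic treatment
#'
#' Maps a canonical drug list to the treatment class used in the
#' ideal-vs-prescribed cross-classification. Combination products
#' (canonicals joined with `+`, e.g. `empagliflozin+metformin`) are expanded
#' into their components first. Precedence: any insulin implies `insulin`;
#' otherwise metformin plus at least one second-line anti-diabetic implies
#' `combined`; metformin alone implies `metformin`; else `none`.
#'
#' @param drugs Character vector of canonical drug names.
#' @param lexicon A `lexicon` providing drug classes.
#' @return One of `"metformin"`, `"combined"`, `"insulin"`, `"none"`.
#' @export
actual_treatment <- function(drugs, lexicon = default_lexicon()) {
  comps <- unique(unlist(strsplit(drugs, "+", fixed = TRUE)))
  if (length(comps) == 0) return("none")
  insulins <- drugs_of_class(lexicon, "insulin")
  hypo <- drugs_of_class(lexicon, "hypoglycemic")
  hypo <- unique(unlist(strsplit(hypo, "+", fixed = TRUE)))
  if (any(comps %in% insulins)) return("insulin")
  has_met <- "metformin" %in% comps
  second <- setdiff(intersect(comps, hypo), "metformin")
  if (has_met && length(second) > 0) return("combined")
  if (has_met) return("metformin")
  "none"
}

#' Guideline rule for the ideal hypoglycemic treatment
#'
#' An ordered band table over HbA1c and eGFR; the first matching band wins and
#' the bands must be exhaustive. The default shipped rule is a declared
#' stand-in for the clinical-practice-guideline algorithm (which is
#' institution-specific): HbA1c < 8 with preserved kidney function (eGFR >=
#' 30) calls for metformin; HbA1c 8-9.5 for metformin plus a second-line
#' agent; HbA1c > 9.5 or eGFR < 30 for insulin.
#'
#' @param bands List of bands, each with `hba1c_max` (exclusive upper bound,
#'   `Inf` allowed), `egfr_min` (inclusive lower bound, `-Inf` allowed) and
#'   `class`.
#' @return An object of class `guideline_rule`.
#' @export
guideline_rule <- function(bands = NULL) {
  if (is.null(bands)) {
    bands <- list(
      list(hba1c_max = Inf, egfr_min = -Inf, egfr_max = 30, class = "insulin"),
      list(hba1c_max = 8,   egfr_min = 30, egfr_max = Inf, class = "metformin"),
      list(hba1c_max = 9.5, egfr_min = 30, egfr_max = Inf, class = "combined"),
      list(hba1c_max = Inf, egfr_min = 30, egfr_max = Inf, class = "insulin")
    )
  }
  for (b in bands) {
    if (!b$class %in% c("metformin", "combined", "insulin"))
      stopf("guideline band class '%s' invalid", b$class)
  }
  structure(list(bands = bands), class = "guideline_rule")
}

#' Ideal hypoglycemic treatment under a guideline rule
#'
#' @param hba1c HbA1c percent (> 0). Vectorised.
#' @param egfr eGFR (> 0).
#' @param rule A [guideline_rule()].
#' @return Character vector of treatment classes.
#' @export
ideal_treatment <- function(hba1c, egfr, rule = guideline_rule()) {
  stopifnot(length(hba1c) == length(egfr))
  if (any(hba1c <= 0 | egfr <= 0, na.rm = TRUE))
    stopf("ideal_treatment: inputs must be positive")
  out <- rep(NA_character_, length(hba1c))
  for (b in rule$bands) {
    hit <- is.na(out) & hba1c < b$hba1c_max & egfr >= b$egfr_min &
      egfr < (b$egfr_max %||% Inf)
    out[hit] <- b$class
  }
  if (anyNA(out))
    stopf("guideline rule bands are not exhaustive (first uncovered: hba1c=%s, egfr=%s)",
          hba1c[which(is.na(out))[1]], egfr[which(is.na(out))[1]])
  out
}

#' Ideal-versus-prescribed treatment cross-tabulation
#'
#' 3x3 cross-classification of ideal (rows) against actually prescribed
#' (columns) hypoglycemic treatment class, with row percentages. The diagonal
#' is guideline concordance. Untreated patients must be filtered out first.
#'
#' @param ideal,actual Aligned character vectors with values in
#'   metformin/combined/insulin.
#' @return Object of class `adherence_crosstab`: `counts`, `row_percentages`.
#' @export
cross_tab <- function(ideal, actual) {
  stopifnot(length(ideal) == length(actual))
  classes <- c("metformin", "combined", "insulin")
  if (any(ideal == "none") || any(actual == "none"))
    stopf("cross_tab: filter untreated patients ('none' class) before tabulating")
  if (!all(ideal %in% classes) || !all(actual %in% classes))
    stopf("cross_tab: values must be in {metformin, combined, insulin}")
  counts <- table(factor(ideal, classes), factor(actual, classes))
  counts <- matrix(as.integer(counts), 3, 3, dimnames = list(classes, classes))
  pct <- 100 * counts / rowSums(counts)
  pct[rowSums(counts) == 0, ] <- NA_real_
  structure(list(counts = counts, row_percentages = pct),
            class = "adherence_crosstab")
}

#' @export
print.adherence_crosstab <- function(x, ...) {
  cat("ideal (rows) vs prescribed (columns), row %\n")
  print(round(x$row_percentages, 2))
  invisible(x)
}

#' Professional guideline-adherence flags for one patient-year
#'
#' `hba1c_guide` is true iff the prescribed hypoglycemic class equals the
#' guideline-ideal class for the year. `cholesterol_guide` is true iff a
#' lipid-lowering drug is present when LDL exceeds the threshold (default
#' 100 mg/dL), the LDL is at/below threshold, or a guideline-marker span was
#' found in the note.
#'
#' @param drugs Canonical drug list for the year.
#' @param hba1c,egfr,ldl Biomarkers.
#' @param rule A [guideline_rule()].
#' @param lexicon A `lexicon`.
#' @param ldl_threshold LDL threshold in mg/dL.
#' @param guideline_marker Was a guideline-marker span extracted from the
#'   note? Overrides the cholesterol rule when TRUE.
#' @return Named logical vector `c(hba1c_guide=, cholesterol_guide=)`.
#' @export
professional_adherence_flags <- function(drugs, hba1c, egfr, ldl,
                                         rule = guideline_rule(),
                                         lexicon = default_lexicon(),
                                         ldl_threshold = 100,
                                         guideline_marker = FALSE) {
  actual <- actual_treatment(drugs, lexicon)
  ideal <- ideal_treatment(hba1c, egfr, rule)
  lipid <- drugs_of_class(lexicon, "lipid_lowering")
  chol <- if (isTRUE(guideline_marker)) TRUE
  else if (ldl > ldl_threshold) any(drugs %in% lipid)
  else TRUE
  c(hba1c_guide = actual == ideal, cholesterol_guide = chol)
}
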