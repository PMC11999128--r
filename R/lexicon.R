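#' Read a clinical lexicon from JSON
#'
#' A lexicon maps surface forms (single- or multi-word, already normalised:
#' lowercase, accent-free) to canonical entities with a category. Categories
#' drive extraction: `drug` and `condition` become entity sets,
#' `adherence_negative`/`adherence_positive` drive the pharmacological
#' adherence classifier, `recommendation_*` set the lifestyle-recommendation
#' flags and `guideline_marker` feeds the guideline-adherence flags. Drug
#' entries may carry a `class` (hypoglycemic, insulin, antihypertensive,
#' lipid_lowering, analgesic, antacid, other) used by the treatment
#' classifier.
#'
#' @param path Path to the lexicon JSON file.
#' @return An object of class `lexicon`.
#' @export
read_lexicon <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  entries <- raw$entries
  if (is.null(entries$abbreviation)) entries$abbreviation <- FALSE
  entries$abbreviation[is.na(entries$abbreviation)] <- FALSE
  if (is.null(entries$class)) entries$class <- NA_character_
  entries$surface <- tolower(entries$surface)
  if (anyDuplicated(entries$surface))
    stopf("lexicon has duplicate surface form '%s'",
          entries$surface[duplicated(entries$surface)][1])
  lex <- list(
    entries = entries,
    stopwords = tolower(raw$stopwords %||% character(0)),
    negators = tolower(raw$negators %||% c("niega", "denies")),
    positive_negators = tolower(raw$positive_negators %||%
                                  c("no", "not", "sin", "niega", "denies")),
    max_ngram = raw$max_ngram %||% 3L
  )
  # token vocabulary used by the spelling corrector
  lex$word_vocab <- sort(unique(unlist(strsplit(entries$surface, " ", fixed = TRUE))))
  lex$surface_index <- stats::setNames(seq_len(nrow(entries)), entries$surface)
  structure(lex, class = "lexicon")
}

#' Packaged default lexicon
#'
#' The fixture lexicon shipped with the package. It covers the drug classes
#' and entities of the worked extraction examples, bilingual (Spanish/English)
#' surface variants and abbreviations, adherence phrase triggers, and
#' lifestyle-recommendation phrases. Its scope is deliberate: drugs outside it
#' (e.g. plain aspirin or prednisolone) are not extracted.
#'
#' @return A `lexicon`.
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "lexicon.json", package = "dmtransit"))
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("lexicon: %d surface forms, %d canonicals, %d categories, max n-gram %d\n",
              nrow(x$entries), length(unique(x$entries$canonical)),
              length(unique(x$entries$category)), x$max_ngram))
  invisible(x)
}

#' Canonical drug names of a class
#' @param lexicon A `lexicon`.
#' @param class Drug class, e.g. "hypoglycemic", "insulin".
#' @return Character vector of canonical drug names.
#' @export
drugs_of_class <- function(lexicon, class) {
  e <- lexicon$entries
  sort(unique(e$canonical[e$category == "drug" & !is.na(e$class) &
                            e$class == class]))
}

default_note_templates <- function() {
  jsonlite::fromJSON(system.file("extdata", "note_templates.json",
                                 package = "dmtransit"),
                     simplifyVector = TRUE)
}
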