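#' Normalise a clinical note into a token sequence
#'
#' Applies the fixed preprocessing chain: lowercase, URL removal, accent
#' folding, punctuation-to-space, digit removal (so dose strings like "20mg"
#' lose their numerals), whitespace tokenisation, removal of one-character
#' fragments and of stopwords. Negation tokens ("no", "not", "sin") are
#' deliberately not stopwords so that downstream adherence patterns can see
#' them. Token order is preserved.
#'
#' @param text A single character string (may be empty or `NA`).
#' @param lexicon A [read_lexicon()] object supplying the stopword list.
#' @return Character vector of normalised tokens (possibly empty).
#' @export
preprocess <- function(text, lexicon = default_lexicon()) {
  if (length(text) != 1) stopf("preprocess() takes a single note")
  if (is.na(text) || !nzchar(text)) return(character(0))
  x <- tolower(text)
  x <- gsub("(https?://|www\\.)[^[:space:]]+", " ", x)
  # locale-independent accent folding for the Spanish/Portuguese range
  x <- chartr("áéíóúüñàèìòùâêîôûç",
              "aeiouunaeiouaeiouc", x)
  x <- gsub("[^a-z0-9]+", " ", x)
  x <- gsub("[0-9]+", "", x)
  toks <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  toks <- toks[nchar(toks) >= 2]
  toks[!(toks %in% lexicon$stopwords)]
}

#' Dictionary-backed spelling correction of one token
#'
#' Returns the unique lexicon vocabulary word within Levenshtein distance 1 of
#' the token, the token itself if it is already in the vocabulary (exact match
#' wins over any distance-1 neighbour), and the token unchanged when there is
#' no candidate or the candidate is ambiguous (two words at distance 1).
#' Tokens shorter than four characters are never corrected: short tokens are
#' mostly abbreviations, for which a one-character edit is a different word.
#'
#' @param token A single token.
#' @param lexicon A `lexicon`.
#' @return The corrected (or unchanged) token.
#' @export
correct_spelling <- function(token, lexicon = default_lexicon()) {
  correct_tokens(token, lexicon)
}

#' Vectorised spelling correction
#' @param tokens Character vector of normalised tokens.
#' @param lexicon A `lexicon`.
#' @return Character vector of the same length.
#' @export
correct_tokens <- function(tokens, lexicon = default_lexicon()) {
  if (length(tokens) == 0) return(character(0))
  vocab <- lexicon$word_vocab
  out <- tokens
  needs <- !(tokens %in% vocab) & nchar(tokens) >= 4
  for (i in which(needs)) {
    tk <- tokens[i]
    cand <- vocab[abs(nchar(vocab) - nchar(tk)) <= 1]
    if (length(cand) == 0) next
    d <- utils::adist(tk, cand)
    hit <- cand[d == 1]
    if (length(hit) == 1) out[i] <- hit
  }
  out
}

#' Greedy longest-match entity search
#'
#' Scans the token sequence left to right; at each position the longest
#' n-gram (n <= `max_ngram`) that is a lexicon surface form is taken as a
#' match, the scan resumes after it, and matches never overlap. Multi-word
#' entities (combination products, "metoprolol succinate") therefore win over
#' their single-word prefixes.
#'
#' @param tokens Normalised (and optionally spelling-corrected) tokens.
#' @param lexicon A `lexicon`.
#' @return Data frame of matched spans: `start`, `end` (token indices),
#'   `surface`, `canonical`, `category`.
#' @export
simple_search <- function(tokens, lexicon = default_lexicon()) {
  n <- length(tokens)
  empty <- data.frame(start = integer(0), end = integer(0),
                      surface = character(0), canonical = character(0),
                      category = character(0), stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  idx <- lexicon$surface_index
  ent <- lexicon$entries
  starts <- integer(0); ends <- integer(0); hits <- integer(0)
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (len in seq(min(lexicon$max_ngram, n - i + 1L), 1L)) {
      gram <- paste(tokens[i:(i + len - 1L)], collapse = " ")
      j <- idx[gram]
      if (!is.na(j)) {
        starts <- c(starts, i); ends <- c(ends, i + len - 1L)
        hits <- c(hits, j)
        i <- i + len
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  if (length(hits) == 0) return(empty)
  data.frame(start = starts, end = ends,
             surface = ent$surface[hits], canonical = ent$canonical[hits],
             category = ent$category[hits], stringsAsFactors = FALSE)
}

#' Bag-of-words vector over the lexicon vocabulary
#'
#' Counts non-overlapping entity matches per canonical lexicon entity. The
#' vector is indexed by the sorted canonical vocabulary, so repeated mentions
#' accumulate and the total count can never exceed the token count.
#'
#' @param tokens Normalised tokens.
#' @param lexicon A `lexicon`.
#' @return Named integer vector over all canonical entities.
#' @export
bow_vector <- function(tokens, lexicon = default_lexicon()) {
  vocab <- sort(unique(lexicon$entries$canonical))
  counts <- stats::setNames(integer(length(vocab)), vocab)
  spans <- simple_search(tokens, lexicon)
  if (nrow(spans) > 0) {
    tb <- table(spans$canonical)
    counts[names(tb)] <- as.integer(tb)
  }
  counts
}

## is any negator within `window` tokens of span [start, end]?
span_negated <- function(tokens, start, end, negators, window = 4L) {
  lo <- max(1L, start - window); hi <- min(length(tokens), end + window)
  ctx <- tokens[setdiff(lo:hi, start:end)]
  any(ctx %in% negators)
}

#' Rule-based pharmacological-adherence classification
#'
#' Negative adherence patterns (e.g. "no adherencia", a physician's special
#' emphasis on adhering to treatment) that fire un-negated classify the note
#' as `non_compliant`; otherwise an un-negated positive pattern yields
#' `compliant`; with no adherence span at all the note is `unstated`.
#' Negative patterns take precedence. A pattern is negated when one of its
#' negator tokens occurs within four tokens of the matched span.
#'
#' @param tokens Normalised tokens.
#' @param spans Matched spans from [simple_search()] (recomputed if `NULL`).
#' @param lexicon A `lexicon` (supplies patterns via its adherence entries and
#'   negator lists).
#' @return One of `"compliant"`, `"non_compliant"`, `"unstated"`.
#' @export
classify_adherence <- function(tokens, spans = NULL, lexicon = default_lexicon()) {
  if (is.null(spans)) spans <- simple_search(tokens, lexicon)
  neg <- spans[spans$category == "adherence_negative", , drop = FALSE]
  pos <- spans[spans$category == "adherence_positive", , drop = FALSE]
  for (k in seq_len(nrow(neg))) {
    if (!span_negated(tokens, neg$start[k], neg$end[k], lexicon$negators))
      return("non_compliant")
  }
  for (k in seq_len(nrow(pos))) {
    if (!span_negated(tokens, pos$start[k], pos$end[k], lexicon$positive_negators))
      return("compliant")
  }
  "unstated"
}

#' End-to-end extraction from one clinical note
#'
#' Composes preprocessing, spelling correction, greedy entity search and
#' adherence classification into the structured extraction result for a note.
#'
#' @param note Raw note text.
#' @param lexicon A `lexicon`.
#' @param correct Apply dictionary spelling correction (default TRUE).
#' @return An object of class `extraction_result`: `conditions` and `drugs`
#'   (character sets of canonicals), `adherence`, `recommendations` (named
#'   logical: nutrition, physical, alcohol, tobacco), `guideline_marker`
#'   (logical), `matched_spans` (audit data frame), `tokens`.
#' @export
extract_record <- function(note, lexicon = default_lexicon(), correct = TRUE) {
  tokens <- preprocess(note, lexicon)
  if (correct) tokens <- correct_tokens(tokens, lexicon)
  spans <- simple_search(tokens, lexicon)
  rec_cats <- c(nutrition = "recommendation_nutrition",
                physical = "recommendation_physical",
                alcohol = "recommendation_alcohol",
                tobacco = "recommendation_tobacco")
  recs <- vapply(rec_cats, function(cc) any(spans$category == cc), logical(1))
  structure(list(
    conditions = sort(unique(spans$canonical[spans$category == "condition"])),
    drugs = sort(unique(spans$canonical[spans$category == "drug"])),
    adherence = classify_adherence(tokens, spans, lexicon),
    recommendations = recs,
    guideline_marker = any(spans$category == "guideline_marker"),
    matched_spans = spans,
    tokens = tokens
  ), class = "extraction_result")
}

#' @export
print.extraction_result <- function(x, ...) {
  cat("conditions:", if (length(x$conditions)) paste(x$conditions, collapse = ", ") else "-", "\n")
  cat("drugs:     ", if (length(x$drugs)) paste(x$drugs, collapse = ", ") else "-", "\n")
  cat("adherence: ", x$adherence, "\n")
  cat("recommend.:", paste(names(x$recommendations)[x$recommendations], collapse = ", "), "\n")
  invisible(x)
}

#' Merge NLP-extracted values into a structured cohort row
#'
#' Entity fields (drugs, conditions) take the union of the structured and
#' extracted values; scalar flags keep the structured value whenever one is
#' present and fall back to the extracted value otherwise. Disagreements on
#' scalar flags are kept on the structured side and reported as conflicts.
#'
#' @param row One-row data frame with (at least) `drugs_structured`; optional
#'   `conditions_structured`, `patient_compliance`, `rec_nutrition`,
#'   `rec_physical`, `rec_alcohol`, `rec_tobacco`.
#' @param extraction An `extraction_result`.
#' @return List with `row` (completed row, semicolon-packed `drugs` and
#'   `conditions` columns), `provenance` (character vector of fields filled
#'   from the note) and `conflicts` (data frame of field, structured,
#'   extracted).
#' @export
merge_structured <- function(row, extraction) {
  if (!is.data.frame(row) || nrow(row) != 1)
    stopf("merge_structured expects a one-row data frame")
  if (!"drugs_structured" %in% names(row))
    stopf("row schema invalid: missing 'drugs_structured'")
  prov <- character(0)
  conflicts <- data.frame(field = character(0), structured = character(0),
                          extracted = character(0), stringsAsFactors = FALSE)
  sdrugs <- unpack_list(row$drugs_structured)[[1]]
  merged_drugs <- sort(union(sdrugs, extraction$drugs))
  if (length(setdiff(extraction$drugs, sdrugs)) > 0) prov <- c(prov, "drugs")
  row$drugs <- pack_list(list(merged_drugs))
  sconds <- if ("conditions_structured" %in% names(row))
    unpack_list(row$conditions_structured)[[1]] else character(0)
  merged_conds <- sort(union(sconds, extraction$conditions))
  if (length(setdiff(extraction$conditions, sconds)) > 0)
    prov <- c(prov, "conditions")
  row$conditions <- pack_list(list(merged_conds))

  ext_compliance <- switch(extraction$adherence,
                           compliant = TRUE, non_compliant = FALSE, NA)
  if (!"patient_compliance" %in% names(row)) row$patient_compliance <- NA
  if (is.na(row$patient_compliance)) {
    if (!is.na(ext_compliance)) {
      row$patient_compliance <- ext_compliance
      prov <- c(prov, "patient_compliance")
    }
  } else if (!is.na(ext_compliance) &&
             row$patient_compliance != ext_compliance) {
    conflicts <- rbind(conflicts, data.frame(
      field = "patient_compliance",
      structured = as.character(row$patient_compliance),
      extracted = as.character(ext_compliance), stringsAsFactors = FALSE))
  }
  for (f in c("nutrition", "physical", "alcohol", "tobacco")) {
    col <- paste0("rec_", f)
    if (!col %in% names(row)) row[[col]] <- NA
    if (is.na(row[[col]])) {
      row[[col]] <- unname(extraction$recommendations[f])
      prov <- c(prov, col)
    } else if (row[[col]] != extraction$recommendations[f]) {
      conflicts <- rbind(conflicts, data.frame(
        field = col, structured = as.character(row[[col]]),
        extracted = as.character(extraction$recommendations[f]),
        stringsAsFactors = FALSE))
    }
  }
  list(row = row, provenance = prov, conflicts = conflicts)
}

prf <- function(tp, fp, fn) {
  undef <- (tp + fp) == 0
  precision <- if (undef) 0 else tp / (tp + fp)
  recall <- if ((tp + fn) == 0) 1 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  c(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
    f1 = f1, precision_undefined = as.numeric(undef))
}

#' Extraction quality against generator ground truth
#'
#' Micro-averaged precision/recall/F1 per category, comparing a list of
#' extraction results with the ground-truth annotations emitted by the
#' synthetic generator. An undefined precision (nothing retrieved) is
#' reported as 0 and flagged.
#'
#' @param results Named list of `extraction_result`s, names `patient_id:year`.
#' @param truth Ground-truth data frame from [generate_cohort()].
#' @return Data frame with one row per category.
#' @export
evaluate_extraction <- function(results, truth) {
  keys <- paste(truth$patient_id, truth$year, sep = ":")
  missing <- setdiff(keys, names(results))
  if (length(missing) > 0)
    stopf("results missing for %d patient-years (first: %s)",
          length(missing), missing[1])
  acc <- list(drug = c(0, 0, 0), condition = c(0, 0, 0), adherence = c(0, 0, 0),
              nutrition = c(0, 0, 0), physical = c(0, 0, 0),
              alcohol = c(0, 0, 0), tobacco = c(0, 0, 0))
  tdrugs <- unpack_list(truth$drugs)
  tconds <- unpack_list(truth$conditions)
  for (i in seq_along(keys)) {
    r <- results[[keys[i]]]
    for (spec in list(list("drug", r$drugs, tdrugs[[i]]),
                      list("condition", r$conditions, tconds[[i]]))) {
      tp <- length(intersect(spec[[2]], spec[[3]]))
      acc[[spec[[1]]]] <- acc[[spec[[1]]]] +
        c(tp, length(spec[[2]]) - tp, length(spec[[3]]) - tp)
    }
    pa <- r$adherence; ta <- truth$adherence[i]
    acc$adherence <- acc$adherence + c(
      as.numeric(pa != "unstated" && pa == ta),
      as.numeric(pa != "unstated" && pa != ta),
      as.numeric(ta != "unstated" && pa != ta))
    for (f in c("nutrition", "physical", "alcohol", "tobacco")) {
      pv <- isTRUE(unname(r$recommendations[f]))
      tv <- isTRUE(truth[[paste0("rec_", f)]][i])
      acc[[f]] <- acc[[f]] + c(pv && tv, pv && !tv, !pv && tv)
    }
  }
  out <- do.call(rbind, lapply(names(acc), function(cat) {
    v <- acc[[cat]]
    data.frame(category = cat, t(prf(v[1], v[2], v[3])),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
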