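# Brute-force reference implementations, kept deliberately independent of the
# package's algorithms, plus the two printed example notes used throughout.

note_81719 <- paste(
  "67 YEAR OLD PATIENT WITH HBP ON HANDLING WITH INSULIN GLARGINE 52 UNITS",
  "AT NIGHT ASPART 12-12-12 ASA 100X1 OMEPRAZOLE 20X1 PREDNISOLONE 5X1",
  "TESTOSTERONE 250 MG MONTH LOSARTAN+HYDROCHLOROTHIAZIDE 50+12.5X2",
  "ROSUVASTATIN 20X1 IMMUNOSUPPRESSANTS CARBAMAZEPINE 200X1 CLOPIDOGREL 75X1",
  "MYCOPHENOLATE 360MGX3 METOPROLOL SUCCINATE 50X1",
  "Empagliflozin+Metformin 12.5mg/850mg Tab 1 e/12h")

note_10015 <- paste(
  "Seventy-year-old patient with type II diabetes diagnostic. HbA1c on",
  "target, hypertension is not controlled due to a decrease in the enalapril",
  "dose. Special emphasis on adhering to the pharmacological treatment and on",
  "sticking to a healthy diet. General recommendations of a healthy",
  "lifestyle. Next appointment should be scheduled within 3 months.")

drugs_81719 <- sort(c(
  "insulin glargine", "insulin aspart", "omeprazole", "testosterone",
  "losartan+hydrochlorothiazide", "rosuvastatin", "carbamazepine",
  "clopidogrel", "mycophenolate", "metoprolol succinate",
  "empagliflozin+metformin"))

# exhaustive-threshold kappa cutoff: independent kappa via 2x2 table
bf_kappa <- function(labels, pred) {
  n <- length(labels)
  a <- sum(labels == 1 & pred == 1); b <- sum(labels == 0 & pred == 1)
  c2 <- sum(labels == 1 & pred == 0); d <- sum(labels == 0 & pred == 0)
  po <- (a + d) / n
  pe <- ((a + b) / n) * ((a + c2) / n) + ((c2 + d) / n) * ((b + d) / n)
  if (abs(1 - pe) < 1e-12) 0 else (po - pe) / (1 - pe)
}

bf_kappa_cutoff <- function(labels, prob) {
  d <- sort(unique(prob))
  cuts <- sort(unique(c(0, 1, if (length(d) > 1) (d[-1] + d[-length(d)]) / 2)))
  best_cut <- NA; best_k <- -Inf
  for (cc in cuts) {
    k <- bf_kappa(labels, as.integer(prob >= cc))
    if (k > best_k + 1e-12) { best_k <- k; best_cut <- cc }
  }
  list(cutoff = best_cut, kappa = best_k)
}

bf_transition_counts <- function(from, to) {
  s <- stage_levels()
  m <- matrix(0L, 4, 4, dimnames = list(s, s))
  for (i in seq_along(from)) {
    m[from[i], to[i]] <- m[from[i], to[i]] + 1L
  }
  m
}

bf_crosstab_counts <- function(ideal, actual) {
  cls <- c("metformin", "combined", "insulin")
  m <- matrix(0L, 3, 3, dimnames = list(cls, cls))
  for (i in seq_along(ideal)) m[ideal[i], actual[i]] <- m[ideal[i], actual[i]] + 1L
  m
}

# maximal non-overlapping leftmost-longest lexicon matches by explicit
# candidate enumeration
bf_simple_search <- function(tokens, lexicon) {
  surf <- lexicon$entries$surface
  cand <- list()
  for (i in seq_along(tokens)) {
    for (len in seq_len(min(lexicon$max_ngram, length(tokens) - i + 1))) {
      gram <- paste(tokens[i:(i + len - 1)], collapse = " ")
      if (gram %in% surf) cand[[length(cand) + 1]] <- c(i, i + len - 1)
    }
  }
  taken <- logical(length(tokens))
  picked <- list()
  repeat {
    avail <- Filter(function(sp) !any(taken[sp[1]:sp[2]]), cand)
    if (length(avail) == 0) break
    starts <- vapply(avail, `[`, numeric(1), 1)
    lens <- vapply(avail, function(sp) sp[2] - sp[1] + 1, numeric(1))
    sel <- which(starts == min(starts))
    sel <- sel[which.max(lens[sel])]
    sp <- avail[[sel]]
    picked[[length(picked) + 1]] <- sp
    taken[sp[1]:sp[2]] <- TRUE
    # discard anything overlapping or to the left of the pick
    cand <- Filter(function(z) z[1] > sp[2], cand)
  }
  do.call(rbind, picked)
}

# small deterministic staged cohort for hand-traced tests
hand_staged_cohort <- function() {
  # 6 patients x 3 years; stages chosen to exercise every matrix row
  stages <- rbind(
    c("ON-NOT", "ON-NOT", "ON-YES"),
    c("ON-NOT", "OUT-NOT", "OUT-YES"),
    c("OUT-NOT", "OUT-NOT", "OUT-NOT"),
    c("OUT-NOT", "ON-YES", "ON-YES"),
    c("ON-YES", "OUT-YES", "OUT-YES"),
    c("OUT-YES", "ON-YES", "ON-YES"))
  data.frame(
    patient_id = rep(1:6, each = 3),
    year = rep(2018:2020, times = 6),
    stage = as.character(t(stages)),
    stringsAsFactors = FALSE)
}

random_tokens <- function(n, lexicon) {
  words <- unique(unlist(strsplit(lexicon$entries$surface, " ")))
  fillers <- c("zz", "qq", "paciente", "control", "estable", "refiere")
  sample(c(words, fillers), n, replace = TRUE)
}
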