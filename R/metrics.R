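#' Rank-based AUC (Mann-Whitney, mid-rank ties)
#'
#' @param labels Binary 0/1 vector.
#' @param prob Predicted probabilities (any monotone score works; AUC is
#'   invariant under strictly increasing transforms).
#' @return AUC in `[0,1]`, or `NA` when only one class is present.
#' @export
auc_rank <- function(labels, prob) {
  stopifnot(length(labels) == length(prob))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(prob)  # average ranks for ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cohen's kappa for binary predictions
#' @param labels,pred Binary 0/1 vectors.
#' @return Kappa; 0 when the chance-agreement term degenerates.
#' @export
cohen_kappa <- function(labels, pred) {
  n <- length(labels)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  if (abs(1 - pe) < 1e-12) return(0)
  (po - pe) / (1 - pe)
}

#' Kappa-maximising probability cutoff
#'
#' Evaluates Cohen's kappa of the classification rule `prob >= cutoff` at
#' every midpoint between adjacent distinct sorted probabilities, plus the
#' endpoints 0 and 1, and returns the maximising cutoff (ties broken toward
#' the smallest cutoff). This is the rule used to convert the transition
#' models' predicted probabilities into binary predictions for the confusion
#' matrices.
#'
#' @param labels Binary 0/1 vector (both classes must be present).
#' @param prob Predicted probabilities in `[0,1]`.
#' @return The cutoff; attribute `"kappa"` carries the achieved kappa.
#' @export
kappa_optimal_cutoff <- function(labels, prob) {
  if (length(unique(labels)) < 2)
    stopf("kappa_optimal_cutoff: both classes must be present")
  d <- sort(unique(prob))
  cuts <- unique(c(0, if (length(d) > 1) (d[-1] + d[-length(d)]) / 2, 1))
  # cumulative counts below each candidate cutoff -> O(n log n) total
  n <- length(labels)
  npos <- sum(labels == 1); nneg <- n - npos
  kap <- vapply(cuts, function(cc) {
    predpos <- prob >= cc
    tp <- sum(predpos & labels == 1); fp <- sum(predpos & labels == 0)
    fn <- npos - tp; tn <- nneg - fp
    po <- (tp + tn) / n
    pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
    if (abs(1 - pe) < 1e-12) 0 else (po - pe) / (1 - pe)
  }, numeric(1))
  best <- which(kap >= max(kap) - 1e-12)[1]  # smallest cutoff among ties
  structure(cuts[best], kappa = kap[best])
}

#' Binary classification metrics at a cutoff
#'
#' Accuracy, F1 of the positive (event) class, rank AUC (cutoff-free), and
#' the four confusion rates. TPR+FNR and TNR+FPR each sum to 1 exactly.
#'
#' @param labels Binary 0/1 vector.
#' @param prob Probabilities in `[0,1]`.
#' @param cutoff Classification cutoff; prediction is `prob >= cutoff`.
#' @return Named list: accuracy, f1, auc (`NA` + `auc_undefined=TRUE` when a
#'   single class is present), tpr, fpr, tnr, fnr, cutoff.
#' @export
classification_metrics <- function(labels, prob, cutoff = 0.5) {
  stopifnot(all(labels %in% c(0, 1)), all(prob >= 0 & prob <= 1))
  pred <- as.integer(prob >= cutoff)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  auc <- auc_rank(labels, prob)
  list(
    accuracy = (tp + tn) / length(labels),
    f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec),
    auc = auc, auc_undefined = is.na(auc),
    tpr = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    fnr = if (tp + fn == 0) NA_real_ else fn / (tp + fn),
    tnr = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
    fpr = if (tn + fp == 0) NA_real_ else fp / (tn + fp),
    cutoff = cutoff
  )
}
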