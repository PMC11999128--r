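#' Variance, collinearity and importance feature selection
#'
#' Three sequential filters: (1) drop columns with variance below
#' `var_threshold`; (2) for each pair with absolute Pearson correlation above
#' `cor_threshold`, drop the later column (deterministic in column order);
#' (3) when more than `top_k` columns remain, keep the `top_k` most important
#' by gain in a small boosted-tree model fit to the outcome.
#'
#' @param x Numeric feature data frame.
#' @param y Binary outcome (needed only when `top_k` is finite).
#' @param var_threshold Minimum variance.
#' @param cor_threshold Maximum tolerated absolute pairwise correlation.
#' @param top_k Number of columns to keep after the importance ranking.
#' @param seed RNG seed for the importance model.
#' @return List with `x` (reduced data frame) and `kept` (column names).
#' @export
select_features <- function(x, y = NULL, var_threshold = 1e-8,
                            cor_threshold = 0.95, top_k = Inf, seed = 1L) {
  if (ncol(x) < 2) stopf("select_features needs at least 2 columns")
  v <- vapply(x, stats::var, numeric(1))
  keep <- names(x)[!is.na(v) & v > var_threshold]
  if (length(keep) == 0) stopf("all columns dropped by the variance filter")
  x <- x[, keep, drop = FALSE]
  if (ncol(x) > 1) {
    cm <- abs(stats::cor(x))
    drop <- logical(ncol(x))
    for (j in seq_len(ncol(x))[-1]) {
      if (any(cm[seq_len(j - 1), j] > cor_threshold & !drop[seq_len(j - 1)]))
        drop[j] <- TRUE
    }
    x <- x[, !drop, drop = FALSE]
  }
  if (is.finite(top_k) && ncol(x) > top_k) {
    if (is.null(y)) stopf("top_k selection requires the outcome y")
    set.seed(seed)
    bst <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3, eta = 0.3,
                    nthread = 1),
      data = xgboost::xgb.DMatrix(as.matrix(x), label = y),
      nrounds = 50, verbose = 0)
    imp <- xgboost::xgb.importance(model = bst)
    ranked <- c(imp$Feature, setdiff(names(x), imp$Feature))
    x <- x[, ranked[seq_len(top_k)], drop = FALSE]
  }
  if (ncol(x) == 0) stopf("all columns dropped")
  list(x = x, kept = names(x))
}

smote_points <- function(xmin, n_new, k) {
  n <- nrow(xmin)
  if (n < k + 1)
    stopf("minority class has %d points, need > k_neighbors = %d; use a smaller k",
          n, k)
  sc <- scale(xmin)
  sc[, attr(sc, "scaled:scale") == 0] <- 0
  dd <- as.matrix(stats::dist(sc))
  diag(dd) <- Inf
  nn <- t(apply(dd, 1, function(r) order(r)[seq_len(k)]))
  i <- sample.int(n, n_new, replace = TRUE)
  j <- nn[cbind(i, sample.int(k, n_new, replace = TRUE))]
  u <- stats::runif(n_new)
  as.data.frame(as.matrix(xmin[i, , drop = FALSE]) +
                  u * (as.matrix(xmin[j, , drop = FALSE]) -
                         as.matrix(xmin[i, , drop = FALSE])))
}

#' SMOTE-style class rebalancing
#'
#' Synthetic minority oversampling: new minority points are convex
#' combinations of a minority point and one of its k nearest minority
#' neighbours, so every synthetic point lies on a segment between two real
#' minority points. Two strategies: `"upsample"` raises the minority count to
#' the majority count (majority untouched); `"up_down"` moves both classes to
#' an intermediate target size (default the mean of the two class sizes),
#' downsampling the majority without replacement. Apply to training folds
#' only — never to a test split.
#'
#' @param x Numeric feature data frame.
#' @param y Binary 0/1 labels (both classes present).
#' @param strategy `"none"`, `"upsample"` or `"up_down"`.
#' @param k Number of minority neighbours.
#' @param target_size Intermediate class size for `"up_down"`.
#' @return List with rebalanced `x`, `y`.
#' @export
resample_classes <- function(x, y, strategy = c("none", "upsample", "up_down"),
                             k = 5, target_size = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "none") return(list(x = x, y = y))
  tb <- table(factor(y, levels = c(0, 1)))
  if (any(tb == 0)) stopf("resample_classes: both classes must be present")
  min_cls <- as.integer(names(tb)[which.min(tb)])
  maj_cls <- 1L - min_cls
  xmin <- x[y == min_cls, , drop = FALSE]
  xmaj <- x[y == maj_cls, , drop = FALSE]
  if (strategy == "upsample") {
    n_new <- nrow(xmaj) - nrow(xmin)
    if (n_new <= 0) return(list(x = x, y = y))
    syn <- smote_points(xmin, n_new, k)
    names(syn) <- names(x)
    list(x = rbind(x, syn), y = c(y, rep(min_cls, n_new)))
  } else {
    target <- target_size %||% round((nrow(xmin) + nrow(xmaj)) / 2)
    n_new <- target - nrow(xmin)
    syn <- if (n_new > 0) smote_points(xmin, n_new, k) else NULL
    if (!is.null(syn)) names(syn) <- names(x)
    xmin2 <- rbind(xmin, syn)
    keep_maj <- sample.int(nrow(xmaj), min(target, nrow(xmaj)))
    xmaj2 <- xmaj[keep_maj, , drop = FALSE]
    list(x = rbind(xmin2, xmaj2),
         y = c(rep(min_cls, nrow(xmin2)), rep(maj_cls, nrow(xmaj2))))
  }
}
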