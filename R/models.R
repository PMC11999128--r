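## Learner registry: every family exposes fit(x, y, params) -> model and a
## shared probability predictor via predict_prob(). Families wrap established
## implementations; the nested-task layer, selection logic, cutoffs and
## marginal effects live in this package.

default_grids <- function() {
  list(
    logistic    = list(list()),
    knn         = list(list(k = 5), list(k = 15), list(k = 31)),
    tree        = list(list(maxdepth = 3), list(maxdepth = 5), list(maxdepth = 10)),
    rf          = list(list(ntree = 100)),
    extra_trees = list(list(num.trees = 100)),
    gboost      = list(list(nrounds = 50, max_depth = 3, eta = 0.3),
                       list(nrounds = 200, max_depth = 3, eta = 0.1)),
    mlp         = list(list(reg = 1e-4, lr = 1e-3, epochs = 20))
  )
}

fit_learner <- function(family, x, y, params, seed = 1L) {
  set.seed(seed)
  model <- switch(
    family,
    logistic = suppressWarnings(stats::glm(y ~ ., family = stats::binomial(),
                                           data = cbind(x, y = y))),
    knn = {
      ctr <- colMeans(x); scl <- vapply(x, stats::sd, numeric(1)); scl[scl == 0] <- 1
      list(x = scale(as.matrix(x), ctr, scl), y = factor(y, levels = c(0, 1)),
           k = params$k, center = ctr, scale = scl)
    },
    tree = rpart::rpart(y ~ ., data = cbind(x, y = factor(y, levels = c(0, 1))),
                        method = "class",
                        control = rpart::rpart.control(
                          maxdepth = params$maxdepth, cp = 0.001, xval = 0)),
    rf = randomForest::randomForest(x = x, y = factor(y, levels = c(0, 1)),
                                    ntree = params$ntree %||% 100),
    extra_trees = ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                                 num.trees = params$num.trees %||% 100,
                                 splitrule = "extratrees", probability = TRUE,
                                 num.threads = 1, seed = seed),
    gboost = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth %||% 3,
                    eta = params$eta %||% 0.3, nthread = 1),
      data = xgboost::xgb.DMatrix(as.matrix(x), label = y),
      nrounds = params$nrounds %||% 50, verbose = 0),
    mlp = train_feedforward(x, y, grid = list(params), seed = seed),
    stopf("unknown learner family '%s'", family)
  )
  structure(list(family = family, model = model, params = params,
                 features = names(x)),
            class = "dmt_learner")
}

#' Predicted event probabilities of a fitted learner
#'
#' @param fit A `dmt_learner` from the training layer.
#' @param x Feature data frame (superset of the training features).
#' @return Numeric vector of probabilities of the positive class.
#' @export
predict_prob <- function(fit, x) {
  x <- x[, fit$features, drop = FALSE]
  p <- switch(
    fit$family,
    logistic = suppressWarnings(stats::predict(fit$model, newdata = x,
                                               type = "response")),
    knn = {
      m <- fit$model
      xt <- scale(as.matrix(x), m$center, m$scale)
      pr <- class::knn(m$x, xt, m$y, k = m$k, prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "1", win, 1 - win)
    },
    tree = stats::predict(fit$model, newdata = x, type = "prob")[, "1"],
    rf = stats::predict(fit$model, newdata = x, type = "prob")[, "1"],
    extra_trees = stats::predict(fit$model, data = x,
                                 num.threads = 1)$predictions[, "1"],
    gboost = stats::predict(fit$model, xgboost::xgb.DMatrix(as.matrix(x))),
    mlp = stats::predict(fit$model, x),
    constant = rep(fit$model, nrow(x)),  # fixed-probability stub, for testing
    stopf("unknown learner family '%s'", fit$family)
  )
  as.numeric(pmin(pmax(p, 0), 1))
}

#' Training configuration for the transition models
#'
#' @param families Learner families to compare. The default covers the model
#'   grid minus the network, which is expensive to cross-validate and can be
#'   added explicitly (`families = c(train_config()$families, "mlp")`).
#' @param grids Named list of per-family hyperparameter grids (lists of
#'   parameter lists); defaults per [default_grids()].
#' @param cv_folds Stratified cross-validation folds (default 10).
#' @param resampling `"none"` (default), `"upsample"` or `"up_down"`; applied
#'   to training folds only.
#' @param test_fraction Held-out stratified test fraction (default 0.2).
#' @param top_k Feature-selection budget passed to [select_features()].
#' @param seed RNG seed controlling the split, folds and every fit.
#' @return An object of class `train_config`.
#' @export
train_config <- function(families = c("logistic", "knn", "tree", "rf",
                                      "extra_trees", "gboost"),
                         grids = default_grids(), cv_folds = 10L,
                         resampling = "none", test_fraction = 0.2,
                         top_k = Inf, seed = 1L) {
  stopifnot(all(families %in% names(grids)))
  structure(list(families = families, grids = grids,
                 cv_folds = as.integer(cv_folds), resampling = resampling,
                 test_fraction = test_fraction, top_k = top_k,
                 seed = as.integer(seed)),
            class = "train_config")
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    ix <- sample(which(y == cls))
    fold[ix] <- rep_len(seq_len(k), length(ix))
  }
  fold
}

#' Cross-validated model selection for one prediction task
#'
#' Stratified 80/20 train/test split, feature selection on the training side,
#' stratified k-fold cross-validation of every (family, hyperparameter)
#' candidate with optional SMOTE resampling of the training folds, selection
#' by mean fold F1 (ties broken by AUC, then accuracy, then candidate order),
#' refit of the winner on the full training split, kappa-optimal cutoff
#' chosen on the training predictions, and held-out test metrics at that
#' cutoff.
#'
#' @param x Numeric feature data frame.
#' @param y Binary 0/1 labels.
#' @param config A [train_config()].
#' @param task Optional task row carried into the result.
#' @return An object of class `fit_result`: `cv_table`, `family`, `params`,
#'   `fit`, `cutoff`, `metrics_train`, `metrics_test`, `marginal_effects`,
#'   `features`.
#' @export
train_and_select <- function(x, y, config = train_config(), task = NULL) {
  if (nrow(x) == 0) stopf("empty dataset")
  if (length(unique(y)) < 2) stopf("training labels are single-class")
  set.seed(config$seed)
  test_ix <- unlist(lapply(split(seq_along(y), y), function(ix)
    sample(ix, max(1, round(config$test_fraction * length(ix))))))
  xtr <- x[-test_ix, , drop = FALSE]; ytr <- y[-test_ix]
  xte <- x[test_ix, , drop = FALSE]; yte <- y[test_ix]
  if (length(unique(ytr)) < 2) stopf("training split is single-class")
  sel <- select_features(xtr, ytr, top_k = config$top_k, seed = config$seed)
  xtr <- sel$x; xte <- xte[, sel$kept, drop = FALSE]

  folds <- stratified_folds(ytr, config$cv_folds)
  cand <- list()
  for (fam in config$families) {
    for (par in config$grids[[fam]]) cand[[length(cand) + 1]] <-
        list(family = fam, params = par)
  }
  cv <- lapply(seq_along(cand), function(ci) {
    cc <- cand[[ci]]
    f1 <- auc <- acc <- numeric(0)
    for (kf in seq_len(config$cv_folds)) {
      tr <- folds != kf
      if (length(unique(ytr[tr])) < 2 || sum(!tr) == 0) next
      xf <- xtr[tr, , drop = FALSE]; yf <- ytr[tr]
      set.seed(config$seed + 1000L * ci + kf)
      rs <- resample_classes(xf, yf, config$resampling)
      fit <- fit_learner(cc$family, rs$x, rs$y, cc$params,
                         seed = config$seed + 1000L * ci + kf)
      p <- predict_prob(fit, xtr[!tr, , drop = FALSE])
      m <- classification_metrics(ytr[!tr], p)
      f1 <- c(f1, m$f1); auc <- c(auc, ifelse(is.na(m$auc), 0.5, m$auc))
      acc <- c(acc, m$accuracy)
    }
    data.frame(family = cc$family,
               params = paste(names(cc$params), unlist(cc$params),
                              sep = "=", collapse = ","),
               f1 = mean(f1), auc = mean(auc), accuracy = mean(acc),
               stringsAsFactors = FALSE)
  })
  cv_table <- do.call(rbind, cv)
  ord <- order(-cv_table$f1, -cv_table$auc, -cv_table$accuracy,
               seq_len(nrow(cv_table)))
  best <- cand[[ord[1]]]

  set.seed(config$seed)
  rs <- resample_classes(xtr, ytr, config$resampling)
  fit <- fit_learner(best$family, rs$x, rs$y, best$params, seed = config$seed)
  p_tr <- predict_prob(fit, xtr)
  cutoff <- as.numeric(kappa_optimal_cutoff(ytr, p_tr))
  p_te <- predict_prob(fit, xte)
  me <- marginal_effects(fit, xtr)
  structure(list(task = task, cv_table = cv_table, family = best$family,
                 params = best$params, fit = fit, cutoff = cutoff,
                 metrics_train = classification_metrics(ytr, p_tr, cutoff),
                 metrics_test = classification_metrics(yte, p_te, cutoff),
                 marginal_effects = me, features = sel$kept,
                 n_train = nrow(xtr), n_test = nrow(xte),
                 test_index = sort(test_ix), test_labels = yte),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (!is.null(x$task)) cat("task:", x$task$id, "\n")
  cat(sprintf("selected: %s (%s); cutoff %.3f\n", x$family,
              paste(names(x$params), unlist(x$params), sep = "=", collapse = ","),
              x$cutoff))
  mt <- x$metrics_test
  cat(sprintf("test: accuracy %.3f, F1 %.3f, AUC %s\n", mt$accuracy, mt$f1,
              ifelse(is.na(mt$auc), "NA", sprintf("%.3f", mt$auc))))
  invisible(x)
}
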