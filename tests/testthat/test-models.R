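test_that("the nested decomposition yields exactly the twelve tasks", {
  tasks <- build_tasks()
  expect_equal(nrow(tasks), 12)
  for (h in 1:2) {
    th <- tasks[tasks$horizon == h, ]
    expect_equal(sum(th$outcome == "out_goal"), 4)
    expect_equal(sum(th$outcome == "complication"), 2)
    expect_false(any(th$outcome == "complication" &
                       th$initial_stage %in% c("ON-YES", "OUT-YES")))
  }
})

test_that("task datasets carry hand-traceable labels and no horizon leakage", {
  staged <- hand_staged_cohort()
  # add minimal features
  n <- nrow(staged)
  staged$age <- 60; staged$sex <- "F"; staged$ldl <- 90; staged$egfr <- 80
  staged$creatinine <- 1; staged$bmi <- 28; staged$weight <- 70
  staged$height <- 1.6; staged$dbp <- 75; staged$sbp <- 120
  staged$hba1c <- ifelse(staged$stage %in% c("ON-NOT", "ON-YES"), 6.5, 8.5)
  tasks <- build_tasks()
  t1 <- tasks[tasks$id == "1y_ON-NOT_goal", ]
  ds <- make_dataset(staged, t1)
  # pooled pairs: p1 2018->2019 (ON-NOT, 0), p1 2019->2020 (ON-YES: still on
  # goal, 0), p2 2018->2019 (OUT-NOT, 1)
  expect_equal(ds$y, c(0L, 0L, 1L))
  tc <- tasks[tasks$id == "2y_OUT-NOT_comp", ]
  dsc <- make_dataset(staged, tc)
  # patients 3 (OUT-NOT -> OUT-NOT: 0) and 4 (-> ON-YES: 1)
  expect_equal(sort(dsc$y), c(0L, 1L))
  expect_false(any(c("stage", "year", "goal_threshold") %in% names(ds$x)))
  empty_task <- data.frame(id = "x", horizon = 1, initial_stage = "ON-YES",
                           outcome = "out_goal")
  staged2 <- staged[staged$stage != "ON-YES", ]
  expect_error(make_dataset(staged2, empty_task), "ON-YES")
})

test_that("feature selection drops constants and duplicates, keeps signal", {
  set.seed(2)
  n <- 400
  x <- data.frame(signal = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n),
                  konst = 1)
  x$dup <- x$noise1
  y <- as.integer(stats::plogis(2 * x$signal) > runif(n))
  sel <- select_features(x, y)
  expect_false("konst" %in% sel$kept)
  expect_true(xor("noise1" %in% sel$kept, "dup" %in% sel$kept))
  # planted informative feature survives the importance ranking
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    x2 <- as.data.frame(matrix(rnorm(n * 6), n))
    names(x2) <- c("signal", paste0("n", 1:5))
    y2 <- as.integer(stats::plogis(2.5 * x2$signal) > runif(n))
    sel2 <- select_features(x2, y2, top_k = 3, seed = s)
    hits <- hits + ("signal" %in% sel2$kept)
  }
  expect_gte(hits, 9)
  expect_error(select_features(data.frame(a = 1, b = 1)[rep(1, 5), ], NULL),
               "variance")
})

test_that("SMOTE balancing hits the target sizes with convex synthetic points", {
  set.seed(7)
  n <- 1000
  x <- data.frame(a = rnorm(n), b = rnorm(n))
  x$c <- 2 * x$a   # exact linear relation survives convex combination
  y <- c(rep(1L, 100), rep(0L, 900))
  rs <- resample_classes(x, y, "upsample")
  expect_equal(as.numeric(table(rs$y)), c(900, 900))
  syn <- rs$x[-seq_len(n), ]
  expect_equal(syn$c, 2 * syn$a, tolerance = 1e-9)
  expect_true(all(syn$a >= min(x$a[y == 1]) & syn$a <= max(x$a[y == 1])))
  # balanced input is untouched by upsampling
  yb <- rep(c(0L, 1L), each = 50)
  rb <- resample_classes(x[1:100, ], yb, "upsample")
  expect_equal(length(rb$y), 100)
  # up+down moves both classes to the intermediate size
  rd <- resample_classes(x, y, "up_down")
  expect_equal(as.numeric(table(rd$y)), c(500, 500))
  expect_error(resample_classes(x[1:104, ], c(rep(1L, 4), rep(0L, 100)),
                                "upsample"), "smaller k")
})

test_that("kappa cutoff equals exhaustive brute force and handles edge cases", {
  # perfectly separated: smallest midpoint, kappa 1
  lab <- c(0, 0, 0, 1, 1)
  p <- c(0.1, 0.2, 0.3, 0.8, 0.9)
  cut <- kappa_optimal_cutoff(lab, p)
  expect_equal(as.numeric(cut), 0.55)
  expect_equal(attr(cut, "kappa"), 1)
  # 8-point hand example against brute force
  lab8 <- c(1, 0, 1, 1, 0, 0, 1, 0)
  p8 <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.35, 0.3, 0.1)
  bf <- bf_kappa_cutoff(lab8, p8)
  got <- kappa_optimal_cutoff(lab8, p8)
  expect_equal(as.numeric(got), bf$cutoff)
  expect_equal(attr(got, "kappa"), bf$kappa)
  # independence: max kappa near zero at large n
  set.seed(9)
  labr <- rbinom(2000, 1, 0.4); pr <- runif(2000)
  expect_lt(attr(kappa_optimal_cutoff(labr, pr), "kappa"), 0.1)
  expect_error(kappa_optimal_cutoff(rep(1, 5), runif(5)), "both classes")
})

test_that("classification metrics match the standard hand formulas", {
  perfect <- classification_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(perfect$accuracy, 1); expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1); expect_equal(perfect$tpr, 1)
  # TP=3 FP=1 FN=1 TN=5 at cutoff 0.5
  lab <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  p <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.1, 0.1, 0.1, 0.2, 0.3)
  m <- classification_metrics(lab, p)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$f1, 0.75)
  expect_equal(m$tpr + m$fnr, 1, tolerance = 1e-9)
  expect_equal(m$tnr + m$fpr, 1, tolerance = 1e-9)
  # all-equal probabilities: AUC 0.5 by the mid-rank convention
  expect_equal(auc_rank(c(0, 1, 0, 1), rep(0.4, 4)), 0.5)
  # AUC is invariant under strictly monotone transforms
  set.seed(12)
  labr <- rbinom(300, 1, 0.3); pr <- runif(300)
  expect_equal(auc_rank(labr, pr), auc_rank(labr, plogis(5 * pr - 2)))
  # against an established implementation
  expect_equal(auc_rank(labr, pr),
               as.numeric(pROC::auc(pROC::roc(labr, pr, quiet = TRUE))))
  # single-class labels: AUC flagged missing
  m1 <- classification_metrics(rep(1, 4), c(0.2, 0.6, 0.7, 0.9))
  expect_true(m1$auc_undefined)
})

test_that("model selection finds separable structure and is reproducible", {
  set.seed(30)
  n <- 300
  x <- data.frame(a = c(rnorm(n / 2, -3), rnorm(n / 2, 3)), b = rnorm(n))
  y <- rep(c(0L, 1L), each = n / 2)
  cfg <- train_config(families = c("logistic", "tree"), cv_folds = 5, seed = 99)
  fr <- train_and_select(x, y, cfg)
  expect_equal(fr$metrics_test$f1, 1)
  fr2 <- train_and_select(x, y, cfg)
  expect_identical(fr$metrics_test, fr2$metrics_test)
  expect_identical(fr$cv_table, fr2$cv_table)
  expect_error(train_and_select(x, rep(0L, n), cfg), "single-class")
})

test_that("a planted logistic mechanism keeps the logistic family competitive", {
  set.seed(41)
  n <- 600
  x <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- rbinom(n, 1, plogis(1.5 * x$a - 1 * x$b))
  fr <- train_and_select(x, y, train_config(
    families = c("logistic", "tree", "knn"), cv_folds = 5, seed = 7))
  cv <- fr$cv_table
  expect_lt(max(cv$f1) - cv$f1[cv$family == "logistic"], 0.05)
})

test_that("resampling never alters the held-out test split", {
  set.seed(55)
  n <- 500
  x <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, plogis(-1.5 + x$a))
  f_none <- train_and_select(x, y, train_config(families = "logistic",
                                                cv_folds = 5, seed = 3))
  f_up <- train_and_select(x, y, train_config(families = "logistic",
                                              cv_folds = 5, resampling = "upsample",
                                              seed = 3))
  expect_identical(f_none$test_index, f_up$test_index)
  expect_identical(f_none$test_labels, f_up$test_labels)
})

test_that("the feed-forward network has nonlinear capacity and guards", {
  set.seed(77)
  n <- 500
  x <- data.frame(a = sample(c(0, 1), n, TRUE), b = sample(c(0, 1), n, TRUE))
  y <- as.integer(xor(x$a, x$b))
  net <- train_feedforward(x, y, grid = list(list(reg = 1e-4, lr = 1e-3,
                                                  epochs = 40)), seed = 5)
  p <- predict(net, x)
  expect_true(all(p > 0 & p < 1))
  expect_gt(mean((p > 0.5) == y), 0.9)
  expect_error(train_feedforward(x, y, dropout = 1), "dropout")
  expect_error(train_feedforward(x, rep(0L, n)), "single-class")
})

test_that("marginal effects recover closed-form logistic contrasts", {
  set.seed(6)
  n <- 800
  x <- data.frame(bin = sample(c(0, 1), n, TRUE), cont = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.5 + 1.2 * x$bin + 0.8 * x$cont))
  fit <- dmtransit:::fit_learner("logistic", x, y, list(), seed = 1)
  me <- marginal_effects(fit, x)
  beta <- coef(fit$model)
  closed <- mean(plogis(beta[1] + beta[2] * 1 + beta[3] * x$cont) -
                   plogis(beta[1] + beta[2] * 0 + beta[3] * x$cont))
  expect_equal(me$effect_pp[me$feature == "bin"], 100 * closed,
               tolerance = 1e-6)
  # a coefficient forced to zero produces a zero effect
  fit0 <- fit
  fit0$fit <- NULL
  fit0$model$coefficients["bin"] <- 0
  me0 <- marginal_effects(fit0, x)
  expect_equal(me0$effect_pp[me0$feature == "bin"], 0)
})

test_that("the calculator combines nested models as an independent product", {
  stub <- function(p) {
    structure(list(task = NULL, features = character(0), cutoff = 0.5,
                   fit = structure(list(family = "constant", model = p,
                                        features = character(0)),
                                   class = "dmt_learner")),
              class = "fit_result")
  }
  bundle <- list("1y_ON-NOT_goal" = stub(0.3), "1y_ON-NOT_comp" = stub(0.4),
                 "1y_OUT-YES_goal" = stub(0.25))
  patient <- data.frame(age = 50, hba1c = 6.4, has_complication = FALSE)
  v <- predict_stage_probabilities(bundle, patient, 1)
  expect_equal(unname(v), c(0.42, 0.18, 0.28, 0.12))
  expect_equal(sum(v), 1, tolerance = 1e-9)
  # complication starter: structural zeros on the NOT stages
  sick <- data.frame(age = 70, hba1c = 8.2, has_complication = TRUE)
  v2 <- predict_stage_probabilities(bundle, sick, 1)
  expect_equal(unname(v2[c("ON-NOT", "OUT-NOT")]), c(0, 0))
  expect_equal(unname(v2["OUT-YES"]), 0.25)
  expect_error(predict_stage_probabilities(bundle, data.frame(age = 50), 1),
               "hba1c")
})
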