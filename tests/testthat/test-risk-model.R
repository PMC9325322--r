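# Split, SMOTE, threshold selection, evaluation, importance.

make_rows <- function(n, p_pos = 0.2, seed = 1, signal = FALSE) {
  set.seed(seed)
  y <- runif(n) < p_pos
  tibble::tibble(
    patient_id = sprintf("r%04d", seq_len(n)),
    x1 = rnorm(n) + if (signal) 3 * y else 0,
    x2 = rnorm(n),
    x3 = as.integer(runif(n) < 0.5),
    ade = y
  )
}

test_that("the stratified split preserves outcome proportions and seeds", {
  rows <- make_rows(1000, 0.171, seed = 4)
  sp <- stratified_split(rows, test_fraction = 0.2, seed = 9)
  expect_identical(nrow(sp$train) + nrow(sp$test), 1000L)
  p_train <- mean(sp$train$ade)
  p_test <- mean(sp$test$ade)
  # proportions differ by less than one patient's worth
  expect_lt(abs(p_train - p_test), 1 / nrow(sp$test))
  sp2 <- stratified_split(rows, test_fraction = 0.2, seed = 9)
  expect_identical(sp$test$patient_id, sp2$test$patient_id)
  all_neg <- make_rows(50, 0)
  expect_error(stratified_split(all_neg), "two outcome classes")
})

test_that("SMOTE equalizes counts with convex synthetic rows", {
  rows <- make_rows(120, 1 / 6, seed = 7) # 100 vs 20
  rows$ade <- rep(c(TRUE, FALSE), c(20, 100))
  out <- smote(rows, k_neighbors = 5, seed = 1)
  expect_identical(sum(out$ade), 100L)
  expect_identical(sum(!out$ade), 100L)
  # already balanced input is returned unchanged
  bal <- make_rows(100, 0.5, seed = 8)
  bal$ade <- rep(c(TRUE, FALSE), 50)
  expect_identical(smote(bal), bal)
  # too small a minority for the neighbourhood
  tiny <- make_rows(50, 0.08, seed = 3)
  tiny$ade <- rep(c(TRUE, FALSE), c(4, 46))
  expect_error(smote(tiny, k_neighbors = 5), "smaller k")
})

test_that("synthetic points lie on segments between same-cluster neighbours", {
  # two minority clusters far apart: with k = 2 every neighbour is
  # within-cluster, so synthetic points must stay inside their cluster
  set.seed(10)
  minority <- tibble::tibble(
    x1 = c(rnorm(6, 0, 0.1), rnorm(6, 100, 0.1)),
    x2 = c(rnorm(6, 0, 0.1), rnorm(6, 100, 0.1)),
    ade = TRUE
  )
  majority <- tibble::tibble(x1 = rnorm(40, 50, 5), x2 = rnorm(40, 50, 5),
                             ade = FALSE)
  out <- smote(dplyr::bind_rows(minority, majority), k_neighbors = 2,
               seed = 2)
  synth <- out[-seq_len(52), ]
  expect_identical(nrow(synth), 28L)
  in_cluster <- (synth$x1 < 1 & synth$x2 < 1) |
    (synth$x1 > 99 & synth$x2 > 99)
  expect_true(all(in_cluster))
  # convexity: each synthetic point lies on a segment between two
  # original minority points (collinearity within numeric tolerance)
  xm <- as.matrix(minority[, c("x1", "x2")])
  on_segment <- vapply(seq_len(nrow(synth)), function(i) {
    p <- c(synth$x1[i], synth$x2[i])
    any(vapply(seq_len(nrow(xm)), function(a) {
      any(vapply(seq_len(nrow(xm)), function(b) {
        if (a == b) return(FALSE)
        ab <- xm[b, ] - xm[a, ]
        ap <- p - xm[a, ]
        t <- sum(ap * ab) / sum(ab^2)
        t >= -1e-8 && t <= 1 + 1e-8 &&
          sqrt(sum((ap - t * ab)^2)) < 1e-6
      }, logical(1)))
    }, logical(1)))
  }, logical(1))
  expect_true(all(on_segment))
})

test_that("threshold selection equals exhaustive enumeration (<= 20 points)", {
  set.seed(14)
  for (rep in 1:40) {
    n <- sample(4:20, 1)
    scores <- round(runif(n), 2)
    labels <- runif(n) < 0.5
    if (length(unique(labels)) < 2) next
    got <- select_threshold(scores, labels)
    want <- oracle_threshold(scores, labels)
    expect_equal(as.numeric(got), want$t)
    expect_equal(attr(got, "sensitivity"), want$sens)
    expect_equal(attr(got, "specificity"), want$spec)
  }
})

test_that("threshold selection handles edge cases", {
  # perfectly separating scores: distance zero at the separating cut
  got <- select_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_identical(attr(got, "sensitivity"), 1)
  expect_identical(attr(got, "specificity"), 1)
  expect_warning(select_threshold(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)),
                 "constant")
  expect_error(select_threshold(runif(5), rep(1, 5)), "both outcome classes")
})

test_that("trapezoidal AUC is antisymmetric and agrees with pROC", {
  set.seed(15)
  scores <- runif(50)
  labels <- runif(50) < 0.4
  a <- auc_trapezoid(scores, labels)
  expect_equal(auc_trapezoid(-scores, labels), 1 - a)
  expect_equal(a, as.numeric(pROC::auc(pROC::roc(
    labels, scores, quiet = TRUE, direction = "<",
    levels = c(FALSE, TRUE)
  ))))
  expect_identical(auc_trapezoid(c(0.9, 0.8, 0.2), c(1, 1, 0)), 1)
})

test_that("a single-point grid is returned and strong signal is learnable", {
  rows <- make_rows(240, 0.25, seed = 5, signal = TRUE)
  m <- tune_and_train(rows, "random_forest",
                      grid = tibble::tibble(trees = 100, depth = 3),
                      folds = 3, seed = 1)
  expect_identical(m$best_params$trees, 100)
  expect_identical(nrow(m$cv_results), 1L)
  expect_gt(max(m$cv_results$cv_auc), 0.9) # x1 nearly separates classes
})

test_that("label-permuted outcomes give chance-level CV AUC", {
  rows <- make_rows(300, 0.3, seed = 6, signal = FALSE)
  m <- tune_and_train(rows, "gradient_boosted_trees",
                      grid = tibble::tibble(trees = 50, depth = 3,
                                            learning_rate = 0.1),
                      folds = 3, seed = 2)
  expect_lt(abs(max(m$cv_results$cv_auc) - 0.5), 0.15)
})

test_that("evaluation enforces the train-threshold leakage guard", {
  rows <- make_rows(300, 0.25, seed = 9, signal = TRUE)
  sp <- stratified_split(rows, seed = 1)
  m <- tune_and_train(sp$train, "gradient_boosted_trees",
                      grid = tibble::tibble(trees = 60, depth = 3,
                                            learning_rate = 0.1),
                      folds = 3, seed = 1)
  thr_train <- select_threshold(m$train_scores, m$train_labels)
  ev <- evaluate_model(m, sp$test, thr_train)
  expect_true(all(unlist(ev[, c("accuracy", "sensitivity", "specificity",
                                "auc")]) >= 0))
  expect_true(all(unlist(ev[, c("accuracy", "sensitivity", "specificity",
                                "auc")]) <= 1))
  expect_gt(ev$auc, 0.8)
  thr_test <- select_threshold(predict(m, sp$test), sp$test$ade,
                               provenance = "test")
  expect_error(evaluate_model(m, sp$test, thr_test), "leakage")
  expect_error(evaluate_model(m, sp$test, 0.5), "select_threshold")
})

test_that("perfect scores give perfect metrics", {
  rows <- make_rows(100, 0.3, seed = 11)
  m <- structure(list(family = "gradient_boosted_trees", outcome = "ade",
                      features = c("x1", "x2", "x3")),
                 class = "pimddi_model")
  # bypass the fitted model: evaluate on scores equal to the labels
  scores <- as.numeric(rows$ade)
  thr <- select_threshold(scores, rows$ade)
  pred <- as.integer(scores >= as.numeric(thr))
  expect_identical(pred, as.integer(rows$ade))
  expect_identical(auc_trapezoid(scores, rows$ade), 1)
})

test_that("gain importance ranks the driving feature first and sums to 1", {
  rows <- make_rows(300, 0.3, seed = 13, signal = TRUE)
  m <- tune_and_train(rows, "gradient_boosted_trees",
                      grid = tibble::tibble(trees = 60, depth = 3,
                                            learning_rate = 0.1),
                      folds = 3, seed = 3)
  imp <- variable_importance(m)
  expect_identical(imp$feature[1], "x1")
  expect_equal(sum(imp$importance), 1)
  msvm <- structure(list(family = "support_vector_machine"),
                    class = "pimddi_model")
  expect_error(variable_importance(msvm), "tree-ensemble")
})

test_that("the SVM family trains and scores through the same interface", {
  rows <- make_rows(200, 0.3, seed = 17, signal = TRUE)
  m <- tune_and_train(rows, "support_vector_machine",
                      grid = tibble::tibble(cost = 1), folds = 3, seed = 1)
  s <- predict(m, rows)
  expect_true(all(s >= 0 & s <= 1))
  expect_gt(auc_trapezoid(s, rows$ade), 0.8)
})

test_that("the workflow is reproducible under a fixed seed", {
  rows <- make_rows(240, 0.25, seed = 19, signal = TRUE)
  run <- function() {
    sp <- stratified_split(rows, seed = 5)
    m <- tune_and_train(sp$train, "gradient_boosted_trees",
                        grid = tibble::tibble(trees = 40, depth = 3,
                                              learning_rate = 0.1),
                        folds = 3, seed = 5)
    thr <- select_threshold(m$train_scores, m$train_labels)
    evaluate_model(m, sp$test, thr)
  }
  expect_identical(run(), run())
})
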