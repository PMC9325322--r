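# Cross-validated training of the three classifier families, evaluation
# at a train-selected threshold, and gain-based variable importance.

MODEL_FAMILIES <- c("random_forest", "gradient_boosted_trees",
                    "support_vector_machine")

#' Default hyperparameter grids
#'
#' Random forest: trees in {200, 500}, depth in {3, 6, unlimited (0)};
#' gradient boosting: trees in {200, 500}, depth in {3, 6}, learning rate
#' in {0.05, 0.1}; SVM: radial kernel, cost in {0.1, 1, 10}.
#'
#' @param family one of `"random_forest"`, `"gradient_boosted_trees"`,
#'   `"support_vector_machine"`
#' @return tibble, one row per configuration
#' @export
default_grid <- function(family = MODEL_FAMILIES) {
  family <- arg_match(family)
  switch(family,
    random_forest = tidyr::expand_grid(trees = c(200, 500), depth = c(3, 6, 0)),
    gradient_boosted_trees = tidyr::expand_grid(trees = c(200, 500),
                                                depth = c(3, 6),
                                                learning_rate = c(0.05, 0.1)),
    support_vector_machine = tibble(cost = c(0.1, 1, 10))
  )
}

#' Numeric feature matrix from a cohort tibble
#' @noRd
feature_matrix <- function(data, outcome, feature_names = NULL) {
  drop <- intersect(c(outcome, "patient_id"), names(data))
  df <- data[, setdiff(names(data), drop), drop = FALSE]
  if ("sex" %in% names(df)) {
    df$sex <- as.integer(df$sex %in% "M")
    names(df)[names(df) == "sex"] <- "sex_m"
  }
  df <- as.data.frame(lapply(df, function(x) as.numeric(x)))
  m <- as.matrix(df)
  if (!is.null(feature_names)) {
    missing <- setdiff(feature_names, colnames(m))
    if (length(missing) > 0) {
      abort(glue::glue("missing feature column(s): {paste(missing, collapse = ', ')}"))
    }
    m <- m[, feature_names, drop = FALSE]
  }
  m
}

#' @noRd
fit_family <- function(family, x, y, params, seed) {
  if (family == "random_forest") {
    ranger::ranger(
      x = as.data.frame(x), y = factor(y, levels = c(0, 1)),
      num.trees = params$trees, max.depth = params$depth,
      probability = TRUE, importance = "impurity",
      seed = seed, num.threads = 1
    )
  } else if (family == "gradient_boosted_trees") {
    set.seed(seed)
    dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
    xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = params$depth,
                    eta = params$learning_rate, nthread = 1,
                    seed = seed),
      data = dtrain, nrounds = params$trees, verbose = 0
    )
  } else {
    set.seed(seed)
    e1071::svm(x = x, y = factor(y, levels = c(0, 1)), kernel = "radial",
               cost = params$cost, probability = TRUE, scale = TRUE)
  }
}

#' @noRd
score_family <- function(family, fit, x) {
  if (family == "random_forest") {
    predict(fit, data = as.data.frame(x), num.threads = 1)$predictions[, "1"]
  } else if (family == "gradient_boosted_trees") {
    predict(fit, xgboost::xgb.DMatrix(x, nthread = 1))
  } else {
    pred <- predict(fit, x, probability = TRUE)
    attr(pred, "probabilities")[, "1"]
  }
}

#' Stratified cross-validation fold assignment
#' @noRd
stratified_folds <- function(y, folds, seed) {
  if (any(table(y) < folds)) {
    abort("a class has fewer members than folds; stratified folding impossible")
  }
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Tune and train a bleeding-risk classifier
#'
#' Grid search by stratified k-fold cross-validation on the training
#' sample, maximizing mean CV ROC AUC; the winning configuration is refit
#' on the full (rebalanced) training sample. By default SMOTE runs inside
#' each fold on the analysis part only, so no held-out fold information
#' leaks into the synthetic rows; `rebalance = "before_cv"` rebalances
#' once up front instead, for workflows that applied SMOTE before
#' cross-validation.
#'
#' @param train training tibble (from [stratified_split()])
#' @param family `"random_forest"`, `"gradient_boosted_trees"` or
#'   `"support_vector_machine"`
#' @param grid hyperparameter tibble (default [default_grid()])
#' @param folds number of CV folds (default 10)
#' @param seed integer seed controlling folds, SMOTE and model fits
#' @param outcome binary outcome column (default `"ade"`)
#' @param rebalance `"per_fold"` (default) or `"before_cv"`
#' @param smote_k SMOTE neighbourhood size (default 5)
#' @return object of class `pimddi_model`: the refit model, `family`,
#'   `best_params`, a `cv_results` tibble (mean CV AUC per
#'   configuration), `train_scores`/`train_labels` for threshold
#'   selection, and the feature name vector
#' @export
tune_and_train <- function(train, family = MODEL_FAMILIES, grid = NULL,
                           folds = 10, seed = 1, outcome = "ade",
                           rebalance = c("per_fold", "before_cv"),
                           smote_k = 5) {
  family <- arg_match(family)
  rebalance <- arg_match(rebalance)
  if (is.null(grid)) grid <- default_grid(family)
  if (nrow(grid) == 0) abort("hyperparameter grid is empty")

  if (rebalance == "before_cv") {
    train <- smote(train, outcome = outcome, k_neighbors = smote_k, seed = seed)
  }
  y <- as.integer(as.logical(train[[outcome]]))
  fold <- stratified_folds(y, folds, seed)
  feats <- colnames(feature_matrix(train[1, , drop = FALSE], outcome))

  cv_results <- grid
  cv_results$cv_auc <- vapply(seq_len(nrow(grid)), function(g) {
    params <- as.list(grid[g, ])
    aucs <- vapply(seq_len(folds), function(f) {
      analysis <- train[fold != f, , drop = FALSE]
      assessment <- train[fold == f, , drop = FALSE]
      if (rebalance == "per_fold") {
        analysis <- smote(analysis, outcome = outcome, k_neighbors = smote_k,
                          seed = seed + f)
      }
      fit <- fit_family(family,
                        feature_matrix(analysis, outcome, feats),
                        as.integer(as.logical(analysis[[outcome]])),
                        params, seed + f)
      scores <- score_family(family, fit,
                             feature_matrix(assessment, outcome, feats))
      auc_trapezoid(scores, as.logical(assessment[[outcome]]))
    }, numeric(1))
    mean(aucs)
  }, numeric(1))

  best <- which.max(cv_results$cv_auc)
  best_params <- as.list(grid[best, ])
  final_train <- if (rebalance == "per_fold") {
    smote(train, outcome = outcome, k_neighbors = smote_k, seed = seed)
  } else {
    train
  }
  x_final <- feature_matrix(final_train, outcome, feats)
  y_final <- as.integer(as.logical(final_train[[outcome]]))
  fit <- fit_family(family, x_final, y_final, best_params, seed)
  train_scores <- score_family(family, fit, feature_matrix(train, outcome, feats))

  structure(
    list(fit = fit, family = family, best_params = best_params,
         cv_results = as_tibble(cv_results), features = feats,
         outcome = outcome, train_scores = train_scores, train_labels = y),
    class = "pimddi_model"
  )
}

#' @export
print.pimddi_model <- function(x, ...) {
  cat("<pimddi", x$family, "model>\n")
  cat("  best:", paste(names(x$best_params), unlist(x$best_params),
                       sep = "=", collapse = ", "),
      sprintf(" (CV AUC %.3f)", max(x$cv_results$cv_auc)), "\n")
  invisible(x)
}

#' Score new data with a fitted model
#'
#' @param object a `pimddi_model`
#' @param newdata tibble with the training feature columns
#' @param ... unused
#' @return numeric vector of predicted event probabilities
#' @export
predict.pimddi_model <- function(object, newdata, ...) {
  score_family(object$family, object$fit,
               feature_matrix(newdata, object$outcome, object$features))
}

#' Evaluate a model on the test sample
#'
#' Accuracy, sensitivity and specificity at the supplied threshold, and
#' ROC AUC by trapezoidal integration. The threshold must come from
#' [select_threshold()] with provenance `"train"`; a test-derived
#' threshold is refused (leakage guard).
#'
#' @param model a `pimddi_model`
#' @param test test tibble
#' @param threshold a `pimddi_threshold` selected on training scores
#' @return one-row tibble: `family`, `accuracy`, `sensitivity`,
#'   `specificity`, `auc`, `threshold`
#' @export
evaluate_model <- function(model, test, threshold) {
  if (!inherits(threshold, "pimddi_threshold")) {
    abort("threshold must come from select_threshold()")
  }
  if (!identical(attr(threshold, "provenance"), "train")) {
    abort("refusing a threshold selected on test data (leakage guard)")
  }
  scores <- predict(model, test)
  labels <- as.integer(as.logical(test[[model$outcome]]))
  pred <- as.integer(scores >= as.numeric(threshold))
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  tibble(
    family = model$family,
    accuracy = (tp + tn) / length(labels),
    sensitivity = tp / sum(labels == 1),
    specificity = tn / sum(labels == 0),
    auc = auc_trapezoid(scores, labels),
    threshold = as.numeric(threshold)
  )
}

#' Gain-based variable importance of a tree-ensemble model
#'
#' Importance scores normalized to sum to one, in descending order.
#' Random forests report impurity (Gini gain) importance; gradient
#' boosting reports split gain. SVMs have no gain decomposition and are
#' refused.
#'
#' @param model a `pimddi_model` with a tree-ensemble family
#' @return tibble: `feature`, `importance` (sums to 1)
#' @export
variable_importance <- function(model) {
  if (model$family == "support_vector_machine") {
    abort("gain-based importance is only defined for tree-ensemble models")
  }
  raw <- if (model$family == "random_forest") {
    imp <- ranger::importance(model$fit)
    tibble(feature = names(imp), importance = as.numeric(imp))
  } else {
    imp <- xgboost::xgb.importance(model = model$fit)
    tibble(feature = imp$Feature, importance = imp$Gain)
  }
  raw |>
    tidyr::complete(feature = model$features,
                    fill = list(importance = 0)) |>
    mutate(importance = .data$importance / sum(.data$importance)) |>
    arrange(dplyr::desc(.data$importance))
}
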