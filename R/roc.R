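# ROC utilities: curve points, trapezoidal AUC, and Euclidean-distance
# threshold selection.

#' @noRd
check_scores_labels <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    abort("scores and labels must have the same length")
  }
  labels <- as.integer(as.logical(labels))
  if (any(is.na(scores)) || any(is.na(labels))) {
    abort("scores/labels must not contain missing values")
  }
  labels
}

#' ROC curve points over observed score cut-points
#'
#' One row per candidate threshold (each unique score, plus `Inf` for the
#' predict-nothing corner); a score is called positive when
#' `score >= threshold`.
#'
#' @param scores numeric classifier scores (higher = more positive)
#' @param labels binary outcomes (logical or 0/1)
#' @return tibble: `threshold`, `sensitivity`, `specificity`, `fpr`
#' @export
roc_points <- function(scores, labels) {
  labels <- check_scores_labels(scores, labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) abort("both outcome classes must be present")
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thresholds, function(t) sum(scores >= t & labels == 1) / n_pos,
                 numeric(1))
  spec <- vapply(thresholds, function(t) sum(scores < t & labels == 0) / n_neg,
                 numeric(1))
  tibble(threshold = thresholds, sensitivity = sens, specificity = spec,
         fpr = 1 - spec)
}

#' Area under the ROC curve by trapezoidal integration
#'
#' @inheritParams roc_points
#' @return AUC in `[0, 1]`
#' @export
auc_trapezoid <- function(scores, labels) {
  pts <- roc_points(scores, labels) |> arrange(.data$fpr, .data$sensitivity)
  sum(diff(pts$fpr) * (head(pts$sensitivity, -1) + tail(pts$sensitivity, -1)) / 2)
}

#' Select a classification threshold closest to the perfect corner
#'
#' Among observed score cut-points, picks the threshold minimizing the
#' Euclidean distance between its (sensitivity, specificity) pair and the
#' optimal point (1, 1); ties break toward higher sensitivity. The result
#' carries a provenance tag so that [evaluate_model()] can refuse
#' thresholds selected on test data (leakage guard).
#'
#' @inheritParams roc_points
#' @param provenance `"train"` (the legitimate origin) or `"test"`
#' @return the chosen threshold, classed `pimddi_threshold`, with
#'   `sensitivity`, `specificity` and `provenance` attributes
#' @export
select_threshold <- function(scores, labels, provenance = c("train", "test")) {
  provenance <- arg_match(provenance)
  labels_int <- check_scores_labels(scores, labels)
  if (length(unique(labels_int)) < 2) {
    abort("threshold selection needs both outcome classes")
  }
  if (length(unique(scores)) == 1) {
    warn("constant scores: degenerate single cut-point returned")
  }
  pts <- roc_points(scores, labels) |>
    filter(is.finite(.data$threshold)) |>
    mutate(dist = sqrt((1 - .data$sensitivity)^2 + (1 - .data$specificity)^2)) |>
    arrange(.data$dist, dplyr::desc(.data$sensitivity)) |>
    slice(1)
  structure(pts$threshold, class = "pimddi_threshold",
            sensitivity = pts$sensitivity, specificity = pts$specificity,
            provenance = provenance)
}

#' @export
print.pimddi_threshold <- function(x, ...) {
  cat(sprintf("<threshold %.4f (sens %.3f, spec %.3f; selected on %s)>\n",
              unclass(x), attr(x, "sensitivity"), attr(x, "specificity"),
              attr(x, "provenance")))
  invisible(x)
}
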