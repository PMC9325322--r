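# Outcome-stratified train/test split and SMOTE class rebalancing.

#' Outcome-stratified train/test split
#'
#' Samples `test_fraction` of each outcome class (rounded to the nearest
#' patient), so the outcome proportions in train and test differ by less
#' than one patient's worth. Reproducible under `seed`.
#'
#' @param rows cohort tibble
#' @param outcome name of the binary outcome column (default `"ade"`)
#' @param test_fraction fraction held out (default 0.2)
#' @param seed integer seed
#' @return list with `train` and `test` tibbles (each tagged with a
#'   `"role"` attribute)
#' @export
stratified_split <- function(rows, outcome = "ade", test_fraction = 0.2,
                             seed = 1) {
  assert_columns(rows, outcome, "cohort rows")
  y <- as.integer(as.logical(rows[[outcome]]))
  classes <- table(y)
  if (length(classes) < 2) abort("need two outcome classes to split")
  if (any(classes < 2)) {
    abort("each outcome class needs at least 2 members to stratify")
  }
  set.seed(seed)
  test_idx <- unlist(lapply(names(classes), function(cl) {
    idx <- which(y == as.integer(cl))
    sample(idx, size = round(length(idx) * test_fraction))
  }))
  train <- rows[-test_idx, , drop = FALSE]
  test <- rows[test_idx, , drop = FALSE]
  attr(train, "role") <- "train"
  attr(test, "role") <- "test"
  list(train = train, test = test)
}

#' SMOTE: synthetic minority oversampling
#'
#' Equalizes the outcome classes by adding synthetic minority rows. Each
#' synthetic row is a convex combination of a minority seed row and one
#' of its `k_neighbors` nearest minority neighbours (Euclidean distance
#' on the numeric features); non-numeric columns (and the outcome) are
#' copied from the seed row. An already balanced input is returned
#' unchanged.
#'
#' @param train training tibble
#' @param outcome binary outcome column name (default `"ade"`)
#' @param k_neighbors number of nearest minority neighbours (default 5,
#'   the algorithm's canonical value)
#' @param seed integer seed
#' @param id_cols columns excluded from interpolation and copied from the
#'   seed row (default `"patient_id"` when present)
#' @return rebalanced tibble with equal class counts; synthetic rows are
#'   appended after the originals
#' @export
smote <- function(train, outcome = "ade", k_neighbors = 5, seed = 1,
                  id_cols = intersect("patient_id", names(train))) {
  assert_columns(train, outcome, "training rows")
  y <- as.integer(as.logical(train[[outcome]]))
  counts <- table(y)
  if (length(counts) < 2) abort("need two outcome classes to rebalance")
  if (counts[1] == counts[2]) return(train)
  minority <- as.integer(names(counts)[which.min(counts)])
  n_new <- abs(diff(as.integer(counts)))
  min_rows <- train[y == minority, , drop = FALSE]
  if (nrow(min_rows) < k_neighbors + 1) {
    abort(glue::glue(
      "minority class has {nrow(min_rows)} rows; needs at least ",
      "k_neighbors + 1 = {k_neighbors + 1}. Use a smaller k_neighbors."
    ))
  }
  num_cols <- setdiff(
    names(train)[vapply(train, is.numeric, logical(1))],
    c(outcome, id_cols)
  )
  x <- as.matrix(min_rows[, num_cols, drop = FALSE])
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k_neighbors)]))

  set.seed(seed)
  seed_idx <- rep_len(sample(nrow(min_rows)), n_new)
  synth <- min_rows[seed_idx, , drop = FALSE]
  pick <- nn[cbind(seed_idx, sample(k_neighbors, n_new, replace = TRUE))]
  u <- runif(n_new)
  interp <- x[seed_idx, , drop = FALSE] +
    u * (x[pick, , drop = FALSE] - x[seed_idx, , drop = FALSE])
  for (j in seq_along(num_cols)) synth[[num_cols[j]]] <- interp[, j]
  if (length(id_cols) > 0) {
    for (ic in id_cols) {
      synth[[ic]] <- paste0(synth[[ic]], "_smote", seq_len(n_new))
    }
  }
  bind_rows(train, synth)
}
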