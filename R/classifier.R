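#' Train the random-forest narrative classifier
#'
#' Grows `n_trees` classification trees (default 1500), each from an
#' independent balanced bootstrap of the labeled rows (the minority class is
#' matched by an equal-size resample of the majority class, keeping the 0.50
#' decision threshold meaningful under extreme corpus imbalance) and a
#' random feature subset of size `mtry` (default `sqrt(p)`) at every split.
#' Trees are grown to purity (Gini, unlimited depth).  Fully reproducible
#' from `seed`.
#'
#' @param matrix Feature matrix from [transform_texts()] (rows = record ids).
#' @param labels An `ltc_labeled_set`; every labeled id must be a row.
#' @param n_trees Number of trees.
#' @param mtry Features tried per split (default `ceiling(sqrt(ncol))`).
#' @param seed Integer seed.
#' @return Object of class `ltc_forest`.
#' @export
train_forest <- function(matrix, labels, n_trees = 1500L, mtry = NULL,
                         seed = 1L) {
  lab <- as.data.frame(labels)
  if (length(unique(lab$label)) < 2L) {
    stop("training set must contain both classes")
  }
  miss <- setdiff(lab$id, rownames(matrix))
  if (length(miss)) {
    stop("labeled id(s) missing from feature matrix: ",
         paste(head(miss, 5), collapse = ", "))
  }
  X <- as.matrix(matrix[lab$id, , drop = FALSE])
  if (is.null(mtry)) mtry <- max(1L, ceiling(sqrt(ncol(X))))
  model <- .rf_train_cpp(X, as.integer(lab$label), as.integer(n_trees),
                         as.integer(mtry), 1L, TRUE, as.integer(seed))
  structure(list(model = model, n_trees = as.integer(n_trees),
                 mtry = as.integer(mtry), seed = as.integer(seed),
                 fingerprint = matrix_fingerprint(matrix),
                 training_ids = lab$id,
                 class_counts = table(lab$label)),
            class = "ltc_forest")
}

#' @export
print.ltc_forest <- function(x, ...) {
  cat("<ltc_forest> ", x$n_trees, " trees, mtry=", x$mtry,
      ", trained on ", length(x$training_ids), " narratives (",
      paste(names(x$class_counts), as.integer(x$class_counts),
            sep = ":", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Predict LTC-association probabilities
#'
#' The reported probability is the vote share: the fraction of trees whose
#' leaf classifies the narrative as LTC-associated.
#'
#' @param model An [train_forest()] model.
#' @param matrix Feature matrix built with the *same* fitted vectorizer
#'   (vocabulary fingerprints must match).
#' @return Named numeric vector id -> probability in [0, 1].
#' @export
predict_proba <- function(model, matrix) {
  stopifnot(inherits(model, "ltc_forest"))
  fp <- matrix_fingerprint(matrix)
  if (!identical(fp, model$fingerprint)) {
    stop("vocabulary fingerprint mismatch: matrix was built with a ",
         "different vectorizer than the model was trained on")
  }
  r <- methods::as(matrix, "RsparseMatrix")
  probs <- .rf_predict_cpp(model$model, nrow(matrix), r@p, r@j, r@x)
  setNames(probs, rownames(matrix))
}

#' Threshold probabilities into binary labels
#'
#' The boundary is exclusive: a probability of exactly `threshold` (0.50 by
#' default) is classified as *not* associated with LTC.
#'
#' @param probs Named probability vector from [predict_proba()].
#' @param threshold Decision threshold.
#' @return Named integer vector of 0/1 labels.
#' @export
classify <- function(probs, threshold = 0.5) {
  setNames(as.integer(probs > threshold), names(probs))
}

#' Stratified k-fold cross-validation of the classifier
#'
#' @param matrix Feature matrix.
#' @param labels An `ltc_labeled_set`.
#' @param k Number of folds (>= 2); folds are stratified by class.
#' @param n_trees,seed Passed to [train_forest()].
#' @return List with `folds` (per-fold precision/recall/F1 at threshold
#'   0.50) and `mean` (their means).
#' @export
cross_validate <- function(matrix, labels, k = 5L, n_trees = 500L, seed = 1L) {
  lab <- as.data.frame(labels)
  if (k < 2L) stop("k must be >= 2")
  cls <- split(seq_len(nrow(lab)), lab$label)
  if (length(cls) < 2L) stop("need both classes for cross-validation")
  if (any(vapply(cls, length, integer(1)) < k) &&
      min(vapply(cls, length, integer(1))) < 2L) {
    stop("a class is too small to stratify into ", k, " folds")
  }
  fold <- integer(nrow(lab))
  fold[] <- NA_integer_
  # shuffle within class, then deal fold numbers round-robin across the
  # concatenated classes: stratified for k << n, one item per fold at k = n
  order_idx <- with_stream(seed, 401, {
    unlist(lapply(cls, function(idx) idx[sample.int(length(idx))]),
           use.names = FALSE)
  })
  fold[order_idx] <- rep_len(seq_len(k), length(order_idx))
  res <- lapply(seq_len(k), function(f) {
    test <- which(fold == f)
    train <- which(fold != f)
    if (length(unique(lab$label[train])) < 2L) {
      return(c(precision = NA_real_, recall = NA_real_, f1 = NA_real_))
    }
    sub <- lab[train, , drop = FALSE]
    class(sub) <- c("ltc_labeled_set", "data.frame")
    m <- train_forest(matrix, sub, n_trees = n_trees,
                      seed = derive_seed(seed, 500 + f))
    p <- predict_proba(m, matrix[lab$id[test], , drop = FALSE])
    binary_metrics(lab$label[test], as.integer(p > 0.5))
  })
  folds <- do.call(rbind, res)
  list(folds = as.data.frame(folds),
       mean = colMeans(folds, na.rm = TRUE))
}

# Vocabulary binding survives row subsetting (which drops attributes) by
# recomputing the fingerprint from the column names when needed.
matrix_fingerprint <- function(matrix) {
  attr(matrix, "fingerprint") %||% vocab_fingerprint(colnames(matrix))
}

# precision/recall/F1 for predicted vs true 0/1 labels; conventions:
# empty predicted-positive set -> precision NA; F1 of 0/0 -> 0.
binary_metrics <- function(truth, pred) {
  tp <- sum(truth == 1L & pred == 1L)
  fp <- sum(truth == 0L & pred == 1L)
  fn <- sum(truth == 1L & pred == 0L)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  c(precision = precision, recall = recall, f1 = f1)
}
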