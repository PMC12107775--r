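#' Random forest classifier (Gini criterion)
#'
#' Fits a 100-tree (by default) random forest on the training rows and
#' predicts the test rows, returning impurity (mean-decrease-in-Gini)
#' importances as well. Trees are grown to purity on bootstrap samples with
#' `mtry = floor(sqrt(p))` candidate features per split. Reproducible under
#' `set.seed()`.
#'
#' @param x_train,x_test numeric matrices with identical columns.
#' @param y_train factor (or coercible) of training labels.
#' @param ntree number of trees, default 100.
#' @param mtry candidate features per split; default `floor(sqrt(ncol))`.
#' @return list with `pred` (factor over the training levels) and
#'   `importance` (named numeric, one entry per feature).
#' @export
rf_classify <- function(x_train, y_train, x_test, ntree = 100, mtry = NULL) {
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  y_train <- factor(y_train)
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(x_train))))
  fit <- .rf_fit_predict_cpp(x_train, as.integer(y_train) - 1L,
                             nlevels(y_train), x_test,
                             as.integer(ntree), as.integer(mtry))
  list(pred = factor(levels(y_train)[fit$pred + 1L], levels = levels(y_train)),
       importance = setNames(fit$importance,
                             colnames(x_train) %||% seq_len(ncol(x_train))))
}

#' k-nearest-neighbour classifier
#'
#' Euclidean distances, uniform weights, default k = 5. Vote ties are broken
#' toward the smallest class label in sorted order; distance ties keep the
#' earlier training row.
#'
#' @inheritParams rf_classify
#' @param k number of neighbours.
#' @return factor of predictions over the training levels.
#' @export
knn_classify <- function(x_train, y_train, x_test, k = 5) {
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  y_train <- factor(y_train)
  k <- min(k, nrow(x_train))
  # squared Euclidean cross-distances via the expansion trick
  d2 <- outer(rowSums(x_test^2), rowSums(x_train^2), "+") -
    2 * tcrossprod(x_test, x_train)
  pred <- apply(d2, 1, function(row) {
    nn <- order(row)[seq_len(k)]
    tab <- table(y_train[nn])
    names(tab)[which.max(tab)] # which.max: first max = smallest sorted label
  })
  factor(pred, levels = levels(y_train))
}

#' Gaussian naive Bayes with uniform class priors
#'
#' Class-conditional Gaussian likelihoods per feature; priors are uniform
#' over the label alphabet ("without prior probabilities"). Variances are
#' floored at `1e-9 * max feature variance` to tolerate constant features.
#'
#' @inheritParams rf_classify
#' @return factor of predictions over the training levels.
#' @export
gnb_classify <- function(x_train, y_train, x_test) {
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  y_train <- factor(y_train)
  lev <- levels(y_train)
  eps <- 1e-9 * max(apply(x_train, 2, var), 1e-12)
  loglik <- sapply(lev, function(cl) {
    rows <- x_train[y_train == cl, , drop = FALSE]
    mu <- colMeans(rows)
    s2 <- apply(rows, 2, function(v) mean((v - mean(v))^2)) + eps
    colSums(-0.5 * log(2 * pi * s2) -
              0.5 * (t(x_test) - mu)^2 / s2)
  })
  loglik <- matrix(loglik, nrow = nrow(x_test))
  factor(lev[max.col(loglik, ties.method = "first")], levels = lev)
}

#' Trivial baseline classifiers
#'
#' `random_equal` predicts uniformly at random over the label alphabet
#' (expected accuracy `1/n_classes` regardless of the data);
#' `most_frequent` always predicts the modal class of the training labels
#' (ties toward the smallest label in sorted order).
#'
#' @param y_train training labels (factor or coercible).
#' @param n_test number of predictions to draw.
#' @return factor of predictions.
#' @export
random_equal_classify <- function(y_train, n_test) {
  lev <- levels(factor(y_train))
  factor(sample(lev, n_test, replace = TRUE), levels = lev)
}

#' @rdname random_equal_classify
#' @export
most_frequent_classify <- function(y_train, n_test) {
  y_train <- factor(y_train)
  tab <- table(y_train)
  factor(rep(names(tab)[which.max(tab)], n_test), levels = levels(y_train))
}

#' Stratified cross-validation folds
#'
#' Samples are shuffled within each class and dealt round-robin to folds, so
#' every fold's class proportions track the data as closely as integer counts
#' allow. Errors when a class has fewer members than folds.
#'
#' @param labels class labels.
#' @param k number of folds.
#' @return integer fold id (1..k) per sample.
#' @export
stratified_folds <- function(labels, k) {
  labels <- factor(labels)
  if (min(table(labels)) < k)
    stop("fold-construction error: smallest class has fewer than k = ", k,
         " samples")
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated classification accuracy
#'
#' Stratified k-fold cross-validation of one of five classifiers: random
#' forest (`rf`, 100 trees, Gini), k-nearest neighbours (`knn`, k = 5,
#' uniform weights, Euclidean), Gaussian naive Bayes with uniform priors
#' (`nb`), and the trivial baselines `random_equal` and `most_frequent`.
#'
#' @param matrix samples x features [method_matrix()] or plain matrix.
#' @param labels class label per sample.
#' @param classifier one of `"rf"`, `"knn"`, `"nb"`, `"random_equal"`,
#'   `"most_frequent"`.
#' @param k number of folds (default 10).
#' @param seed optional integer; when given, folds and any classifier
#'   randomness are seeded for reproducibility.
#' @param folds optional precomputed fold assignment (overrides `k`), so the
#'   same folds can be shared across classifiers and representations.
#' @return mean validation accuracy over folds (numeric scalar with
#'   per-fold accuracies in `attr(,"per_fold")`).
#' @export
crossval_classify <- function(matrix, labels,
                              classifier = c("rf", "knn", "nb",
                                             "random_equal", "most_frequent"),
                              k = 10, seed = NULL, folds = NULL) {
  classifier <- match.arg(classifier)
  x <- unclass(as.matrix(matrix))
  labels <- factor(labels)
  stopifnot(nrow(x) == length(labels))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(folds)) folds <- stratified_folds(labels, k)
  acc <- sapply(sort(unique(folds)), function(f) {
    tr <- folds != f; te <- !tr
    pred <- switch(classifier,
      rf = rf_classify(x[tr, , drop = FALSE], labels[tr],
                       x[te, , drop = FALSE])$pred,
      knn = knn_classify(x[tr, , drop = FALSE], labels[tr],
                         x[te, , drop = FALSE]),
      nb = gnb_classify(x[tr, , drop = FALSE], labels[tr],
                        x[te, , drop = FALSE]),
      random_equal = random_equal_classify(labels[tr], sum(te)),
      most_frequent = most_frequent_classify(labels[tr], sum(te)))
    mean(pred == labels[te])
  })
  structure(mean(acc), per_fold = acc)
}
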