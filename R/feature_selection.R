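#' Elbow point of a decreasing importance curve
#'
#' Returns the rank N at the point of maximal curvature, computed as the
#' rank maximizing the perpendicular distance to the chord joining the first
#' and last points of the curve. Ties are broken toward smaller N, so a
#' straight (or constant) curve gives N = 1.
#'
#' @param importance_curve numeric vector of (typically decreasing)
#'   importance values, indexed by rank; length >= 3.
#' @return integer rank N.
#' @export
elbow_n <- function(importance_curve) {
  y <- as.numeric(importance_curve)
  n <- length(y)
  if (n < 3) stop("importance curve must have length >= 3")
  if (all(y == y[1])) {
    warning("constant importance curve; returning N = 1")
    return(1L)
  }
  x <- seq_len(n)
  # distance from (x, y) to the chord (1, y1) -- (n, yn)
  dx <- n - 1; dy <- y[n] - y[1]
  d <- abs(dy * x - dx * y + dx * y[1] - dy * 1) / sqrt(dx^2 + dy^2)
  as.integer(which.max(d)) # first max -> smallest N on ties
}

rfe_one_fold <- function(x, y, n_target) {
  feats <- colnames(x)
  size <- length(feats)
  while (size > n_target) {
    nxt <- max(n_target, ceiling(size / 2)) # geometric halving grid
    if (nxt == size) nxt <- size - 1
    fit <- rf_classify(x[, feats, drop = FALSE], y,
                       x[1, feats, drop = FALSE]) # test rows unused here
    feats <- feats[order(-fit$importance)[seq_len(nxt)]]
    size <- nxt
  }
  sort(feats)
}

#' Recursive feature elimination per cross-validation fold
#'
#' For each of k stratified folds, a random-forest importance ranking is
#' refit on the training split while features are eliminated along a
#' geometric halving grid from the full set down to `n_target`; the final
#' `n_target`-sized feature set of each fold is returned. Deterministic
#' given `seed`.
#'
#' @param matrix samples x features [method_matrix()] or plain named matrix.
#' @param labels biome (class) label per sample.
#' @param n_target target number of features per fold (N from the elbow).
#' @param k number of folds, default 10.
#' @param seed integer seed.
#' @return list of k character vectors (sorted feature names, each of size
#'   `n_target`).
#' @export
rfe_per_fold <- function(matrix, labels, n_target, k = 10, seed = 1) {
  x <- unclass(as.matrix(matrix))
  labels <- factor(labels)
  if (n_target < 1) stop("parameter error: n_target must be >= 1")
  if (n_target > ncol(x)) stop("n_target exceeds the number of features")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  set.seed(seed)
  folds <- stratified_folds(labels, k)
  lapply(seq_len(k), function(f) {
    tr <- folds != f
    rfe_one_fold(x[tr, , drop = FALSE], labels[tr], n_target)
  })
}

#' Aggregate per-fold feature sets into rfe1 / rfe2
#'
#' `rfe1` contains every feature selected in at least one fold (union);
#' `rfe2` only features selected consistently in every fold (intersection).
#'
#' @param fold_sets list of character vectors, one per fold.
#' @return list with sorted character vectors `rfe1` and `rfe2`.
#' @export
aggregate_folds <- function(fold_sets) {
  stopifnot(length(fold_sets) >= 1)
  list(rfe1 = sort(Reduce(union, fold_sets)),
       rfe2 = sort(Reduce(intersect, fold_sets)))
}

#' Run the full feature-selection stage
#'
#' When `n_target` is not given, it is chosen by the elbow method applied to
#' the mean sorted random-forest importance curve across the folds' training
#' splits. Per-fold RFE then yields k feature sets, aggregated into rfe1
#' (union) and rfe2 (intersection).
#'
#' @inheritParams rfe_per_fold
#' @param n_target optional feature budget N; elbow-selected when `NULL`.
#' @return A `selection_result`: list with `n_target`, `fold_sets`, `rfe1`,
#'   `rfe2`.
#' @export
select_features <- function(matrix, labels, k = 10, seed = 1,
                            n_target = NULL) {
  x <- unclass(as.matrix(matrix))
  labels <- factor(labels)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (is.null(n_target)) {
    set.seed(seed)
    folds <- stratified_folds(labels, k)
    curves <- sapply(seq_len(k), function(f) {
      tr <- folds != f
      fit <- rf_classify(x[tr, , drop = FALSE], labels[tr],
                         x[1, , drop = FALSE])
      sort(fit$importance, decreasing = TRUE)
    })
    n_target <- elbow_n(rowMeans(matrix(curves, ncol = k)))
  }
  fold_sets <- rfe_per_fold(x, labels, n_target, k, seed)
  agg <- aggregate_folds(fold_sets)
  structure(list(n_target = as.integer(n_target), fold_sets = fold_sets,
                 rfe1 = agg$rfe1, rfe2 = agg$rfe2),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> N = %d; %d folds; |rfe1| = %d, |rfe2| = %d\n",
              x$n_target, length(x$fold_sets), length(x$rfe1), length(x$rfe2)))
  invisible(x)
}
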