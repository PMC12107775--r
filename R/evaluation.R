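#' Euclidean distance matrix between samples
#'
#' @param matrix samples x features numeric matrix.
#' @return full symmetric matrix of pairwise Euclidean distances with zero
#'   diagonal.
#' @export
euclidean_distances <- function(matrix) {
  x <- unclass(as.matrix(matrix))
  if (anyNA(x)) stop("distance input must not contain NaN/NA")
  as.matrix(dist(x, method = "euclidean"))
}

#' Calinski-Harabasz index for labelled groups
#'
#' Ratio of between-group to within-group dispersion,
#' `(B/(k-1)) / (W/(n-k))`, with groups given by the labels (here: biome
#' annotations used as cluster assignments; no clustering algorithm is run).
#'
#' @param matrix samples x features numeric matrix.
#' @param labels group label per sample (>= 2 groups, n > k).
#' @return non-negative numeric scalar.
#' @export
calinski_harabasz <- function(matrix, labels) {
  x <- unclass(as.matrix(matrix))
  labels <- factor(labels)
  n <- nrow(x); k <- nlevels(labels)
  if (k < 2) stop("need at least 2 groups")
  if (n <= k) stop("need more samples than groups")
  grand <- colMeans(x)
  w <- 0; b <- 0
  for (cl in levels(labels)) {
    rows <- x[labels == cl, , drop = FALSE]
    cen <- colMeans(rows)
    w <- w + sum(sweep(rows, 2, cen)^2)
    b <- b + nrow(rows) * sum((cen - grand)^2)
  }
  if (w == 0)
    stop("zero within-cluster variance: Calinski-Harabasz index undefined")
  (b / (k - 1)) / (w / (n - k))
}

#' Dunn index for labelled groups
#'
#' Classic Dunn: minimum between-group point-pair distance divided by the
#' maximum within-group diameter. Zero diameters (all-identical clusters)
#' are floored at `eps` to keep the ratio finite; the result is then a
#' sentinel-scale large value rather than an error.
#'
#' @param distances full symmetric distance matrix (or `dist`).
#' @param labels group label per sample (>= 2 groups).
#' @param eps floor applied to the maximum diameter, default 1e-12.
#' @return non-negative numeric scalar.
#' @export
dunn_index <- function(distances, labels, eps = 1e-12) {
  d <- as.matrix(distances)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 groups")
  same <- outer(labels, labels, "==")
  off <- row(d) != col(d)
  min_between <- min(d[!same])
  max_within <- if (any(same & off)) max(d[same & off]) else 0
  min_between / max(max_within, eps)
}

#' Mean silhouette width for labelled groups
#'
#' For each sample, `a` is its mean distance to its own group (excluding
#' itself) and `b` the smallest mean distance to any other group; the
#' silhouette is `(b - a) / max(a, b)`. Singleton groups get silhouette 0
#' (standard convention). Returns the mean over samples.
#'
#' @inheritParams dunn_index
#' @return numeric scalar in \[-1, 1\].
#' @export
mean_silhouette <- function(distances, labels) {
  d <- as.matrix(distances)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 groups")
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    n_own <- sum(own) - 1
    if (n_own == 0) { s[i] <- 0; next }
    a <- sum(d[i, own]) / n_own
    b <- min(vapply(setdiff(levels(labels), as.character(labels[i])),
                    function(cl) mean(d[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Min-max normalize a metric across compared variants
#'
#' Maps each metric's values across the compared method variants onto
#' \[0, 1\] via `(x - min) / (max - min)`. A constant metric yields all zeros
#' with a warning.
#'
#' @param values numeric vector, one value per variant (>= 2).
#' @return numeric vector in \[0, 1\].
#' @export
normalize_across_variants <- function(values) {
  stopifnot(length(values) >= 2)
  rng <- range(values, na.rm = TRUE)
  if (rng[1] == rng[2]) {
    warning("constant metric across variants; normalized values set to 0")
    return(ifelse(is.na(values), NA_real_, 0))
  }
  (values - rng[1]) / (rng[2] - rng[1])
}

#' PCA projection of a sample representation
#'
#' Centered (unscaled) principal component projection.
#'
#' @param matrix samples x features numeric matrix (>= 2 samples).
#' @param n_components number of components to return, default 2.
#' @return list with `coords` (samples x components) and
#'   `explained_variance` (non-increasing fractions summing to <= 1).
#' @export
pca_project <- function(matrix, n_components = 2) {
  x <- unclass(as.matrix(matrix))
  stopifnot(nrow(x) >= 2)
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  nc <- min(n_components, ncol(p$x))
  ev <- p$sdev^2 / sum(p$sdev^2)
  list(coords = p$x[, seq_len(nc), drop = FALSE],
       explained_variance = ev[seq_len(nc)])
}

#' Evaluate representations x feature sets against biome labels
#'
#' For every (representation, feature set) variant, computes the three
#' clustering validity indices on Euclidean distances with biome labels as
#' cluster assignments, plus cross-validated accuracy of the five
#' classifiers. One stratified fold assignment (from `seed`) is shared by
#' all classifiers and variants so method contrasts are paired. Min-max
#' normalized indices across the compared variants are appended.
#'
#' @param matrices named list of [method_matrix()] objects (after
#'   [filter_uniform()]).
#' @param feature_sets named list of feature-name subsets per matrix; use
#'   `list(full = NULL)` for the unfiltered variant. A `NULL` entry means
#'   all features. Entries may also be a named list per matrix.
#' @param labels biome label per sample (aligned to the matrices' rows).
#' @param k folds for classification, default 10.
#' @param seed integer seed for folds and classifier randomness.
#' @param classifiers which classifiers to run.
#' @return data.frame of class `evaluation_report`, one row per variant.
#' @export
evaluate_variants <- function(matrices, feature_sets, labels, k = 10,
                              seed = 1,
                              classifiers = c("rf", "knn", "nb",
                                              "random_equal",
                                              "most_frequent")) {
  labels <- factor(labels)
  set.seed(seed)
  folds <- stratified_folds(labels, k)
  rows <- list()
  for (m_name in names(matrices)) {
    m <- matrices[[m_name]]
    fs <- feature_sets
    if (!is.null(names(fs)) && m_name %in% names(fs)) fs <- fs[[m_name]]
    for (s_name in names(fs)) {
      sel <- fs[[s_name]]
      cols <- if (is.null(sel)) colnames(m) else intersect(colnames(m), sel)
      row <- data.frame(method = m_name, feature_set = s_name,
                        n_features = length(cols),
                        ch = NA_real_, dunn = NA_real_,
                        silhouette = NA_real_, stringsAsFactors = FALSE)
      for (clf in classifiers) row[[paste0("acc_", clf)]] <- NA_real_
      if (length(cols) >= 1) {
        sub <- unclass(m)[, cols, drop = FALSE]
        d <- euclidean_distances(sub)
        row$ch <- tryCatch(calinski_harabasz(sub, labels),
                           error = function(e) NA_real_)
        row$dunn <- dunn_index(d, labels)
        row$silhouette <- mean_silhouette(d, labels)
        for (clf in classifiers) {
          set.seed(seed + 1000L * match(clf, classifiers))
          row[[paste0("acc_", clf)]] <-
            as.numeric(crossval_classify(sub, labels, clf, folds = folds))
        }
      } else {
        warning("variant ", m_name, "/", s_name,
                " has no features; metrics set to NA")
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  rep_ <- do.call(rbind, rows)
  for (metric in c("ch", "dunn", "silhouette")) {
    rep_[[paste0(metric, "_norm")]] <-
      if (sum(!is.na(rep_[[metric]])) >= 2)
        suppressWarnings(normalize_across_variants(rep_[[metric]]))
      else NA_real_
  }
  class(rep_) <- c("evaluation_report", "data.frame")
  rep_
}
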