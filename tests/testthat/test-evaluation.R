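test_that("euclidean_distances matches hand values and the loop oracle", {
  d <- euclidean_distances(rbind(c(0, 0), c(3, 4)))
  expect_equal(d[1, 2], 5)
  expect_equal(diag(d), c(0, 0), ignore_attr = TRUE)
  same <- euclidean_distances(rbind(c(1, 2), c(1, 2)))
  expect_equal(same[1, 2], 0)
  set.seed(41)
  x <- matrix(rnorm(24), 6, 4)
  expect_equal(unname(euclidean_distances(x)), oracle_euclidean(x),
               tolerance = 1e-12)
  expect_error(euclidean_distances(matrix(c(1, NA), 1)), "NaN")
})

test_that("clustering indices reproduce the 1-D toy hand computations", {
  x <- toy_points(); lab <- toy_labels()
  d <- euclidean_distances(x)
  expect_equal(calinski_harabasz(x, lab), 50)        # (100/1)/(4/2)
  expect_equal(dunn_index(d, lab), 4)                # 8 / 2
  expect_equal(mean_silhouette(d, lab),
               mean(c(9 / 11, 7 / 9, 7 / 9, 9 / 11)))
})

test_that("clustering indices match loop oracles on random instances", {
  set.seed(42)
  for (rep in 1:15) {
    n <- sample(6:14, 1); p <- sample(2:5, 1)
    x <- matrix(rnorm(n * p), n, p)
    lab <- sample(letters[1:3], n, replace = TRUE)
    while (length(unique(lab)) < 2) lab <- sample(letters[1:3], n, TRUE)
    d <- euclidean_distances(x)
    expect_equal(calinski_harabasz(x, lab), oracle_ch(x, lab),
                 tolerance = 1e-12)
    expect_equal(dunn_index(d, lab), oracle_dunn(d, lab), tolerance = 1e-12)
    expect_equal(mean_silhouette(d, lab), oracle_silhouette(d, lab),
                 tolerance = 1e-12)
  }
})

test_that("indices respond monotonically to moving a cluster away", {
  set.seed(43)
  base <- rbind(matrix(rnorm(10, 0), 5, 2), matrix(rnorm(10, 3), 5, 2))
  lab <- rep(c("a", "b"), each = 5)
  shifts <- c(0, 2, 5, 100)
  ch <- dunn <- sil <- numeric(length(shifts))
  for (i in seq_along(shifts)) {
    x <- base; x[6:10, ] <- x[6:10, ] + shifts[i]
    d <- euclidean_distances(x)
    ch[i] <- calinski_harabasz(x, lab)
    dunn[i] <- dunn_index(d, lab)
    sil[i] <- mean_silhouette(d, lab)
  }
  expect_true(all(diff(ch) > 0))
  expect_true(all(diff(dunn) > 0))
  expect_true(all(diff(sil) >= 0))
  expect_gt(sil[4], 0.95)       # silhouette -> 1 as separation grows
})

test_that("index degenerate cases raise documented errors", {
  x <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  rownames(x) <- paste0("s", 1:4)
  lab <- rep(c("a", "b"), each = 2)
  expect_error(calinski_harabasz(x, lab), "zero within-cluster variance")
  expect_error(calinski_harabasz(x, rep("a", 4)), "2 groups")
  expect_error(mean_silhouette(euclidean_distances(x), rep("a", 4)),
               "2 groups")
  # Dunn floors the zero diameter at eps instead of failing
  expect_gt(dunn_index(euclidean_distances(x), lab), 1e10)
})

test_that("normalize_across_variants is a rank-preserving min-max map", {
  expect_equal(normalize_across_variants(c(2, 4, 6)), c(0, 0.5, 1))
  expect_warning(z <- normalize_across_variants(c(5, 5)), "constant")
  expect_equal(z, c(0, 0))
  set.seed(44)
  v <- rnorm(10)
  expect_identical(order(normalize_across_variants(v)), order(v))
})

test_that("pca_project returns sane explained-variance fractions", {
  x <- cbind(1:10, (1:10) * 2)            # collinear -> PC1 explains all
  p <- pca_project(x)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-12)
  set.seed(45)
  iso <- matrix(rnorm(4000), 2000, 2)
  expect_equal(pca_project(iso)$explained_variance[1], 0.5, tolerance = 0.07)
  # rank-2 data: projection onto 2 PCs preserves pairwise distances
  y <- matrix(rnorm(40), 20, 2) %*% matrix(c(1, 2, 0, 1, 1, 3), 2, 3)
  pr <- pca_project(y, 2)
  expect_equal(unname(as.matrix(dist(pr$coords))),
               unname(as.matrix(dist(y))), tolerance = 1e-9)
})

test_that("crossval_classify: separable data, baselines, determinism", {
  x <- matrix(c(rep(0, 10), rep(10, 10)), ncol = 1)
  rownames(x) <- paste0("s", 1:20); colnames(x) <- "f"
  y <- rep(c("A", "B"), each = 10)
  expect_equal(as.numeric(crossval_classify(x, y, "knn", k = 5, seed = 1)), 1)
  expect_equal(as.numeric(crossval_classify(x, y, "nb", k = 5, seed = 1)), 1)
  expect_equal(as.numeric(crossval_classify(x, y, "rf", k = 5, seed = 1)), 1)

  # most_frequent equals the validation-fold frequency of the training mode
  y2 <- factor(rep(c("A", "A", "B"), times = c(14, 0, 7)))
  x2 <- matrix(rnorm(21), ncol = 1,
               dimnames = list(paste0("s", 1:21), "f"))
  acc <- crossval_classify(x2, y2, "most_frequent", k = 7, seed = 2)
  per_fold <- attr(acc, "per_fold")
  expect_equal(per_fold, rep(2 / 3, 7))   # each fold: 2 A, 1 B; mode is A

  # random_equal accuracy is invariant to the feature matrix
  a1 <- crossval_classify(x2, y2, "random_equal", k = 7, seed = 3)
  a2 <- crossval_classify(x2 * 100 + 5, y2, "random_equal", k = 7, seed = 3)
  expect_identical(as.numeric(a1), as.numeric(a2))

  expect_error(crossval_classify(x2, y2, "knn", k = 10), "fold-construction")
})

test_that("kNN and NB break ties deterministically toward sorted labels", {
  xtr <- matrix(c(0, 0, 10, 10), ncol = 1)
  ytr <- c("b", "a", "a", "b")   # 2-NN vote tie at both test points
  pred <- knn_classify(xtr, ytr, matrix(c(0, 10), ncol = 1), k = 2)
  expect_equal(as.character(pred), c("a", "a"))
})

test_that("evaluate_variants builds the full variant grid", {
  st <- tiny_study()
  preds <- st$predictions
  md <- st$metadata
  m1 <- filter_uniform(ccv_matrix(preds, "compound_class"))
  m2 <- filter_uniform(ccv_matrix(preds, "fingerprint"))
  labels <- md$biome[match(rownames(m1), md$sample_id)]
  fsets <- list(cc_avg = list(full = NULL, top2 = colnames(m1)[1:2]),
                mfp_avg = list(full = NULL, top2 = colnames(m2)[1:2]))
  rep_ <- evaluate_variants(list(cc_avg = m1, mfp_avg = m2), fsets, labels,
                            k = 3, seed = 8,
                            classifiers = c("knn", "most_frequent"))
  expect_equal(nrow(rep_), 4)             # 2 matrices x 2 feature sets
  expect_true(all(c("ch", "dunn", "silhouette", "ch_norm", "acc_knn",
                    "acc_most_frequent") %in% names(rep_)))
  expect_true(all(rep_$ch >= 0))
  expect_true(all(rep_$silhouette >= -1 & rep_$silhouette <= 1))
  expect_true(all(rep_$ch_norm >= 0 & rep_$ch_norm <= 1, na.rm = TRUE))
})
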