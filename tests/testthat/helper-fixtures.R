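# Shared in-code fixtures; everything is generated at test time.

.fixture_cache <- new.env(parent = emptyenv())

tiny_study <- function(seed = 42) {
  key <- paste0("tiny", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- make_fixture("tiny", seed = seed)
  .fixture_cache[[key]]
}

# two well-separated 1-D clusters used by the hand-computed index oracles
toy_points <- function() matrix(c(0, 2, 10, 12), ncol = 1,
                                dimnames = list(paste0("s", 1:4), "f1"))
toy_labels <- function() c("a", "a", "b", "b")

# small prediction set built by hand: n peaks at given mz, given 0/1-ish probs
manual_prediction_set <- function(sample_ids, peak_ids, mz, fp_probs, cc_probs) {
  prediction_set(
    data.frame(sample_id = sample_ids, peak_id = peak_ids, mz = mz,
               stringsAsFactors = FALSE),
    fp_probs, cc_probs,
    characteristic_defs(seq_len(ncol(fp_probs)), "fingerprint"),
    characteristic_defs(seq_len(ncol(cc_probs)), "compound_class"))
}

# planted 3-class dataset: 5 informative of `p` features, shift `delta`
planted_matrix <- function(n_per_class = 20, p = 200, delta = 2, seed = 1) {
  set.seed(seed)
  n <- 3 * n_per_class
  x <- matrix(runif(n * p), n)
  colnames(x) <- sprintf("f%03d", seq_len(p))
  rownames(x) <- sprintf("s%03d", seq_len(n))
  y <- rep(c("A", "B", "C"), each = n_per_class)
  x[, 1] <- x[, 1] + delta * (y == "A")
  x[, 2] <- x[, 2] + delta * (y == "B")
  x[, 3] <- x[, 3] + delta * (y == "C")
  x[, 4] <- x[, 4] - delta * (y == "A")
  x[, 5] <- x[, 5] + delta * (y == "B") - delta * (y == "C")
  list(x = x, y = y, informative = sprintf("f%03d", 1:5))
}

# independent loop-based oracles --------------------------------------------

oracle_euclidean <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
  d
}

oracle_ch <- function(x, labels) {
  labels <- factor(labels)
  n <- nrow(x); k <- nlevels(labels)
  grand <- colMeans(x)
  w <- 0; b <- 0
  for (cl in levels(labels)) {
    rows <- which(labels == cl)
    cen <- colMeans(x[rows, , drop = FALSE])
    for (i in rows) w <- w + sum((x[i, ] - cen)^2)
    b <- b + length(rows) * sum((cen - grand)^2)
  }
  (b / (k - 1)) / (w / (n - k))
}

oracle_dunn <- function(d, labels) {
  labels <- factor(labels)
  n <- nrow(d)
  min_between <- Inf; max_within <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (labels[i] == labels[j]) max_within <- max(max_within, d[i, j])
    else min_between <- min(min_between, d[i, j])
  }
  min_between / max(max_within, 1e-12)
}

oracle_silhouette <- function(d, labels) {
  labels <- factor(labels)
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) next
    a <- mean(d[i, own])
    b <- Inf
    for (cl in levels(labels)) {
      if (cl == labels[i]) next
      b <- min(b, mean(d[i, labels == cl]))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# brute-force elbow: maximal perpendicular distance to the chord
oracle_elbow <- function(y) {
  n <- length(y)
  x1 <- 1; y1 <- y[1]; x2 <- n; y2 <- y[n]
  dd <- vapply(seq_len(n), function(i) {
    abs((y2 - y1) * i - (x2 - x1) * y[i] + x2 * y1 - y2 * x1) /
      sqrt((y2 - y1)^2 + (x2 - x1)^2)
  }, numeric(1))
  which(dd == max(dd))[1]
}

# full enumeration of the two-sided rank-sum p-value (ties allowed)
oracle_ranksum_p <- function(g1, g2) {
  pooled <- c(g1, g2)
  r <- rank(pooled)
  n1 <- length(g1)
  w_obs <- sum(r[seq_len(n1)])
  ws <- apply(combn(length(pooled), n1), 2, function(ix) sum(r[ix]))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}
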