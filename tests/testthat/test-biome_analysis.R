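md_for <- function(ids, biomes, contributor = "lab1") {
  sample_metadata(data.frame(sample_id = ids, biome = biomes,
                             contributor = contributor,
                             stringsAsFactors = FALSE))
}

test_that("class_ratio_table summarizes per-biome percent distributions", {
  vals <- rbind(S1 = c(c1 = 0.2, c2 = 0), S2 = c(c1 = 0.4, c2 = 0),
                S3 = c(c1 = 0.1, c2 = 0))
  m <- method_matrix(vals, "cc_avg")
  md <- md_for(c("S1", "S2", "S3"), c("X", "X", "Y"))
  crt <- class_ratio_table(m, md)
  sx <- crt$summary[crt$summary$biome == "X" & crt$summary$characteristic == "c1", ]
  expect_equal(sx$mean, 30)
  expect_equal(c(sx$min, sx$max), c(20, 40))
  expect_equal(sx$n, 2)
  # absent-everywhere characteristic -> all-zero distribution
  expect_true(all(crt$samples$percent[crt$samples$characteristic == "c2"] == 0))
  # single-sample biome is degenerate but valid
  sy <- crt$summary[crt$summary$biome == "Y" & crt$summary$characteristic == "c1", ]
  expect_equal(c(sy$mean, sy$min, sy$max), c(10, 10, 10))
  expect_error(class_ratio_table(m, md, "nope"), "unknown characteristic")
})

test_that("class ratio means equal per-biome column means (loop oracle)", {
  set.seed(51)
  vals <- matrix(runif(8 * 5), 8, 5,
                 dimnames = list(paste0("S", 1:8), paste0("c", 1:5)))
  m <- method_matrix(vals, "cc_avg")
  md <- md_for(paste0("S", 1:8), rep(c("X", "Y"), each = 4))
  crt <- class_ratio_table(m, md)
  for (b in c("X", "Y")) for (ch in paste0("c", 1:5)) {
    rows <- paste0("S", if (b == "X") 1:4 else 5:8)
    manual <- mean(vals[rows, ch]) * 100
    got <- crt$summary$mean[crt$summary$biome == b &
                              crt$summary$characteristic == ch]
    expect_equal(got, manual, tolerance = 1e-12)
  }
})

test_that("ranksum_compare: exact branch matches enumeration and wilcox.test", {
  rs <- ranksum_compare(1:3, 4:6)
  expect_equal(rs$p_value, 0.1)                 # 2/20 arrangements
  expect_equal(rs$statistic, 6)                 # ranks 1+2+3
  expect_identical(rs$method, "exact")
  expect_equal(ranksum_compare(c(5, 7, 9), c(5, 7, 9))$p_value, 1)

  set.seed(52)
  for (n1 in 1:6) for (n2 in n1:6) {
    g1 <- rnorm(n1); g2 <- rnorm(n2)           # tie-free almost surely
    ours <- ranksum_compare(g1, g2)
    expect_equal(ours$p_value, oracle_ranksum_p(g1, g2), tolerance = 1e-12)
    ref <- suppressWarnings(wilcox.test(g1, g2, exact = TRUE))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    # U = W - n1(n1+1)/2 links our rank-sum to the Mann-Whitney statistic
    expect_equal(ours$statistic - n1 * (n1 + 1) / 2,
                 unname(ref$statistic))
  }
  # tied data against the enumeration oracle
  for (i in 1:5) {
    g1 <- sample(1:3, sample(2:5, 1), replace = TRUE)
    g2 <- sample(1:3, sample(2:5, 1), replace = TRUE)
    expect_equal(ranksum_compare(g1, g2)$p_value, oracle_ranksum_p(g1, g2),
                 tolerance = 1e-12)
  }
  expect_error(ranksum_compare(numeric(0), 1:3), "non-empty")
})

test_that("ranksum normal approximation is calibrated for large shifts", {
  set.seed(53)
  g1 <- rnorm(50); g2 <- rnorm(50, mean = 3)
  rs <- ranksum_compare(g1, g2)
  expect_identical(rs$method, "normal approximation")
  expect_lt(rs$p_value, 1e-6)
  # approximation tracks wilcox.test's corrected normal approximation
  g3 <- rnorm(20); g4 <- rnorm(15, 0.5)
  ours <- ranksum_compare(g3, g4)$p_value
  ref <- wilcox.test(g3, g4, exact = FALSE, correct = TRUE)$p.value
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("massgroup_class_profile isolates planted mass bins", {
  # class c2 present only in peaks above 550 Th
  mz <- c(120, 300, 580, 700)
  cc <- cbind(c1 = c(1, 1, 0, 0), c2 = c(0, 0, 1, 1))
  preds <- manual_prediction_set(rep("S1", 4), paste0("p", 1:4), mz,
                                 matrix(0.9, 4, 2), cc)
  m <- ccv_matrix(preds, "compound_class", massgrouped = TRUE)
  md <- md_for("S1", "X")
  prof <- massgroup_class_profile(m, md, "c2")
  nonzero <- prof$samples[prof$samples$percent > 0, ]
  expect_identical(unique(nonzero$bin), "550-900")
  expect_equal(nonzero$percent, 100)            # both 550-900 peaks carry c2
  expect_error(massgroup_class_profile(m, md, "zzz"), "unknown characteristic")

  # per-bin values recombine to the whole-sample value via peak counts
  whole <- ccv_matrix(preds, "compound_class")
  bins <- assign_mass_group(mz)
  weights <- table(factor(bins, levels = 1:7)) / length(mz)
  grouped <- unclass(m)["S1", grep("\\|c2$", colnames(m))]
  expect_equal(sum(weights * grouped), unclass(whole)["S1", "c2"],
               tolerance = 1e-12)
})

test_that("within_biome_contrast flags the planted subgroup classes", {
  set.seed(55)
  cfg <- study_config(n_biomes = 2, samples_per_biome = 16,
                      peaks_per_sample = c(60, 90),
                      n_fingerprint = 30, n_class = 40, n_informative = 3,
                      effect_size = 0.6,
                      subgroup = list(fraction = 0.5, n_classes = 2),
                      seed = 55)
  st <- generate_study(cfg)
  m <- ccv_matrix(st$predictions, "compound_class")
  res <- within_biome_contrast(m, st$metadata, st$truth$subgroup$biome,
                               groupby = "contributor", adjust = TRUE)
  planted <- paste0("c", st$truth$subgroup$classes)
  expect_true(all(res$p_value[res$characteristic %in% planted] < 0.01))
  null_p <- res$p_value[!res$characteristic %in% planted]
  expect_gt(median(null_p), 0.05)   # non-planted classes look null
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_identical(unname(attr(res, "groups")),
                   sort(unique(st$metadata$contributor[
                     st$metadata$biome == st$truth$subgroup$biome])))
})
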