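test_that("binarize uses the inclusive >= 0.5 convention", {
  expect_equal(binarize(c(0.49, 0.50, 0.51)), c(0, 1, 1))
  expect_equal(binarize(c(0, 1)), c(0, 1))          # idempotent on binary
  expect_equal(binarize(rep(0, 4)), rep(0, 4))
  expect_equal(binarize(c(0.3, 0.7), threshold = 0.3), c(1, 1))
  expect_error(binarize(0.5, threshold = 0), "parameter error")
  expect_error(binarize(0.5, threshold = 1), "parameter error")
  expect_error(binarize(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("peaks_for_sample filters by sample-specific MS/MS and m/z window", {
  preds <- manual_prediction_set(
    c("S1", "S1", "S1", "S2"), c("p1", "p2", "p3", "p1"),
    c(99.9, 100.0, 900.0, 500),
    matrix(c(0.9, 0.1, 0.6, 0.2, 0.8, 0.7, 0.3, 0.4), 4, 2),
    matrix(0.5, 4, 2))
  got <- peaks_for_sample("S1", preds, "fingerprint")
  expect_equal(nrow(got$vectors), 2)        # 99.9 excluded, 100.0 kept
  expect_equal(got$mz, c(100, 900))         # both bounds inclusive
  expect_equal(got$vectors[1, ], c(c1 = 0, c2 = 1))
  expect_equal(nrow(peaks_for_sample("S3", preds, "fingerprint")$vectors), 0)
})

test_that("average_ccv is the columnwise fraction of ones", {
  expect_equal(average_ccv(rbind(c(1, 0, 1), c(1, 1, 0))), c(1, 0.5, 0.5))
  v <- c(1, 0, 1)
  expect_equal(average_ccv(rbind(v)), v)     # single vector is identity
  m <- rbind(c(1, 1), c(1, 0), c(0, 1))
  expect_equal(average_ccv(m), c(2 / 3, 2 / 3))
  expect_error(average_ccv(matrix(numeric(0), 0, 3)), "no MS/MS peaks")
  expect_error(average_ccv(list()), "no MS/MS peaks")
})

test_that("massgrouped_ccv concatenates per-bin averages with zero blocks", {
  vec <- rbind(c(1, 0), c(0, 1))
  out <- massgrouped_ccv(vec, mz = c(120, 600))
  expect_length(out, 14)                            # 7 bins x 2 features
  expect_equal(unname(out[1:2]), c(1, 0))           # bin 100-250
  expect_equal(unname(out[13:14]), c(0, 1))         # bin 550-900
  expect_equal(unname(out[3:12]), rep(0, 10))       # empty bins

  # all peaks in one bin: that bin equals the whole-sample CCV
  m <- rbind(c(1, 1, 0), c(0, 1, 0), c(1, 1, 1))
  out2 <- massgrouped_ccv(m, mz = c(260, 270, 280))
  expect_equal(unname(out2[4:6]), unname(average_ccv(m)))
  expect_equal(sum(out2[-(4:6)]), 0)

  expect_error(massgrouped_ccv(vec, mz = c(120, 950)), "assignment error")
})

test_that("conservation: whole-sample CCV is the peak-weighted mean of bins", {
  scheme <- mass_group_scheme()
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(2:50, 1); p <- sample(2:20, 1)
    vec <- matrix(rbinom(n * p, 1, 0.3), n, p)
    mz <- runif(n, 100, 900)
    whole <- average_ccv(vec)
    grouped <- massgrouped_ccv(vec, mz, scheme)
    bins <- assign_mass_group(mz, scheme)
    recomb <- Reduce(`+`, lapply(seq_len(scheme$n_bins), function(g) {
      (sum(bins == g) / n) * grouped[((g - 1) * p + 1):(g * p)]
    }))
    expect_equal(unname(recomb), unname(whole), tolerance = 1e-12)
    # loop-oracle equivalence, bin by bin and bit by bit
    for (g in unique(bins)) {
      rows <- which(bins == g)
      manual <- apply(vec[rows, , drop = FALSE], 2, function(col)
        sum(col) / length(rows))
      expect_equal(unname(grouped[((g - 1) * p + 1):(g * p)]),
                   unname(manual), tolerance = 1e-15)
    }
  }
})

test_that("adding a peak updates the CCV by the exact running-mean rule", {
  set.seed(12)
  vec <- matrix(rbinom(30 * 6, 1, 0.4), 30, 6)
  old <- average_ccv(vec[1:29, ])
  new <- average_ccv(vec)
  expect_equal(new, (old * 29 + vec[30, ]) / 30, tolerance = 1e-15)
})

test_that("ms1_matrix builds presence and log10 representations", {
  ft <- feature_table(
    c("a", "b", "c"), mz = c(150, 500, 950), rt = c(1, 2, 3),
    cbind(S1 = c(0, 1e6, 10), S2 = c(3, 0, 5)))
  pres <- ms1_matrix(ft, "presence")
  lg <- ms1_matrix(ft, "log10")
  expect_identical(attr(pres, "method"), "ms1_presence")
  expect_equal(ncol(pres), 2)                       # mz 950 excluded
  expect_equal(unclass(pres)["S1", ], c(peaka = 0, peakb = 1))
  expect_equal(unclass(lg)["S1", "peakb"], 6)       # log10(1e6)
  expect_equal(unclass(lg)["S1", "peaka"], 0)       # absent -> 0, not -Inf

  # presence is invariant to strictly monotone intensity rescaling
  ft2 <- ft; ft2$intensities <- ft$intensities^3 * 7
  expect_identical(unclass(ms1_matrix(ft2, "presence")), unclass(pres))
})

test_that("filter_uniform drops exactly the constant columns", {
  vals <- cbind(allzero = c(0, 0, 0), const = c(0.3, 0.3, 0.3),
                near = c(0.3, 0.3000001, 0.3), vary = c(0, 1, 0))
  rownames(vals) <- paste0("S", 1:3)
  m <- method_matrix(vals, "cc_avg")
  f <- filter_uniform(m)
  expect_identical(colnames(f), c("near", "vary"))
  allu <- method_matrix(vals[, 1:2], "cc_avg")
  expect_error(filter_uniform(allu), "no informative features")
})

test_that("to_percent scales fractions to percent of LC-MS peaks", {
  expect_equal(to_percent(0.046), 4.6)
  expect_equal(to_percent(c(0, 1)), c(0, 100))
  expect_error(to_percent(1.2), "\\[0, 1\\]")
})

test_that("ccv_matrix excludes zero-MS/MS samples with a warning", {
  preds <- manual_prediction_set(
    c("S1", "S1"), c("p1", "p2"), c(200, 300),
    matrix(c(0.9, 0.2, 0.6, 0.8), 2, 2), matrix(0.6, 2, 2))
  expect_warning(m <- ccv_matrix(preds, "fingerprint",
                                 samples = c("S1", "S2")),
                 "zero qualifying MS/MS")
  expect_identical(rownames(m), "S1")
  expect_error(suppressWarnings(ccv_matrix(preds, "fingerprint",
                                           samples = "S9")),
               "no sample has qualifying MS/MS")
})
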