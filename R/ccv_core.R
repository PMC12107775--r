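#' Method matrix: one sample representation
#'
#' A `method_matrix` is a samples x features numeric matrix tagged with the
#' representation it encodes. Six representations are supported: MS1
#' presence/absence, MS1 log10 intensity, whole-sample averaged fingerprint
#' or compound class CCVs, and their mass-grouped variants.
#'
#' @param values numeric matrix with sample row names and feature column
#'   names; no NaN/NA allowed.
#' @param method one of `ms1_presence`, `ms1_log10`, `mfp_avg`,
#'   `mfp_massgrouped`, `cc_avg`, `cc_massgrouped`.
#' @return The matrix with class `method_matrix` and a `method` attribute.
#' @export
method_matrix <- function(values, method) {
  method <- match.arg(method, METHOD_TAGS)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("method matrix must not contain NaN/NA")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("method matrix needs sample row names and feature column names")
  if (method == "ms1_presence" && !all(values %in% c(0, 1)))
    stop("presence/absence values must be in {0, 1}")
  if (method %in% c("mfp_avg", "mfp_massgrouped", "cc_avg", "cc_massgrouped") &&
      (min(values) < 0 || max(values) > 1))
    stop("CCV values must lie in [0, 1]")
  structure(values, method = method, class = c("method_matrix", "matrix"))
}

#' @export
print.method_matrix <- function(x, ...) {
  cat(sprintf("<method_matrix:%s> %d samples x %d features\n",
              attr(x, "method"), nrow(x), ncol(x)))
  invisible(x)
}

#' Binarize probabilistic characteristic predictions
#'
#' Probabilities are turned into presence/absence calls: present when the
#' probability is greater than or equal to the threshold (inclusive
#' convention at the boundary).
#'
#' @param probs numeric vector or matrix of probabilities in \[0,1\].
#' @param threshold decision threshold, strictly inside (0, 1); default 0.5.
#' @return 0/1 object of the same shape as `probs`.
#' @export
binarize <- function(probs, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1)
    stop("parameter error: threshold must lie strictly inside (0, 1)")
  if (length(probs) && (anyNA(probs) || min(probs) < 0 || max(probs) > 1))
    stop("probabilities must lie in [0, 1]")
  (probs >= threshold) + 0
}

#' Mass-group scheme for precursor m/z binning
#'
#' Default edges give the seven groups 100-250, 250-300, 300-350, 350-400,
#' 400-450, 450-550 and 550-900 Th, chosen to spread typical small-molecule
#' LC-MS peaks evenly. Bins are half-open \[lo, hi) except the last, which is
#' closed.
#'
#' @param edges strictly increasing numeric vector of bin boundaries (>= 2).
#' @return An object of class `mass_group_scheme`.
#' @export
mass_group_scheme <- function(edges = c(100, 250, 300, 350, 400, 450, 550, 900)) {
  edges <- as.numeric(edges)
  if (length(edges) < 2 || any(diff(edges) <= 0))
    stop("edges must be strictly increasing with at least 2 values")
  labels <- paste0(format(edges[-length(edges)], trim = TRUE), "-",
                   format(edges[-1], trim = TRUE))
  structure(list(edges = edges, labels = labels,
                 n_bins = length(edges) - 1L),
            class = "mass_group_scheme")
}

#' Assign precursor m/z values to mass-group bins
#'
#' @param mz numeric vector of m/z values.
#' @param scheme a [mass_group_scheme()].
#' @return integer bin index per value; values outside the scheme raise an
#'   assignment error.
#' @export
assign_mass_group <- function(mz, scheme = mass_group_scheme()) {
  lo <- scheme$edges[1]; hi <- scheme$edges[length(scheme$edges)]
  if (any(mz < lo | mz > hi))
    stop("assignment error: m/z value outside mass-group scheme [",
         lo, ", ", hi, "]")
  bin <- findInterval(mz, scheme$edges, rightmost.closed = TRUE)
  as.integer(bin)
}

#' Binarized characteristic vectors of one sample's MS/MS peaks
#'
#' Selects the peaks for which MS/MS was acquired in this specific sample,
#' restricts to the precursor m/z range (inclusive on both ends), and
#' binarizes the probability vectors.
#'
#' @param sample sample identifier.
#' @param preds a [prediction_set()].
#' @param kind `"fingerprint"` or `"compound_class"`.
#' @param mz_range numeric length-2, default `c(100, 900)`.
#' @param threshold binarization threshold, default 0.5.
#' @return list with `vectors` (peaks x characteristics 0/1 matrix, possibly
#'   zero rows) and `mz` (per-peak precursor m/z).
#' @export
peaks_for_sample <- function(sample, preds,
                             kind = c("fingerprint", "compound_class"),
                             mz_range = c(100, 900), threshold = 0.5) {
  kind <- match.arg(kind)
  stopifnot(inherits(preds, "prediction_set"))
  probs <- if (kind == "fingerprint") preds$fingerprint_probs else preds$class_probs
  keep <- preds$entries$sample_id == sample &
    preds$entries$mz >= mz_range[1] & preds$entries$mz <= mz_range[2]
  vec <- binarize(probs[keep, , drop = FALSE], threshold)
  list(vectors = vec, mz = preds$entries$mz[keep])
}

#' Average binary characteristic vectors into a CCV
#'
#' Each entry of the chemical characteristics vector is the fraction of the
#' sample's MS/MS-characterized peaks carrying that characteristic, i.e. the
#' column mean of the binary peak x characteristic matrix.
#'
#' @param vectors 0/1 matrix (peaks x characteristics) or list of equal-length
#'   0/1 vectors.
#' @return numeric fraction vector in \[0,1\].
#' @export
average_ccv <- function(vectors) {
  if (is.list(vectors)) {
    if (!length(vectors)) stop("no MS/MS peaks for sample")
    vectors <- do.call(rbind, vectors)
  }
  vectors <- as.matrix(vectors)
  if (nrow(vectors) == 0) stop("no MS/MS peaks for sample")
  colMeans(vectors)
}

#' Mass-grouped CCV: per-bin averages, concatenated
#'
#' Peaks are partitioned by precursor m/z into the scheme's bins; each bin is
#' averaged separately with [average_ccv()] and the per-bin vectors are
#' concatenated in bin order. Bins without peaks contribute an all-zero block
#' so the output length is always `n_bins * n_characteristics`.
#'
#' @param vectors 0/1 matrix (peaks x characteristics).
#' @param mz per-peak precursor m/z, same length as `nrow(vectors)`.
#' @param scheme a [mass_group_scheme()].
#' @return named fraction vector of length `n_bins * ncol(vectors)`.
#' @export
massgrouped_ccv <- function(vectors, mz, scheme = mass_group_scheme()) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) == 0) stop("no MS/MS peaks for sample")
  stopifnot(length(mz) == nrow(vectors))
  bins <- assign_mass_group(mz, scheme)
  p <- ncol(vectors)
  out <- numeric(scheme$n_bins * p)
  feat <- colnames(vectors) %||% as.character(seq_len(p))
  names(out) <- as.vector(t(outer(scheme$labels, feat,
                                  function(b, f) paste0("mz", b, "|", f))))
  for (g in seq_len(scheme$n_bins)) {
    in_bin <- bins == g
    if (any(in_bin))
      out[((g - 1) * p + 1):(g * p)] <- colMeans(vectors[in_bin, , drop = FALSE])
  }
  out
}

#' Build the MS1 representation matrix
#'
#' @param table a [feature_table()].
#' @param mode `"presence"` (1 iff peak area > 0) or `"log10"`
#'   (log10(intensity) for detected peaks, 0 for absent ones).
#' @param mz_range precursor m/z window applied to all representations for
#'   parity; default `c(100, 900)`, inclusive.
#' @return A [method_matrix()] with samples as rows and peaks as columns.
#' @export
ms1_matrix <- function(table, mode = c("presence", "log10"),
                       mz_range = c(100, 900)) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "feature_table"))
  keep <- table$mz >= mz_range[1] & table$mz <= mz_range[2]
  inten <- t(table$intensities[keep, , drop = FALSE])
  if (!ncol(inten)) stop("no peaks within the m/z range")
  if (mode == "presence") {
    vals <- (inten > 0) + 0
    tag <- "ms1_presence"
  } else {
    vals <- ifelse(inten > 0, log10(inten), 0)
    tag <- "ms1_log10"
  }
  colnames(vals) <- paste0("peak", table$peak_id[keep])
  method_matrix(vals, tag)
}

#' Build a CCV representation matrix across samples
#'
#' For each sample, peaks with sample-specific MS/MS inside the m/z window
#' are binarized and averaged — whole-sample or per mass group. Samples with
#' zero qualifying peaks are excluded with a warning rather than emitting an
#' all-zero vector (an all-zero CCV would be a statement about chemistry, not
#' about missingness).
#'
#' @param preds a [prediction_set()].
#' @param kind `"fingerprint"` or `"compound_class"`.
#' @param massgrouped logical; concatenate per-mass-group averages?
#' @param samples sample ids to build rows for; defaults to the samples
#'   present in `preds`.
#' @param scheme a [mass_group_scheme()] (mass-grouped variant only).
#' @param mz_range,threshold see [peaks_for_sample()].
#' @return A [method_matrix()] tagged `mfp_avg`, `mfp_massgrouped`, `cc_avg`
#'   or `cc_massgrouped`.
#' @export
ccv_matrix <- function(preds, kind = c("fingerprint", "compound_class"),
                       massgrouped = FALSE, samples = NULL,
                       scheme = mass_group_scheme(),
                       mz_range = c(100, 900), threshold = 0.5) {
  kind <- match.arg(kind)
  samples <- samples %||% unique(preds$entries$sample_id)
  rows <- vector("list", length(samples))
  keep <- logical(length(samples))
  for (i in seq_along(samples)) {
    pk <- peaks_for_sample(samples[i], preds, kind, mz_range, threshold)
    if (nrow(pk$vectors) == 0) next
    keep[i] <- TRUE
    rows[[i]] <- if (massgrouped) massgrouped_ccv(pk$vectors, pk$mz, scheme)
                 else average_ccv(pk$vectors)
  }
  if (!any(keep)) stop("no sample has qualifying MS/MS peaks")
  if (any(!keep))
    warning("excluded sample(s) with zero qualifying MS/MS peaks: ",
            paste(samples[!keep], collapse = ", "))
  m <- do.call(rbind, rows[keep])
  rownames(m) <- samples[keep]
  tag <- paste0(if (kind == "fingerprint") "mfp" else "cc",
                if (massgrouped) "_massgrouped" else "_avg")
  method_matrix(m, tag)
}

#' Drop uninformative (uniform) features
#'
#' Removes every column whose value is identical across all samples — all
#' zeros, all ones, or any other constant (exact equality). Columns with at
#' least two distinct values are always retained.
#'
#' @param matrix a [method_matrix()].
#' @return The filtered [method_matrix()].
#' @export
filter_uniform <- function(matrix) {
  stopifnot(inherits(matrix, "method_matrix"))
  vals <- unclass(matrix)
  varying <- apply(vals, 2, function(col) any(col != col[1]))
  if (!any(varying)) stop("no informative features: all columns are uniform")
  method_matrix(vals[, varying, drop = FALSE], attr(matrix, "method"))
}

#' Express CCV fractions as percentages of LC-MS peaks
#'
#' @param ccv numeric fractions in \[0,1\] (vector or matrix).
#' @return the same object scaled by 100, in \[0,100\].
#' @export
to_percent <- function(ccv) {
  if (anyNA(ccv) || min(ccv) < 0 || max(ccv) > 1)
    stop("CCV fractions must lie in [0, 1]")
  ccv * 100
}
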