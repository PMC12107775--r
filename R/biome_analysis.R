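#' Per-biome compound class ratio distributions
#'
#' Scales the averaged compound-class CCV matrix to percent (fraction of a
#' sample's MS/MS-characterized LC-MS peaks annotated with the class) and
#' summarizes the per-sample values per biome.
#'
#' @param ccv_matrix a [method_matrix()] of averaged CCVs (`cc_avg` or
#'   `mfp_avg`); values are fractions in \[0,1\].
#' @param metadata a `sample_metadata` table covering the matrix rows.
#' @param characteristics character vector of feature (column) names to
#'   summarize; default all columns.
#' @return list of class `class_ratio_summary` with `samples` (long
#'   data.frame: sample_id, biome, characteristic, percent), `summary`
#'   (biome x characteristic mean/min/max in percent and sample count `n`).
#' @export
class_ratio_table <- function(ccv_matrix, metadata,
                              characteristics = colnames(ccv_matrix)) {
  stopifnot(inherits(ccv_matrix, "method_matrix"))
  missing <- setdiff(characteristics, colnames(ccv_matrix))
  if (length(missing))
    stop("unknown characteristic(s): ", paste(missing, collapse = ", "),
         "; available: ", paste(head(colnames(ccv_matrix), 10), collapse = ", "),
         if (ncol(ccv_matrix) > 10) ", ...")
  samples <- intersect(rownames(ccv_matrix), metadata$sample_id)
  if (!length(samples)) stop("no overlap between matrix rows and metadata")
  pct <- to_percent(unclass(ccv_matrix)[samples, characteristics, drop = FALSE])
  biome <- metadata$biome[match(samples, metadata$sample_id)]
  long <- data.frame(
    sample_id = rep(samples, times = length(characteristics)),
    biome = rep(biome, times = length(characteristics)),
    characteristic = rep(characteristics, each = length(samples)),
    percent = as.vector(pct), stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(long, list(long$biome, long$characteristic),
                                      drop = TRUE), function(g)
    data.frame(biome = g$biome[1], characteristic = g$characteristic[1],
               mean = mean(g$percent), min = min(g$percent),
               max = max(g$percent), n = nrow(g), stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  structure(list(samples = long, summary = summ),
            class = "class_ratio_summary")
}

#' @export
print.class_ratio_summary <- function(x, ...) {
  cat(sprintf("<class_ratio_summary> %d biomes x %d characteristics\n",
              length(unique(x$summary$biome)),
              length(unique(x$summary$characteristic))))
  invisible(x)
}

ranksum_exact_p <- function(g1, g2) {
  pooled <- c(g1, g2)
  r <- rank(pooled)
  n1 <- length(g1)
  w_obs <- sum(r[seq_len(n1)])
  sets <- combn(length(pooled), n1)
  ws <- colSums(matrix(r[sets], nrow = n1))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

#' Two-sided Wilcoxon rank-sum comparison
#'
#' Statistic is the rank-sum of `group1` in the pooled ranking. The p-value
#' is exact (full enumeration of group assignments, two-sided as twice the
#' smaller tail, capped at 1) when `n1 + n2 <= exact_limit`, otherwise a
#' normal approximation with tie correction and 0.5 continuity correction.
#'
#' @param group1,group2 numeric vectors of per-sample values (each n >= 1).
#' @param exact_limit combined size up to which the exact enumeration is
#'   used; default 12.
#' @return list with `statistic` (rank-sum of group1), `p_value`, and
#'   `method` ("exact" or "normal approximation").
#' @export
ranksum_compare <- function(group1, group2, exact_limit = 12) {
  if (!length(group1) || !length(group2))
    stop("both groups must be non-empty")
  n1 <- length(group1); n2 <- length(group2); n <- n1 + n2
  r <- rank(c(group1, group2))
  w <- sum(r[seq_len(n1)])
  if (n <= exact_limit) {
    p <- ranksum_exact_p(group1, group2)
    method <- "exact"
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1 # every observation tied: no evidence either way
    } else {
      z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation"
  }
  list(statistic = w, p_value = p, method = method)
}

#' Within-biome two-group contrast across characteristics
#'
#' Splits one biome's samples into groups by a metadata column (contributor
#' or origin — subgroup structure comes from the study design, not from
#' clustering) and runs [ranksum_compare()] per characteristic on the
#' percent-scaled values. Raw p-values are reported by default; an optional
#' Benjamini-Hochberg adjustment can be added.
#'
#' @param ccv_matrix averaged CCV [method_matrix()].
#' @param metadata `sample_metadata` table.
#' @param biome biome whose samples are contrasted.
#' @param groupby metadata column defining the two groups, default
#'   `"contributor"`.
#' @param groups optional length-2 character vector selecting which two
#'   group labels to compare; defaults to the two most frequent.
#' @param characteristics columns to test; default all.
#' @param adjust apply Benjamini-Hochberg correction? Default `FALSE`.
#' @return data.frame with characteristic, group means (percent), statistic,
#'   p_value (and `p_adjusted` when requested).
#' @export
within_biome_contrast <- function(ccv_matrix, metadata, biome,
                                  groupby = "contributor", groups = NULL,
                                  characteristics = colnames(ccv_matrix),
                                  adjust = FALSE) {
  stopifnot(groupby %in% names(metadata))
  md <- metadata[metadata$biome == biome, , drop = FALSE]
  md <- md[md$sample_id %in% rownames(ccv_matrix), , drop = FALSE]
  if (is.null(groups)) {
    tab <- sort(table(md[[groupby]]), decreasing = TRUE)
    if (length(tab) < 2) stop("need at least two groups in '", groupby, "'")
    groups <- names(tab)[1:2]
  }
  ids1 <- md$sample_id[md[[groupby]] == groups[1]]
  ids2 <- md$sample_id[md[[groupby]] == groups[2]]
  pct <- to_percent(unclass(ccv_matrix)[, characteristics, drop = FALSE])
  res <- do.call(rbind, lapply(characteristics, function(ch) {
    g1 <- pct[ids1, ch]; g2 <- pct[ids2, ch]
    rs <- ranksum_compare(g1, g2)
    data.frame(characteristic = ch,
               mean_group1 = mean(g1), mean_group2 = mean(g2),
               statistic = rs$statistic, p_value = rs$p_value,
               stringsAsFactors = FALSE)
  }))
  if (adjust) res$p_adjusted <- stats::p.adjust(res$p_value, "BH")
  attr(res, "groups") <- setNames(groups, c("group1", "group2"))
  res
}

#' Mass-group profile of one compound class across biomes
#'
#' Extracts, from a mass-grouped CCV matrix, the per-bin percent values of a
#' single characteristic and tabulates their distribution per biome.
#'
#' @param ccv_matrix a mass-grouped [method_matrix()] (`cc_massgrouped` or
#'   `mfp_massgrouped`) whose columns are named `mz<bin>|<characteristic>`.
#' @param metadata `sample_metadata` covering the matrix rows.
#' @param characteristic characteristic (column suffix) to profile.
#' @return list with `samples` (long data.frame: sample_id, biome, bin,
#'   percent) and `summary` (per biome x bin mean/min/max percent, n).
#' @export
massgroup_class_profile <- function(ccv_matrix, metadata, characteristic) {
  stopifnot(inherits(ccv_matrix, "method_matrix"))
  cols <- grep(paste0("\\|", characteristic, "$"), colnames(ccv_matrix),
               value = TRUE)
  if (!length(cols))
    stop("unknown characteristic: ", characteristic, "; available suffixes: ",
         paste(head(unique(sub("^mz[^|]*\\|", "", colnames(ccv_matrix))), 10),
               collapse = ", "))
  bins <- sub("^mz([^|]*)\\|.*$", "\\1", cols)
  samples <- intersect(rownames(ccv_matrix), metadata$sample_id)
  pct <- to_percent(unclass(ccv_matrix)[samples, cols, drop = FALSE])
  biome <- metadata$biome[match(samples, metadata$sample_id)]
  long <- data.frame(
    sample_id = rep(samples, times = length(cols)),
    biome = rep(biome, times = length(cols)),
    bin = rep(bins, each = length(samples)),
    percent = as.vector(pct), stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(long, list(long$biome, long$bin),
                                      drop = TRUE), function(g)
    data.frame(biome = g$biome[1], bin = g$bin[1], mean = mean(g$percent),
               min = min(g$percent), max = max(g$percent), n = nrow(g),
               stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  list(samples = long, summary = summ)
}
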