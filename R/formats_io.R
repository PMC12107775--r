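#' Construct a feature table of aligned LC-MS peaks
#'
#' A `feature_table` holds one row per aligned chromatographic peak (MS1
#' feature) with its precursor m/z, retention time, and one non-negative
#' peak-area column per sample. A zero intensity means the peak was not
#' detected in that sample.
#'
#' @param peak_id character or integer vector of unique peak identifiers.
#' @param mz numeric vector of precursor mass-to-charge values (Th), > 0.
#' @param rt numeric vector of retention times (minutes), >= 0.
#' @param intensities numeric matrix, peaks x samples, with unique column
#'   names (sample identifiers) and non-negative entries.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(peak_id, mz, rt, intensities) {
  peak_id <- as.character(peak_id)
  intensities <- as.matrix(intensities)
  if (anyDuplicated(peak_id))
    stop("integrity error: duplicate peak ids: ",
         paste(unique(peak_id[duplicated(peak_id)]), collapse = ", "))
  if (is.null(colnames(intensities)) || anyDuplicated(colnames(intensities)))
    stop("sample identifiers must be unique and named")
  if (length(mz) != length(peak_id) || length(rt) != length(peak_id) ||
      nrow(intensities) != length(peak_id))
    stop("peak_id, mz, rt and intensity rows must have equal length")
  if (any(!is.finite(mz)) || any(mz <= 0)) stop("mz must be positive and finite")
  if (any(!is.finite(rt)) || any(rt < 0)) stop("rt must be non-negative")
  intensities[is.na(intensities)] <- 0
  if (any(intensities < 0)) stop("intensities must be non-negative")
  rownames(intensities) <- peak_id
  structure(list(peak_id = peak_id, mz = as.numeric(mz), rt = as.numeric(rt),
                 intensities = intensities),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d peaks x %d samples, m/z %.1f-%.1f\n",
              length(x$peak_id), ncol(x$intensities),
              min(x$mz), max(x$mz)))
  invisible(x)
}

#' Read a GNPS/MZmine feature quantification CSV
#'
#' Expects the GNPS export dialect: mandatory columns `row ID`, `row m/z`,
#' `row retention time`, and one `<sample> Peak area` column per sample.
#' A trailing empty column (rows ending with a comma) is tolerated. Blank or
#' missing intensities are read as 0 (not detected).
#'
#' @param path path to the CSV file.
#' @return A [feature_table()].
#' @export
read_quant_table <- function(path) {
  dt <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE,
                          check.names = FALSE)
  required <- c("row ID", "row m/z", "row retention time")
  missing <- setdiff(required, names(dt))
  if (length(missing))
    stop("format error: missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  area_cols <- grep(" Peak area$", names(dt), value = TRUE)
  if (!length(area_cols))
    stop("format error: no '<sample> Peak area' columns found")
  ids <- as.character(dt[["row ID"]])
  if (anyDuplicated(ids))
    stop("integrity error: duplicate row IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  inten <- as.matrix(dt[, area_cols, drop = FALSE])
  storage.mode(inten) <- "double"
  inten[is.na(inten)] <- 0
  colnames(inten) <- sub(" Peak area$", "", area_cols)
  feature_table(ids, dt[["row m/z"]], dt[["row retention time"]], inten)
}

#' Write a feature table in the GNPS/MZmine quant CSV dialect
#'
#' @param table a [feature_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  out <- data.frame(check.names = FALSE,
                    `row ID` = table$peak_id,
                    `row m/z` = table$mz,
                    `row retention time` = table$rt)
  inten <- as.data.frame(table$intensities)
  names(inten) <- paste0(colnames(table$intensities), " Peak area")
  data.table::fwrite(cbind(out, inten), path, sep = ",")
  invisible(path)
}

#' Construct a characteristic definition table
#'
#' Characteristics are molecular fingerprint positions (substructures) or
#' compound class positions (ontology categories), keyed by the stable
#' `absoluteIndex` integer of the prediction engine.
#'
#' @param absolute_index unique integer keys.
#' @param kind `"fingerprint"` or `"compound_class"`.
#' @param description free-text description per characteristic.
#' @return data.frame ordered by `absolute_index` with class
#'   `characteristic_defs`.
#' @export
characteristic_defs <- function(absolute_index, kind, description = NULL) {
  kind <- match.arg(kind, c("fingerprint", "compound_class"))
  absolute_index <- as.integer(absolute_index)
  if (anyDuplicated(absolute_index))
    stop("absolute_index must be unique within a kind")
  if (is.null(description))
    description <- paste0(substr(kind, 1, 2), "_", absolute_index)
  d <- data.frame(absolute_index = absolute_index, kind = kind,
                  description = as.character(description),
                  stringsAsFactors = FALSE)
  d <- d[order(d$absolute_index), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("characteristic_defs", "data.frame")
  d
}

#' Construct a prediction set
#'
#' A `prediction_set` stores per-(sample, peak) probabilistic fingerprint and
#' compound class vectors, as produced by an MS/MS annotation engine. Every
#' entry denotes that an MS/MS spectrum was acquired for that peak in that
#' specific sample.
#'
#' @param entries data.frame with columns `sample_id`, `peak_id`, `mz`.
#' @param fingerprint_probs numeric matrix, rows aligned to `entries`,
#'   columns aligned to `fp_defs` order; probabilities in \[0,1\].
#' @param class_probs numeric matrix, same layout over `cc_defs`.
#' @param fp_defs,cc_defs [characteristic_defs()] tables.
#' @return An object of class `prediction_set`.
#' @export
prediction_set <- function(entries, fingerprint_probs, class_probs,
                           fp_defs, cc_defs) {
  entries <- as.data.frame(entries)
  stopifnot(all(c("sample_id", "peak_id", "mz") %in% names(entries)))
  fingerprint_probs <- as.matrix(fingerprint_probs)
  class_probs <- as.matrix(class_probs)
  if (nrow(entries)) {
    if (ncol(fingerprint_probs) != nrow(fp_defs))
      stop("shape error: fingerprint vector length ", ncol(fingerprint_probs),
           " != number of fingerprint definitions ", nrow(fp_defs))
    if (ncol(class_probs) != nrow(cc_defs))
      stop("shape error: class vector length ", ncol(class_probs),
           " != number of class definitions ", nrow(cc_defs))
    rng <- range(fingerprint_probs, class_probs)
    if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 1)
      stop("probabilities must lie in [0, 1]; found value outside range")
  } else {
    fingerprint_probs <- matrix(numeric(0), 0, nrow(fp_defs))
    class_probs <- matrix(numeric(0), 0, nrow(cc_defs))
  }
  colnames(fingerprint_probs) <- paste0("c", fp_defs$absolute_index)
  colnames(class_probs) <- paste0("c", cc_defs$absolute_index)
  structure(list(entries = entries,
                 fingerprint_probs = fingerprint_probs,
                 class_probs = class_probs,
                 fp_defs = fp_defs, cc_defs = cc_defs),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf(
    "<prediction_set> %d (sample, peak) entries; %d fingerprint + %d class characteristics\n",
    nrow(x$entries), nrow(x$fp_defs), nrow(x$cc_defs)))
  invisible(x)
}

read_defs_file <- function(path, kind) {
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  stopifnot(all(c("absolute_index", "description") %in% names(d)))
  characteristic_defs(d$absolute_index, kind, d$description)
}

read_pred_file <- function(path, defs) {
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                         check.names = FALSE)
  if (!nrow(d))
    return(list(entries = data.frame(sample_id = character(0),
                                     peak_id = character(0), mz = numeric(0)),
                probs = matrix(numeric(0), 0, nrow(defs))))
  stopifnot(all(c("sample_id", "peak_id", "mz") %in% names(d)))
  prob_cols <- setdiff(names(d), c("sample_id", "peak_id", "mz"))
  if (length(prob_cols) != nrow(defs))
    stop("shape error: ", length(prob_cols), " probability columns but ",
         nrow(defs), " definitions")
  # columns are ordered by absolute_index on disk; realign defensively
  idx <- as.integer(sub("^c", "", prob_cols))
  if (!setequal(idx, defs$absolute_index))
    stop("shape error: prediction columns do not match definition indices")
  probs <- as.matrix(d[, prob_cols[order(idx)], drop = FALSE])
  storage.mode(probs) <- "double"
  if (anyNA(probs) || min(probs) < 0 || max(probs) > 1)
    stop("probabilities must lie in [0, 1]; found value outside range")
  list(entries = data.frame(sample_id = as.character(d$sample_id),
                            peak_id = as.character(d$peak_id),
                            mz = as.numeric(d$mz)),
       probs = probs)
}

#' Read fingerprint and compound class prediction tables
#'
#' Predictions are stored as wide tab-separated tables: one row per
#' (sample, peak) with MS/MS, columns `sample_id`, `peak_id`, `mz`, then one
#' probability column `c<absoluteIndex>` per characteristic, ordered by
#' absolute index. Definitions are separate two-column tables
#' (`absolute_index`, `description`).
#'
#' @param fp_path,cc_path fingerprint / class prediction tables.
#' @param defs_fp,defs_cc fingerprint / class definition tables.
#' @param metadata optional [read_metadata()] result; sample ids absent from
#'   it trigger a warning (records are retained).
#' @return A [prediction_set()].
#' @export
read_predictions <- function(fp_path, cc_path, defs_fp, defs_cc,
                             metadata = NULL) {
  fpd <- read_defs_file(defs_fp, "fingerprint")
  ccd <- read_defs_file(defs_cc, "compound_class")
  fp <- read_pred_file(fp_path, fpd)
  cc <- read_pred_file(cc_path, ccd)
  if (!identical(dim(fp$entries), dim(cc$entries)) ||
      !identical(fp$entries$peak_id, cc$entries$peak_id) ||
      !identical(fp$entries$sample_id, cc$entries$sample_id))
    stop("fingerprint and class tables must cover the same (sample, peak) rows")
  if (!is.null(metadata)) {
    unknown <- setdiff(unique(fp$entries$sample_id), metadata$sample_id)
    if (length(unknown))
      warning("prediction sample id(s) absent from metadata: ",
              paste(unknown, collapse = ", "))
  }
  prediction_set(fp$entries, fp$probs, cc$probs, fpd, ccd)
}

#' Write a prediction set to the on-disk layout of [read_predictions()]
#'
#' @param preds a [prediction_set()].
#' @param fp_path,cc_path,defs_fp,defs_cc output paths.
#' @return Invisibly, the four paths.
#' @export
write_predictions <- function(preds, fp_path, cc_path, defs_fp, defs_cc) {
  stopifnot(inherits(preds, "prediction_set"))
  wd <- function(defs, path)
    data.table::fwrite(defs[, c("absolute_index", "description")], path,
                       sep = "\t")
  wp <- function(probs, defs, path) {
    d <- cbind(preds$entries[, c("sample_id", "peak_id", "mz")],
               as.data.frame(probs))
    names(d)[-(1:3)] <- paste0("c", defs$absolute_index)
    data.table::fwrite(d, path, sep = "\t")
  }
  wd(preds$fp_defs, defs_fp); wd(preds$cc_defs, defs_cc)
  wp(preds$fingerprint_probs, preds$fp_defs, fp_path)
  wp(preds$class_probs, preds$cc_defs, cc_path)
  invisible(c(fp_path, cc_path, defs_fp, defs_cc))
}

#' Read a sample metadata table
#'
#' Delimited (TSV or CSV) table with at least `sample_id`, `biome`, and
#' `contributor` columns; an `origin` column is optional. Biome categories are
#' exposed in stable sorted order via `attr(x, "biomes")`.
#'
#' @param path path to the metadata file.
#' @return data.frame of class `sample_metadata`.
#' @export
read_metadata <- function(path) {
  d <- data.table::fread(path, header = TRUE, data.table = FALSE)
  stopifnot(all(c("sample_id", "biome", "contributor") %in% names(d)))
  sample_metadata(d)
}

#' @rdname read_metadata
#' @param d data.frame with `sample_id`, `biome`, `contributor` (and
#'   optionally `origin`) columns.
#' @export
sample_metadata <- function(d) {
  d <- as.data.frame(d)
  d$sample_id <- as.character(d$sample_id)
  d$biome <- as.character(d$biome)
  if (anyDuplicated(d$sample_id))
    stop("integrity error: duplicate sample_id: ",
         paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", "))
  if (any(is.na(d$biome) | !nzchar(d$biome)))
    stop("every sample must have a non-empty biome")
  if (is.null(d$origin)) d$origin <- ""
  attr(d, "biomes") <- sort(unique(d$biome))
  class(d) <- c("sample_metadata", "data.frame")
  d
}

#' @rdname read_metadata
#' @param metadata a `sample_metadata` object.
#' @export
write_metadata <- function(metadata, path) {
  data.table::fwrite(as.data.frame(metadata), path, sep = "\t")
  invisible(path)
}

#' Write / read a method matrix
#'
#' Matrices are stored as TSV with a `# method: <tag>` comment header; rows
#' are samples, columns are named features. Round-trips preserve values to at
#' least 12 significant digits, row/column order, and the method tag.
#'
#' @param matrix a [method_matrix()].
#' @param path file path.
#' @return `write_matrix`: `path` invisibly; `read_matrix`: a
#'   [method_matrix()].
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "method_matrix"))
  if (anyNA(unclass(matrix)))
    stop("refusing to write matrix with NaN/NA cells")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# method: ", attr(matrix, "method")), con)
  writeLines(paste(c("sample", colnames(matrix)), collapse = "\t"), con)
  vals <- format(unclass(matrix), digits = 15, scientific = TRUE, trim = TRUE)
  for (i in seq_len(nrow(matrix)))
    writeLines(paste(c(rownames(matrix)[i], vals[i, ]), collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  tag <- sub("^# method: ", "", first)
  d <- data.table::fread(path, sep = "\t", header = TRUE, skip = 1L,
                         data.table = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- d[[1]]
  method_matrix(m, tag)
}
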