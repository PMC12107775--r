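#' Validate a pipeline configuration
#'
#' The pipeline is driven by a single declarative config (JSON on disk, or an
#' equivalent named list). Recognized fields, with defaults:
#' `seed` (1), `input` (`list(mode = "simulate", fixture = "tiny")` or
#' `mode = "files"` with `quant`, `fp`, `cc`, `defs_fp`, `defs_cc`,
#' `metadata` paths), `threshold` (0.5), `mz_range` (`c(100, 900)`),
#' `mass_group_edges` (the seven-bin scheme), `methods` (all six tags),
#' `selection` (`k` 10, `n_target` NULL = elbow), `evaluation` (`folds` 10,
#' all five classifiers).
#'
#' @param config named list or path to a JSON file.
#' @return validated config list with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  known <- c("seed", "input", "threshold", "mz_range", "mass_group_edges",
             "methods", "selection", "evaluation", "analysis")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("config error: unknown field(s): ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(known, collapse = ", "))
  config$seed <- as.integer(config$seed %||% 1)
  config$input <- config$input %||% list(mode = "simulate", fixture = "tiny")
  if (!config$input$mode %in% c("simulate", "files"))
    stop("config error: input$mode must be 'simulate' or 'files'")
  if (config$input$mode == "files") {
    need <- c("quant", "fp", "cc", "defs_fp", "defs_cc", "metadata")
    miss <- setdiff(need, names(config$input))
    if (length(miss))
      stop("config error: input$mode = 'files' requires field(s): ",
           paste(miss, collapse = ", "))
  }
  config$threshold <- config$threshold %||% 0.5
  config$mz_range <- as.numeric(config$mz_range %||% c(100, 900))
  config$mass_group_edges <-
    as.numeric(config$mass_group_edges %||% c(100, 250, 300, 350, 400, 450, 550, 900))
  config$methods <- unlist(config$methods %||% METHOD_TAGS)
  bad <- setdiff(config$methods, METHOD_TAGS)
  if (length(bad))
    stop("config error: unknown method tag(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(METHOD_TAGS, collapse = ", "))
  config$selection <- config$selection %||% list()
  config$selection$k <- config$selection$k %||% 10
  config$evaluation <- config$evaluation %||% list()
  config$evaluation$folds <- config$evaluation$folds %||% 10
  config$evaluation$classifiers <- unlist(
    config$evaluation$classifiers %||%
      c("rf", "knn", "nb", "random_equal", "most_frequent"))
  config
}

# deterministic per-stage substreams fanned out from the global seed;
# kept far below 2^31
stage_seed <- function(seed, stage) {
  (seed * 97L + match(stage, c("simulate", "build", "select", "evaluate",
                               "analyze")) * 1009L) %% 2000000011L
}

build_matrices <- function(ft, preds, config, log = message) {
  scheme <- mass_group_scheme(config$mass_group_edges)
  out <- list()
  samples <- unique(preds$entries$sample_id)
  for (tag in config$methods) {
    m <- switch(tag,
      ms1_presence = ms1_matrix(ft, "presence", config$mz_range),
      ms1_log10 = ms1_matrix(ft, "log10", config$mz_range),
      mfp_avg = ccv_matrix(preds, "fingerprint", FALSE, samples, scheme,
                           config$mz_range, config$threshold),
      mfp_massgrouped = ccv_matrix(preds, "fingerprint", TRUE, samples, scheme,
                                   config$mz_range, config$threshold),
      cc_avg = ccv_matrix(preds, "compound_class", FALSE, samples, scheme,
                          config$mz_range, config$threshold),
      cc_massgrouped = ccv_matrix(preds, "compound_class", TRUE, samples,
                                  scheme, config$mz_range, config$threshold))
    before <- ncol(m)
    m <- filter_uniform(m)
    log(sprintf("[build] %s: %d features (%d uniform removed)",
                tag, ncol(m), before - ncol(m)))
    out[[tag]] <- m
  }
  out
}

#' Run the full pipeline
#'
#' Orchestrates simulate/ingest, representation building (with uniform
#' feature filtering), per-representation recursive feature elimination
#' (rfe1/rfe2), the 18-variant evaluation grid, compound class ratio tables,
#' and a reproducibility manifest. Every filtering count (m/z-excluded
#' peaks, uniform features removed, samples excluded for zero MS/MS) is
#' logged.
#'
#' @param config named list or path to a JSON config (see
#'   [validate_config()]).
#' @param out_dir output directory, created if needed.
#' @param quiet suppress progress messages?
#' @return `out_dir`, invisibly; outputs: `matrix_<tag>.tsv`,
#'   `selection_<tag>.json`, `evaluation.tsv`/`.json`,
#'   `class_ratios.tsv`, `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  log <- if (quiet) function(...) invisible() else message
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- c(); digests <- list()
  tick <- function(stage) {
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    t0 <<- proc.time()[["elapsed"]]
  }

  if (config$input$mode == "simulate") {
    study <- make_fixture(config$input$fixture %||% "tiny",
                          seed = stage_seed(config$seed, "simulate"))
    ft <- study$feature_table; preds <- study$predictions
    metadata <- study$metadata
  } else {
    ft <- read_quant_table(config$input$quant)
    metadata <- read_metadata(config$input$metadata)
    preds <- read_predictions(config$input$fp, config$input$cc,
                              config$input$defs_fp, config$input$defs_cc,
                              metadata)
    digests <- as.list(tools::md5sum(unlist(config$input[
      c("quant", "fp", "cc", "defs_fp", "defs_cc", "metadata")])))
  }
  n_dropped <- sum(ft$mz < config$mz_range[1] | ft$mz > config$mz_range[2])
  log(sprintf("[ingest] %d aligned peaks (%d outside m/z [%g, %g]); %d samples; %d MS/MS entries (%.1f%% coverage)",
              length(ft$peak_id), n_dropped, config$mz_range[1],
              config$mz_range[2], nrow(metadata), nrow(preds$entries),
              100 * nrow(preds$entries) /
                max(1, sum(ft$intensities > 0))))
  tick("ingest")

  matrices <- build_matrices(ft, preds, config, log)
  for (tag in names(matrices))
    write_matrix(matrices[[tag]], file.path(out_dir, paste0("matrix_", tag, ".tsv")))
  tick("build")

  labels_of <- function(m)
    metadata$biome[match(rownames(m), metadata$sample_id)]
  selections <- list()
  for (tag in names(matrices)) {
    sel <- select_features(matrices[[tag]], labels_of(matrices[[tag]]),
                           k = config$selection$k,
                           seed = stage_seed(config$seed, "select"),
                           n_target = config$selection$n_target)
    selections[[tag]] <- sel
    jsonlite::write_json(
      list(method = tag, n_target = sel$n_target,
           fold_sets = sel$fold_sets, rfe1 = sel$rfe1, rfe2 = sel$rfe2),
      file.path(out_dir, paste0("selection_", tag, ".json")),
      auto_unbox = TRUE)
    log(sprintf("[select] %s: N = %d, |rfe1| = %d, |rfe2| = %d",
                tag, sel$n_target, length(sel$rfe1), length(sel$rfe2)))
  }
  tick("select")

  feature_sets <- lapply(selections, function(sel)
    list(full = NULL, rfe1 = sel$rfe1, rfe2 = sel$rfe2))
  report <- evaluate_variants(matrices, feature_sets,
                              labels_of(matrices[[1]]),
                              k = config$evaluation$folds,
                              seed = stage_seed(config$seed, "evaluate"),
                              classifiers = config$evaluation$classifiers)
  data.table::fwrite(report, file.path(out_dir, "evaluation.tsv"), sep = "\t")
  jsonlite::write_json(report, file.path(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA)
  tick("evaluate")

  if ("cc_avg" %in% names(matrices)) {
    crt <- class_ratio_table(matrices[["cc_avg"]], metadata)
    data.table::fwrite(crt$summary, file.path(out_dir, "class_ratios.tsv"),
                       sep = "\t")
  }
  tick("analyze")

  manifest <- list(
    package_version = as.character(utils::packageVersion("ccvkit")),
    config = config,
    seeds = sapply(c("simulate", "build", "select", "evaluate", "analyze"),
                   function(s) stage_seed(config$seed, s)),
    input_digests = digests,
    stage_seconds = as.list(timings))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
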