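#' Configuration for a synthetic untargeted LC-MS/MS study
#'
#' The generator emulates the data layer downstream of an MS/MS annotation
#' engine: an aligned feature quantification table, per-(sample, peak)
#' probabilistic fingerprint and compound class vectors, and biome/contributor
#' metadata. Defaults mirror the conditions of a large cross-biome survey:
#' 11 biomes, 5,899 fingerprint bits, 2,723 compound class bits, about 62%
#' MS/MS coverage of detected peaks, variable per-sample peak counts, and an
#' optional contributor sub-cluster inside one biome.
#'
#' @param n_biomes number of biomes, default 11.
#' @param samples_per_biome samples per biome, default 10 (desk scale).
#' @param peaks_per_sample integer range of detected peaks per sample,
#'   default `c(200, 2000)`.
#' @param msms_fraction probability that a detected peak has sample-specific
#'   MS/MS, default 0.62.
#' @param n_fingerprint,n_class characteristic counts, defaults 5899 / 2723.
#' @param n_informative informative characteristics per biome and kind,
#'   default 5.
#' @param effect_size delta in \[0,1\]: informative characteristics shift
#'   from the shared baseline `p0` to `p0 + delta * (1 - p0)` in their biome.
#'   Default 0.5.
#' @param subgroup `NULL`, or a list with `fraction` (of one biome's
#'   samples), `n_classes` (compound classes carrying the subgroup shift) and
#'   optionally `biome` (defaults to the first biome). Default: fraction 1/3,
#'   4 classes, emulating a second-contributor sub-cluster.
#' @param beta_shape1,beta_shape2 Beta parameters of the shared baseline
#'   probability per characteristic, defaults 0.4 / 5 (mean ~0.07; most
#'   characteristics present in under 10% of peaks).
#' @param concentration per-peak jitter concentration: peak probabilities are
#'   drawn from `Beta(c*p, c*(1-p))` around the sample's profile `p`.
#'   Default 8.
#' @param mz_edges mass bins used to draw precursor m/z values (uniform over
#'   bins, uniform within a bin — peaks spread evenly across the default
#'   seven groups); defaults to [mass_group_scheme()] edges.
#' @param intensity_meanlog,intensity_sdlog log-normal peak-area parameters,
#'   defaults `log(1e5)` and `log(10)` (median 1e5, sigma one decade).
#' @param seed integer seed.
#' @return list of class `study_config`.
#' @export
study_config <- function(n_biomes = 11, samples_per_biome = 10,
                         peaks_per_sample = c(200, 2000),
                         msms_fraction = 0.62,
                         n_fingerprint = 5899, n_class = 2723,
                         n_informative = 5, effect_size = 0.5,
                         subgroup = list(fraction = 1/3, n_classes = 4),
                         beta_shape1 = 0.4, beta_shape2 = 5,
                         concentration = 8,
                         mz_edges = c(100, 250, 300, 350, 400, 450, 550, 900),
                         intensity_meanlog = log(1e5),
                         intensity_sdlog = log(10),
                         seed = 1) {
  cfg <- as.list(environment())
  if (cfg$msms_fraction <= 0 || cfg$msms_fraction > 1)
    stop("config error: msms_fraction must lie in (0, 1]")
  if (cfg$effect_size < 0) stop("config error: effect_size must be >= 0")
  if (any(c(n_biomes, samples_per_biome, n_fingerprint, n_class,
            n_informative, peaks_per_sample) < 1))
    stop("config error: all counts must be >= 1")
  n_sub <- if (is.null(subgroup)) 0 else subgroup$n_classes
  if (n_biomes * n_informative > n_fingerprint ||
      n_biomes * n_informative + n_sub > n_class)
    stop("config error: n_informative x n_biomes (plus subgroup classes) ",
         "exceeds the number of characteristics")
  class(cfg) <- "study_config"
  cfg
}

draw_probs <- function(profile, n_rows, concentration) {
  p <- pmin(pmax(profile, 1e-4), 1 - 1e-4)
  nc <- length(p)
  m <- matrix(rbeta(nc * n_rows, concentration * p, concentration * (1 - p)),
              nrow = nc)
  t(m)
}

#' Generate a complete synthetic study
#'
#' Generative model: each characteristic gets a shared baseline presence
#' probability `p0 ~ Beta(a, b)`; each biome shifts its own disjoint set of
#' informative characteristics to `p0 + delta * (1 - p0)`; each peak draws
#' its probability vector from a Beta centred on its sample's profile
#' (per-peak jitter). Detected-peak counts vary per sample, MS/MS is
#' assigned to about `msms_fraction` of each sample's peaks, intensities are
#' log-normal, and precursor m/z is spread evenly over the mass bins. An
#' optional subgroup implants a second compound class profile in a fraction
#' of one biome's samples (recorded as a distinct contributor). Fully
#' reproducible given `seed`.
#'
#' @param config a [study_config()].
#' @return list of class `ccv_study` with `feature_table`, `predictions`,
#'   `metadata`, and `truth` (informative indices per biome and kind,
#'   subgroup membership and classes).
#' @export
generate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  nb <- config$n_biomes
  biomes <- sprintf("biome%02d", seq_len(nb))
  n_fp <- config$n_fingerprint; n_cc <- config$n_class

  fp_defs <- characteristic_defs(seq_len(n_fp), "fingerprint")
  cc_defs <- characteristic_defs(seq_len(n_cc), "compound_class")

  p0_fp <- rbeta(n_fp, config$beta_shape1, config$beta_shape2)
  p0_cc <- rbeta(n_cc, config$beta_shape1, config$beta_shape2)

  ni <- config$n_informative
  inf_fp <- split(sample(n_fp, nb * ni), rep(biomes, each = ni))[biomes]
  inf_cc_pool <- sample(n_cc, nb * ni +
                          (if (!is.null(config$subgroup))
                             config$subgroup$n_classes else 0))
  inf_cc <- split(inf_cc_pool[seq_len(nb * ni)], rep(biomes, each = ni))[biomes]
  sub_classes <- if (!is.null(config$subgroup))
    sort(inf_cc_pool[(nb * ni + 1):length(inf_cc_pool)]) else integer(0)

  shift <- function(p, idx, delta) {
    p[idx] <- p[idx] + delta * (1 - p[idx]); p
  }
  prof_fp <- lapply(biomes, function(b)
    shift(p0_fp, inf_fp[[b]], config$effect_size))
  prof_cc <- lapply(biomes, function(b)
    shift(p0_cc, inf_cc[[b]], config$effect_size))
  names(prof_fp) <- names(prof_cc) <- biomes

  n_samples <- nb * config$samples_per_biome
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  biome_of <- rep(biomes, each = config$samples_per_biome)

  sub_biome <- NULL; sub_members <- character(0)
  if (!is.null(config$subgroup)) {
    sub_biome <- config$subgroup$biome %||% biomes[1]
    in_b <- sample_ids[biome_of == sub_biome]
    n_sub <- max(1L, round(config$subgroup$fraction * length(in_b)))
    sub_members <- sample(in_b, n_sub)
  }
  contributor <- paste0("contrib_", biome_of, "_1")
  contributor[sample_ids %in% sub_members] <- paste0("contrib_", sub_biome, "_2")
  metadata <- sample_metadata(data.frame(
    sample_id = sample_ids, biome = biome_of, contributor = contributor,
    origin = paste0("origin_", biome_of), stringsAsFactors = FALSE))

  # aligned peak universe: pool sized to the largest per-sample count
  pr <- range(config$peaks_per_sample)
  n_pool <- ceiling(1.3 * pr[2])
  pool_mz <- {
    bin <- sample(length(config$mz_edges) - 1, n_pool, replace = TRUE)
    runif(n_pool, config$mz_edges[bin], config$mz_edges[bin + 1])
  }
  pool_rt <- runif(n_pool, 0.5, 15)
  peak_ids <- as.character(seq_len(n_pool))

  inten <- matrix(0, n_pool, n_samples,
                  dimnames = list(peak_ids, sample_ids))
  entries <- vector("list", n_samples)
  fp_rows <- vector("list", n_samples)
  cc_rows <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    n_det <- if (pr[1] == pr[2]) pr[1] else sample(pr[1]:pr[2], 1)
    det <- sort(sample(n_pool, n_det))
    inten[det, i] <- rlnorm(n_det, config$intensity_meanlog,
                            config$intensity_sdlog)
    has_ms2 <- det[rbinom(n_det, 1, config$msms_fraction) == 1]
    if (!length(has_ms2)) next
    entries[[i]] <- data.frame(sample_id = sample_ids[i],
                               peak_id = peak_ids[has_ms2],
                               mz = pool_mz[has_ms2],
                               stringsAsFactors = FALSE)
    b <- biome_of[i]
    pf <- prof_fp[[b]]
    pc <- if (sample_ids[i] %in% sub_members)
      shift(prof_cc[[b]], sub_classes, config$effect_size) else prof_cc[[b]]
    fp_rows[[i]] <- draw_probs(pf, length(has_ms2), config$concentration)
    cc_rows[[i]] <- draw_probs(pc, length(has_ms2), config$concentration)
  }
  entries <- do.call(rbind, entries[!vapply(entries, is.null, TRUE)])
  preds <- prediction_set(entries,
                          do.call(rbind, fp_rows[!vapply(fp_rows, is.null, TRUE)]),
                          do.call(rbind, cc_rows[!vapply(cc_rows, is.null, TRUE)]),
                          fp_defs, cc_defs)
  ft <- feature_table(peak_ids, pool_mz, pool_rt, inten)
  truth <- list(informative_fingerprint = inf_fp,
                informative_class = inf_cc,
                baseline_fingerprint = p0_fp, baseline_class = p0_cc,
                subgroup = list(biome = sub_biome, members = sort(sub_members),
                                classes = sub_classes))
  structure(list(feature_table = ft, predictions = preds,
                 metadata = metadata, truth = truth, config = config),
            class = "ccv_study")
}

#' @export
print.ccv_study <- function(x, ...) {
  cat(sprintf(
    "<ccv_study> %d samples, %d biomes, %d aligned peaks, %d MS/MS entries\n",
    nrow(x$metadata), length(attr(x$metadata, "biomes")),
    length(x$feature_table$peak_id), nrow(x$predictions$entries)))
  invisible(x)
}

#' Packaged synthetic fixtures
#'
#' `tiny` (3 biomes x 5 samples, 30-50 peaks, 20 fingerprint + 10 class
#' characteristics) builds in well under a second and drives the fast tests.
#' `default` mirrors the study dimensions of the emulated survey — 11 biomes
#' and the full 5,899 fingerprint / 2,723 compound class characteristic
#' counts — at desk-scale sample and peak numbers.
#'
#' @param name `"tiny"` or `"default"`.
#' @param seed integer seed, default 1.
#' @return A `ccv_study` (see [generate_study()]).
#' @export
make_fixture <- function(name = c("tiny", "default"), seed = 1) {
  name <- match.arg(name)
  cfg <- switch(name,
    tiny = study_config(n_biomes = 3, samples_per_biome = 5,
                        peaks_per_sample = c(30, 50),
                        n_fingerprint = 20, n_class = 10,
                        n_informative = 3, effect_size = 0.6,
                        subgroup = list(fraction = 0.4, n_classes = 1),
                        seed = seed),
    default = study_config(samples_per_biome = 3,
                           peaks_per_sample = c(80, 160),
                           seed = seed))
  generate_study(cfg)
}

#' Write a synthetic study in the package's input formats
#'
#' Emits the quant CSV, prediction/definition TSVs, metadata TSV, and a JSON
#' truth record into a directory.
#'
#' @param study a `ccv_study`.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "ccv_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(quant = file.path(dir, "quant.csv"),
             fp = file.path(dir, "fingerprint_predictions.tsv"),
             cc = file.path(dir, "class_predictions.tsv"),
             defs_fp = file.path(dir, "fingerprint_definitions.tsv"),
             defs_cc = file.path(dir, "class_definitions.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.json"))
  write_quant_table(study$feature_table, paths["quant"])
  write_predictions(study$predictions, paths["fp"], paths["cc"],
                    paths["defs_fp"], paths["defs_cc"])
  write_metadata(study$metadata, paths["metadata"])
  truth <- study$truth
  truth$baseline_fingerprint <- NULL # large and re-derivable from the seed
  truth$baseline_class <- NULL
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
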