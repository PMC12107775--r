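# ccvkit

Chemical characteristics vectors (CCVs) for comparing the chemical space of
untargeted LC–MS/MS samples.

## The problem

Untargeted metabolomics profiles of environmental and host-associated
samples (soil, water, animal gut, plant surface, …) differ enormously in the
number of chromatographic peaks they yield, and most peaks never get a
confident compound identification. That makes sample-to-sample comparison of
*chemistry* — rather than of aligned peak lists — hard. The CCV approach
works at the level of predicted chemical characteristics instead: per-peak
probabilistic molecular fingerprint (MFP, substructure) and compound class
(CC, ontology) predictions, as produced by MS/MS annotation engines, are
binarized at a 0.5 threshold and **averaged within each sample**:

    CCV(s)_j = (1/n_s) * Σ_i 1[ p_ij ≥ 0.5 ]

Entry *j* is the fraction of sample *s*'s MS/MS-characterized peaks
predicted to carry characteristic *j*: a fixed-length vector, comparable
across samples regardless of peak counts, and interpretable (×100 it is
"% of LC–MS peaks in this sample annotated with this class"). A
mass-grouped variant averages within seven precursor *m/z* bins
(100–250, …, 550–900 Th) and concatenates the seven vectors.

`ccvkit` implements the full workflow for six sample representations
(MS1 presence/absence, MS1 log10 intensity, whole-sample and mass-grouped
CCVs for fingerprints and classes):

* I/O for GNPS/MZmine quant CSVs, SIRIUS-style prediction tables keyed by
  `absoluteIndex`, and biome metadata;
* representation building with m/z-window and uniform-feature filtering;
* recursive feature elimination under stratified k-fold CV with
  elbow-selected feature budgets and the `rfe1` (union) / `rfe2`
  (intersection) fold-aggregation rules;
* evaluation: Calinski–Harabasz, Dunn, and silhouette indices on Euclidean
  distances with biome labels as cluster assignments, min-max normalization
  across method variants, PCA, and cross-validated classification with
  random forest (100 trees, Gini), kNN (k = 5), Gaussian naive Bayes with
  uniform priors, plus two trivial baselines;
* interpretation: per-biome compound class ratio distributions, mass-group
  class profiles, and within-biome two-group contrasts with exact/approximate
  Wilcoxon rank-sum tests;
* a synthetic study generator with planted biome effects and a ground-truth
  record, so the whole pipeline is testable without any downloads.

## Worked example

```r
library(ccvkit)

study <- make_fixture("tiny", seed = 42)   # 3 biomes x 5 samples
study
#> <ccv_study> 15 samples, 3 biomes, 65 aligned peaks, 378 MS/MS entries

ccv <- ccv_matrix(study$predictions, "compound_class")
round(unclass(ccv)[1:3, 1:5], 3)
#>      c1 c2    c3    c4    c5
#> S001  0  0 0.000 0.036 0.893
#> S002  0  0 0.741 0.000 0.704
#> S003  0  0 0.792 0.000 0.750
```

Each row is a sample, each entry the fraction of its MS/MS peaks carrying a
class: 89% of S001's characterized peaks are predicted to be class `c5`.
Biome separation and feature selection:

```r
ccv    <- filter_uniform(ccv)
labels <- study$metadata$biome[match(rownames(ccv), study$metadata$sample_id)]
d      <- euclidean_distances(ccv)
calinski_harabasz(ccv, labels)   #> 107.18
dunn_index(d, labels)            #> 2.05
mean_silhouette(d, labels)       #> 0.828

sel <- select_features(ccv, labels, k = 3, seed = 1, n_target = 4)
sel
#> <selection_result> N = 4; 3 folds; |rfe1| = 8, |rfe2| = 1
crossval_classify(ccv, labels, "knn", k = 3, seed = 1)
#> [1] 1
```

The three planted biomes are perfectly separable (kNN accuracy 1.0), and one
class is selected consistently in every fold (`rfe2`). Its per-biome ratio
distribution, in percent of peaks per sample:

```r
class_ratio_table(ccv, study$metadata, sel$rfe2[1])$summary
#>     biome characteristic      mean min      max n
#> 1 biome01            c10 88.128594  75 92.85714 5
#> 2 biome02            c10  6.105852   0 11.53846 5
#> 3 biome03            c10  5.103680   0 10.52632 5
```

The full pipeline (simulate → build 6 matrices → select → evaluate the
18-variant grid → class ratios) runs from one config:

```r
run_pipeline(list(seed = 5, input = list(mode = "simulate", fixture = "tiny"),
                  selection = list(k = 3), evaluation = list(folds = 3)),
             out_dir = "out")
```

or from the command line:

```sh
Rscript inst/cli/ccv simulate --out study/ --fixture tiny --seed 3
Rscript inst/cli/ccv run --config config.json --out out/
```

## Scope notes

Running the MS/MS annotation engines themselves (SIRIUS / CSI:FingerID /
CANOPUS), raw peak picking, and retention-time alignment are out of scope:
the package consumes (or simulates) their tabular outputs. See
`vignettes/ccv-methods.Rmd` for the model, the synthetic generator's
assumptions, and the design decisions.
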