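---
title: "Chemical characteristics vectors: model, assumptions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemical characteristics vectors: model, assumptions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccvkit)
```

## The problem

Untargeted LC–MS/MS profiles of environmental and host-associated samples
differ wildly in complexity: one sample may yield a few hundred aligned
chromatographic peaks, another several thousand. Raw peak lists are therefore
hard to compare directly across samples, and most peaks never receive a
confident structural annotation. The chemical characteristics vector (CCV)
sidesteps per-compound identification: probabilistic molecular fingerprint
(MFP) and compound class (CC) predictions, available for every peak with a
fragmentation spectrum, are binarized and **averaged within a sample**. Entry
$j$ of a sample's CCV is then the *fraction of its MS/MS-characterized peaks
predicted to carry characteristic $j$* — a fixed-length, unit-free vector
comparable across samples regardless of their peak counts.

Formally, for sample $s$ with binarized peak vectors
$b_1, \dots, b_{n_s} \in \{0,1\}^p$:

$$\mathrm{CCV}(s)_j = \frac{1}{n_s} \sum_{i=1}^{n_s} b_{ij}, \qquad
b_{ij} = \mathbf{1}[\,\hat{p}_{ij} \ge t\,],\ t = 0.5 .$$

The mass-grouped variant partitions peaks by precursor $m/z$ into seven bins
(100–250, 250–300, 300–350, 350–400, 400–450, 450–550, 550–900 Th) and
concatenates the per-bin averages, preserving coarse information about where
in the mass range a characteristic lives. The package also builds the two
MS1-only baselines (binary presence/absence, and $\log_{10}$ peak area) so
all six representations can be compared on equal footing; the same $m/z$
window (100–900 Th) is applied to every representation for parity.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `threshold` | 0.5 | probability | Presence call on predicted probabilities; the inclusive convention ($\ge$) is used at the boundary and is configurable. |
| `mz_range` | [100, 900] | Th | Typical small-molecule precursor window; applied to MS1 and CCV branches alike. |
| `mass_group_edges` | 100…900, 7 bins | Th | Chosen so peaks spread roughly evenly over bins in broad surveys. |
| RFE folds `k` | 10 | — | Tenfold cross-validation; fold sets are aggregated as union (`rfe1`) and intersection (`rfe2`). |
| `ntree` / `mtry` | 100 / $\lfloor\sqrt{p}\rfloor$ | — | Random forest with the Gini criterion, used both as the RFE importance engine and as a classifier. |
| kNN `k` | 5 | neighbours | Uniform weights, Euclidean distance. |

## Semantics that required a decision

* **Binarization boundary.** A probability of exactly 0.5 counts as
  *present*. Only "a threshold of 0.5" is conventionally stated for such
  pipelines; the inclusive reading is the common default and is exposed as a
  parameter.
* **Mass bins.** Half-open $[lo, hi)$ with a closed last bin, so touching
  bin edges partition the window with no overlap and every in-range peak
  lands in exactly one bin.
* **Empty bins** contribute an all-zero block rather than being dropped:
  fixed dimensionality is what makes mass-grouped CCVs concatenable and
  comparable; always-zero columns are removed later by `filter_uniform()`,
  which drops any column constant across samples (all zeros *or any other
  identical value*, exact equality).
* **Zero-MS/MS samples** are excluded with a warning instead of emitting an
  all-zero CCV — an all-zero vector would claim "no chemistry" when the
  truth is "no data".
* **log10 of absent peaks.** Absent peaks map to 0 and the logarithm is
  applied only to positive areas, avoiding $-\infty$ while keeping absence
  below any detected peak of area $\ge 1$.
* **Dunn index.** The classic definition (minimum between-cluster pair
  distance over maximum within-cluster diameter) is implemented. Prose
  descriptions of the index sometimes speak of *mean* distances; the widely
  used implementations compute the min/max form, and that is what we match.
  Degenerate zero diameters are floored at `eps = 1e-12`, so duplicated
  clusters give a large finite sentinel rather than an error.
* **"Naive Bayes without prior probabilities"** is read as Gaussian naive
  Bayes with *uniform* class priors: the features are fractions in $[0,1]$
  and the intent of "without prior" is that class frequencies should not
  drive predictions.
* **Elbow rule.** The feature budget $N$ maximizes the perpendicular
  distance to the chord joining the first and last points of the mean sorted
  random-forest importance curve across training folds; ties break toward
  smaller $N$, so a straight or constant curve yields $N = 1$. Which exact
  curve the elbow was applied to is an interpretation on our part and is
  flagged as such.
* **Folds** are stratified by biome and shared across classifiers and
  representations: with many imbalanced classes, unstratified folds can lack
  entire classes, and shared folds make method contrasts paired.
* **Rank-sum test.** Two-sided; the statistic is the rank-sum of group 1.
  Exact by full enumeration when $n_1 + n_2 \le 12$ (cheap:
  $\binom{12}{6} = 924$ arrangements), a tie-corrected normal approximation
  with continuity correction otherwise. When every pooled observation is
  tied the variance is zero and $p = 1$. No multiple-testing correction by
  default (raw p-values are what such analyses report);
  Benjamini–Hochberg is available via `adjust = TRUE`.
* **UMAP** is out of scope: its outputs are non-deterministic across
  back-ends and contribute nothing testable here. PCA (`pca_project()`)
  covers the dimensionality-reduction contract deterministically.

## What the synthetic generator emulates — and what it does not

`generate_study()` produces the three inputs of a real study: a GNPS-style
quant table, SIRIUS-style per-peak probability tables keyed by
`absoluteIndex`, and biome/contributor metadata.

The generative model is deliberately simple and fully stated:

1. Each characteristic draws a **shared baseline** presence probability
   $p_0 \sim \mathrm{Beta}(0.4, 5)$ (mean $\approx 0.07$ — most
   characteristics appear in under 10% of peaks, matching what broad surveys
   report).
2. Each biome owns a disjoint set of `n_informative` characteristics whose
   probability shifts to $p_0 + \delta (1 - p_0)$. The baseline is shared
   across biomes *by design*: with a per-biome baseline draw, even
   $\delta = 0$ worlds would be separable, and the null calibration tests
   would be meaningless.
3. Per peak, probabilities jitter around the sample's profile via
   $\mathrm{Beta}(c\,p,\ c(1-p))$ with concentration $c = 8$ — calibrated
   values in $[0,1]$ with tunable within-sample spread.
4. Detected peak counts vary per sample (default 200–2000); about 62% of a
   sample's peaks carry MS/MS; peak areas are log-normal (median $10^5$,
   one decade sigma); precursor $m/z$ is drawn uniformly over the seven mass
   bins, then uniformly within a bin.
5. An optional subgroup implants a second compound class profile in a
   fraction (default 1/3) of one biome's samples and records them under a
   second contributor — the within-biome sub-cluster structure that
   contributor-level contrasts probe.

The defaults for `n_informative` (5 per biome) reflect that consistently
selected class sets in real surveys amount to a handful of characteristics
per biome. `make_fixture("default")` keeps the real-world *dimensions* that
matter for contracts — 11 biomes, 5,899 fingerprint bits, 2,723 class bits —
but uses desk-scale sample and peak counts (3 samples/biome, 80–160 peaks);
full-scale counts would need multi-gigabyte probability matrices and buy no
additional test power.

Not emulated: mass spectra and fragmentation themselves, retention-time
chromatography, ionization or extraction biases, correlated characteristics
(real fingerprint bits are strongly dependent; ours are conditionally
independent given the profile), and alignment artifacts. A green test
therefore establishes that the *pipeline machinery* is correct under the
stated model — not that the method will separate any particular real
biome pair.

## Numerical choices

* Conservation identity — the whole-sample CCV equals the peak-count
  weighted mean of per-bin CCVs — holds to machine precision and is asserted
  at `1e-12` over random instances.
* Clustering indices are validated to `1e-12` against independent loop-based
  oracles and to hand-computed values on a 1-D toy configuration
  (CH $= 50$, Dunn $= 4$, mean silhouette $\approx 0.7980$).
* Singleton clusters get silhouette 0 (standard convention). CH with zero
  within-cluster variance raises an explicit error rather than returning
  infinity.
* Classifier tie-breaks are deterministic: kNN votes and forest votes
  resolve toward the smallest class label in sorted order.
* Matrix serialization keeps 15 significant digits; round-trips are tested
  at `1e-13` relative tolerance.
* All randomness flows through R's RNG; pipeline stages derive fixed
  substream seeds from the single global seed, so stage outputs are
  reproducible independently of execution order.

## Known limitations

* The random forest is a compact in-package implementation (exhaustive
  split search, grown to purity). It matches the standard algorithm but is
  not tuned for very large feature counts; RFE on tens of thousands of
  features will be slow compared to optimized libraries.
* `rfe2` can legitimately be empty (disjoint fold sets); downstream
  evaluation reports such variants as `NA` with a warning rather than
  failing the whole grid.
* Accuracy values from k-fold cross-validation on a few hundred samples
  carry fold noise of a few percent; paired folds mitigate but do not remove
  it.
* The simulated world cannot reproduce dataset-specific published numbers
  (clustering index magnitudes, per-biome class percentages); only
  structural and calibration properties are claimed.
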