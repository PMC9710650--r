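---
title: "lfqpipe: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lfqpipe: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfqpipe)
```

This vignette documents the statistical machinery of `lfqpipe`, the
assumptions behind it, and the choices made where the design was genuinely
open. The README shows the user-facing workflow; here we explain *why* the
pieces look the way they do.

## Data model

The central container is the `intensity_table`: a proteins × samples matrix
of **log2** intensities with `NA` marking missing values. Three conventions
are fixed at import and everything downstream relies on them:

* **Detection.** A protein is detected in a sample iff its raw intensity is
  strictly positive. A raw 0 is *not* treated as `log2(0)`; it becomes a
  missing value. In data-dependent acquisition, a zero means the peptide was
  not selected/identified, not that the protein is absent, and the dropout
  probability rises as abundance falls — a missing-not-at-random mechanism.
* **Log scale.** All normalizations are formulated as subtraction of
  per-sample medians or means, which is only meaningful on a log scale, so
  the log2 transform happens once, at import.
* **Filtering.** Rows flagged `+` in any of `Only identified by site`,
  `Reverse`, `Potential contaminant` are dropped — the de facto standard
  treatment of a MaxQuant table. Absent flag columns are tolerated with a
  warning so that minimal tables remain readable.
* **Identifiers.** The first entry of `Gene names` names the protein group;
  rows sharing a symbol are aggregated by **summing raw intensities before
  the log transform** (intensity is additive on the linear scale, so this is
  the physically coherent collision rule); rows without a gene name fall
  back to the majority-protein accession.

Sample names encode the experimental hierarchy (`line_treatment_replicate`
by default, separator configurable). `build_design()` turns them into a tree
whose *levels* define the groupings all analyses use. Group names are joined
prefixes, which makes them unique by construction.

## The detection threshold

Group comparisons must not be driven by proteins observed only sporadically.
The required detected fraction for a group of $n$ samples is

$$
f(n) = \begin{cases}
1 & n \le n_{\text{full}} \\
0.5 & n \ge n_{\text{half}} \\
0.5 + 0.5\,\sigma\!\big(-k\,(n - m)\big) & \text{otherwise,}
\end{cases}
$$

with $\sigma$ the standard logistic, midpoint $m = (n_{\text{full}} +
n_{\text{half}})/2 = 7.5$ samples and rate $k$ (per sample). Defaults:
$n_{\text{full}} = 3$, $n_{\text{half}} = 12$, $k = 1$. Only the two
endpoints are normative for the method — full detection required up to
triplicates, half detection from 12 samples on; the connecting curve was an
open choice. We use a logistic because it is smooth, monotone and
"sigmoidal" in the ordinary sense, and we hard-clamp the two plateaus so the
endpoints hold exactly rather than asymptotically. $k = 1$ per sample makes
the transition essentially complete within the open interval (4–11 samples).
The minimum count is $\lceil f(n)\, n\rceil$: the ceiling guarantees the
threshold is never met with fewer detections than the fraction implies.

For two groups the per-protein label is:

* `comparable` — above threshold in both groups;
* `unique_in_A` / `unique_in_B` — above threshold on one side and **zero**
  detections on the other;
* `not_considered` — everything else.

The ambiguous case (above threshold in A, detected but below threshold in B)
is deliberately `not_considered`: "unique" requires utter absence, and
"comparable" requires both sides above threshold. Totality and symmetry of
this labeling are property-tested by exhaustive enumeration over all
detection-count pairs for group sizes up to 15.

## Normalization

All five strategies operate on log2 intensities and restore the missing mask
bit-exactly:

* `median_norm` subtracts from each sample the difference between its median
  and the grand mean of sample medians. After it, all sample medians agree
  (to numerical precision; tested at 1e−9).
* `quantile_norm` ranks each sample, averages intensities per rank across
  samples, and assigns the rank means back. Ties receive the average of the
  adjacent rank means (the standard convention; the method description is
  silent on ties). On complete data the sorted vectors of all samples are
  identical afterwards.
* `trqn` ("tail-robust" quantile normalization) centers each sample by its
  mean, quantile-normalizes, and adds the means back, protecting the
  distribution tails from over-flattening. `trmn` is the same wrapper around
  median normalization.
* Missing-value handling (`*_missing_handled`): missing cells are
  temporarily filled by sampling **with replacement from the same sample's
  observed values** (seeded), the complete matrix is normalized, and the
  cells are set back to missing. Per-sample (rather than global) sampling
  was chosen because each sample's intensity distribution is exactly what
  quantile normalization operates on; filled values never leave the module.
* Plain `quantile_norm`/`trqn` **refuse** matrices containing missing values
  instead of silently dropping rows — with unequal missing counts the
  columns effectively have different lengths, which is precisely the problem
  the missing-handling variants exist to solve.

Degenerate inputs: a sample with no observed values cannot be normalized and
raises an error naming the sample; an empty (all-filtered) table flows
through the pipeline and fails per-analysis, not globally.

## Moderated differential statistics

For each comparable protein with at least two observations per group we
compute group means, the log2 fold change (first-named group minus second),
and the pooled residual variance $s_g^2$ on $d_g$ degrees of freedom. The
variances are then shrunk by empirical Bayes: assuming a scaled
inverse-$\chi^2$ prior with $d_0$ degrees of freedom and scale $s_0^2$, the
posterior variance is

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$$

and the moderated $t = \Delta / \sqrt{\tilde s_g^2 (1/n_A + 1/n_B)}$ has
$d_0 + d_g$ degrees of freedom. $(d_0, s_0^2)$ are estimated by the method of
moments on $\log s_g^2$ (Smyth-style, using digamma/trigamma identities for
the log-$\chi^2$ moments, with a Newton solver for the trigamma inverse).
With `trend = TRUE` (the volcano default) the prior scale is a function of
average log2 intensity, fitted by `lowess` with span 0.3 — this is the
correction for the intensity–variance relationship of MS data. Numerical
conventions, chosen to match the established empirical-Bayes practice and
verified against the limma implementation in the test suite (limma is used
only as a cross-check oracle, never called by the package code):

* if the observed dispersion of $\log s_g^2$ does not exceed its sampling
  noise, $d_0 = \infty$ and the prior scale is the plain mean of the
  variances (constant case) or the trend fit (trend case);
* the total degrees of freedom are capped at the summed residual df of the
  fit, so the infinite-prior limit stays finite;
* proteins with zero residual variance are excluded from the moment
  estimation but still receive a posterior variance.

Limiting cases are tested: $d_0 = 0$ reproduces the ordinary pooled t-test
to 1e−9, $d_0 = \infty$ returns the prior for every protein, and on null
simulations (500 proteins, 4 vs 4) the type-I error at $p < 0.05$ lies within
the binomial 99% interval around 0.05.

The remaining kernels are deliberately bought, not built: the ordinary
two-sample test is `t.test(var.equal = TRUE)` (two-sided, pooled variance —
the scientific default where only "independent t-test" is specified),
Benjamini–Hochberg is `p.adjust(method = "BH")`, the one-tailed Fisher exact
test is the upper hypergeometric tail via `phyper`, PCA is `prcomp`, and
Pearson correlation is `cor`. Each is still covered by an independent oracle
in the tests (closed-form pooled formula, hand-computed step-up values,
combinatorial `choose()` enumeration for all tables with margins ≤ 20).

## Analysis catalogue conventions

* **Relative SD** is computed on the **linear** scale ($2^{\log_2 x}$): a
  coefficient of variation of log-scale values is not scale-meaningful. The
  x-axis stays in log2 for readability. Only above-threshold proteins with
  at least two observations enter.
* **Rank percentiles** use $100\,i/(N-1)$ over proteins sorted by
  descending group-mean intensity ($i$ zero-based), so the most abundant
  protein is exactly 0% and the least abundant exactly 100%; a single
  protein gets 0%.
* **PCA** uses only proteins observed in every sample (complete case) — no
  imputation is allowed to leak into the ordination.
* **GO enrichment** builds the 2×2 table within the *measured background*
  (all proteins of the filtered table): in-term vs not × detected in the
  group (≥ 1 sample) vs not, one-tailed toward enrichment. The measured
  background is the defensible universe when the input is a single
  proteinGroups table; a whole-genome background would inflate enrichment.
* **Pathway/GO membership** is by exact, case-insensitive gene-symbol match;
  term lists are flat text files (one symbol per line, filename = term).
* **Venn diagrams** support up to 6 sets (bars with an intersection label;
  classic circles for ≤ 3); beyond that the regions are uninterpretable and
  the call errors.
* **Volcano** plots $-\log_{10}$ of the *unadjusted* p against log2 fold
  change (the adjusted p is in the CSV and drives significance coloring and
  top-10 annotation); unique proteins appear on the sides at their group
  mean intensities.

## Reproducibility machinery

`run_pipeline()` validates the configuration before writing anything, runs
each analysis in isolation (an error is logged and the remaining analyses
still run), and writes per analysis one PDF and one CSV holding the plotted
numbers. The full configuration, including the package version, is saved as
YAML; timestamps live only in the run log, so re-running with the same
config and seed produces byte-identical CSVs — this determinism is asserted
in the test suite. All randomness (missing-value sampling) flows from
explicit seeds in the configuration.

## The synthetic-data generator

`generate_fixture()` writes a MaxQuant-dialect table with known ground
truth. The model: per-protein base abundance $\sim N(25, 2)$ on the log2
scale (the magnitude of typical MaxQuant raw intensities), per-sample
systematic shifts $\sim N(0, 0.2)$, replicate noise $\sim N(0, 0.3)$, an
optional planted shift (default 1 log2 unit in a chosen cell line), and
intensity-dependent dropout with probability
$\operatorname{logit}^{-1}(k_d(m_d - x))$ (midpoint $m_d = 21$, steepness
$k_d = 1$ per log2 unit) — left-censoring, the regime the detection
threshold exists for. The default design is 2 lines × 3 treatments × 2
replicates (12 samples). Flags are planted in configurable fractions
(5%/2%/2% contaminant/reverse/site).

What it emulates: column dialect, zero-encoded missingness, monotone
intensity-dependent dropout, systematic sample shifts, planted effects and
flags — enough to verify every module against bookkeeping rather than
against itself. What it does **not** emulate: peptide-level quantification
noise structure, correlated protein co-regulation, shared peptides between
protein groups, differing values across the three intensity flavors (the
generator writes identical values for all three, a documented
simplification), or batch effects. Passing tests therefore demonstrate
algorithmic correctness on the stated model, not performance on any
particular real dataset.

Test problem sizes were chosen to keep the suite fast while leaving no
estimator starved: 100–1000 proteins, 6–12 samples, 500-protein null and
recovery simulations. On the recovery fixture (10% of proteins shifted by 1
log2 unit, σ = 0.3, 4 vs 4) the volcano ranking is required to achieve
AUROC > 0.95 and >90% recall at adjusted p < 0.05 — property-level bars
computed by the tests themselves.

## Known limitations

* Only the MaxQuant proteinGroups dialect is parsed natively; other formats
  enter through the documented reader interface (see `?reader-interface`).
* No peptide-level modeling, no imputation for inference (filled values are
  confined to normalization), no multi-group F-statistics or permutation
  tests, no GO-DAG propagation (term lists are flat), no label-based or DIA
  designs.
* The logistic shape and steepness of the threshold interpolation between
  the fixed endpoints is a package convention; analyses near the boundary
  group sizes (4–11 samples) inherit it.
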