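# lfqpipe

Downstream analysis of label-free quantitative (LFQ) shotgun-proteomics data
in R. `lfqpipe` picks up where MaxQuant stops: it imports a
`proteinGroups.txt`-style table of per-sample protein intensities (raw
`Intensity`, `LFQ intensity` or `iBAQ` columns), filters decoys,
contaminants and site-only identifications, and runs a standardized,
fully reproducible catalogue of quality-control, exploratory and
differential analyses. Every analysis is written both as a PDF figure and as
a CSV file holding exactly the plotted numbers, and the complete run
configuration (all parameters plus the package version) is saved alongside,
so any result can be regenerated bit-for-bit.

It is aimed at proteomics labs that need consistent QC and differential
analysis across many experiments without hand-rolled scripts.

## The method in brief

* **Analysis design tree.** Sample names such as `LineA_treated_r1` are split
  on a separator into components (cell line / treatment / replicate …),
  forming a rooted tree. Choosing a *level* slices the samples into groups —
  level 0 groups by cell line, level 1 by line+treatment, and so on. Every
  analysis operates on the groups of the selected level.
* **Detection thresholding.** In label-free MS, proteins drop out
  preferentially at low intensity (missing not at random), so a protein is
  only used in a group comparison if it is detected (raw intensity > 0) in
  enough samples of the group. The required fraction *f(n)* of a group of
  *n* samples is sigmoidal: *f(n) = 1* for *n ≤ 3*, *f(n) = 0.5* for
  *n ≥ 12*, and *f(n) = 0.5 + 0.5·σ(−k(n − 7.5))* in between (logistic σ,
  rate *k* = 1 per sample). The minimum count is ⌈*f(n)·n*⌉. For a pair of
  groups this yields four scenarios per protein: **comparable** (above
  threshold in both), **unique** to one side (above threshold there, zero
  detections on the other), or **not considered**.
* **Normalization.** Five strategies on log2 intensities, all preserving the
  missing-value mask: `median_norm`, `quantile_norm_missing_handled`,
  tail-robust quantile normalization `trqn` (+ `trqn_missing_handled`) and
  tail-robust median normalization `trmn`, plus `none`. Missing-value
  handling temporarily fills gaps by sampling from the sample's own observed
  intensity distribution (seeded), then restores them.
* **Differential analysis.** Comparable proteins get an empirical-Bayes
  moderated t-statistic: per-protein variances *s²_g* (df *d_g*) are shrunk
  toward a prior *s₀²(ā)* that follows the intensity–variance trend (lowess
  on average log2 intensity), giving the posterior variance
  *(d₀s₀² + d_g s²_g)/(d₀ + d_g)* and *d₀ + d_g* degrees of freedom; p-values
  are Benjamini–Hochberg adjusted. Unique proteins are reported on the sides
  of the volcano plot with their group intensities.
* **Catalogue.** Detection counts, detected-per-sample, sample/group Venn
  diagrams, PCA (complete-case proteins), intensity histograms, relative SD
  (computed on the linear scale), replicate scatter (Pearson r²), thresholded
  group-vs-group comparison, intensity rank plots (0% = most abundant),
  pathway intensity plots with pairwise t-tests, GO term detection counts
  with one-tailed Fisher enrichment tests, and the volcano analysis.

## Worked example

```r
library(lfqpipe)

# a synthetic MaxQuant-style table: 1000 proteins, 2 cell lines x 4
# replicates, 10% of proteins shifted by 1 log2 unit in line L2
spec  <- fixture_spec(n_proteins = 1000, n_lines = 2, n_treatments = 1,
                      n_replicates = 4, effect_fraction = 0.1, seed = 42)
truth <- generate_fixture(spec, "proteinGroups.txt")

tab <- to_intensity_table(filter_protein_groups(
  read_protein_groups("proteinGroups.txt", flavor = "lfq")))
tab
#> intensity_table (lfq, log2): 910 proteins x 8 samples, 481 missing values
tab <- apply_normalization(tab, "median_norm")

design <- build_design(sample_names(tab))
groups <- groups_at_level(design, 0)   # L1 vs L2
pol <- threshold_policy()
required_count(pol, 4)
#> [1] 4    # groups of 4: every replicate must show a detection

res <- volcano(groups$L1, groups$L2, tab, pol, name_a = "L1", name_b = "L2")
table(res$category)
#> comparable   excluded
#>        656        254
sum(res$adj_p_value < 0.05, na.rm = TRUE)
#> [1] 51
head(res[order(res$adj_p_value),
         c("protein", "log2_fc", "p_value", "adj_p_value")], 3)
#>      protein log2_fc  p_value adj_p_value
#> 529 GENE0589   -1.42 4.29e-11    2.81e-08
#> 300 GENE0333   -1.32 8.76e-10    2.87e-07
#> 738 GENE0812   -1.33 5.78e-09    1.26e-06
```

Of the 910 surviving protein groups, 656 are detected often enough in both
lines to be compared; 51 reach an adjusted p below 0.05, with negative log2
fold changes (L1 − L2) of about −1 — the planted up-shift in L2. The same
run via the driver writes one PDF + CSV per analysis plus `config.yml` and
`run.log`:

```r
cfg <- default_config(input_path = "proteinGroups.txt", output_dir = "out")
run_pipeline(cfg)   # 13 analyses
qc_report(cfg)      # one multi-page QC PDF
```

A shell entry point with the same functionality lives in
`inst/scripts/lfqpipe.R` (`analyze`, `qc`, `list-analyses`, `make-fixture`).

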