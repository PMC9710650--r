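# Shared helpers: in-code fixtures and independent reference implementations.

# intensity_table from a plain matrix, labelling rows/columns if absent
make_tab <- function(m, flavor = "lfq") {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("G", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("S", seq_len(ncol(m)))
  intensity_table(m, flavor = flavor)
}

# Write a minimal hand-rolled proteinGroups file; intensities is a matrix of
# RAW (linear) intensities with sample names as colnames.
write_mini_pg <- function(intensities, genes = NULL, flags = NULL,
                          path = tempfile(fileext = ".txt"),
                          prefix = "Intensity ") {
  n <- nrow(intensities)
  genes <- genes %||% paste0("G", seq_len(n))
  df <- data.frame(`Protein IDs` = paste0("P", seq_len(n)),
                   `Majority protein IDs` = paste0("P", seq_len(n)),
                   `Gene names` = genes,
                   `Only identified by site` = rep("", n),
                   Reverse = rep("", n),
                   `Potential contaminant` = rep("", n),
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(flags)) for (cn in names(flags)) df[[cn]] <- flags[[cn]]
  for (j in seq_len(ncol(intensities))) {
    df[[paste0(prefix, colnames(intensities)[j])]] <-
      sprintf("%.12g", intensities[, j])
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Naive quantile normalization reference: sort, average, reassign by rank
# (complete, tie-free matrices only).
naive_quantile_norm <- function(m) {
  means <- rowMeans(apply(m, 2, sort))
  apply(m, 2, function(col) means[rank(col)])
}

# Naive BH step-up reference.
naive_bh <- function(p) {
  n <- length(p)
  ord <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[ord] * n / rank(p)[ord]))
  out <- numeric(n)
  out[ord] <- adj
  out
}

# Brute-force upper-tail hypergeometric by direct combinatorial enumeration:
# probability of drawing >= x in-term proteins when k of (m + n) proteins are
# detected and m are in the term.
brute_hyper_upper <- function(x, m, n, k) {
  supp <- max(0, k - n):min(k, m)
  probs <- choose(m, supp) * choose(n, k - supp) / choose(m + n, k)
  sum(probs[supp >= x])
}

# AUROC of scores for recovering a logical label (Mann-Whitney formulation);
# larger score = more confident positive.
auroc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label)
  n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
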