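pol <- threshold_policy()

test_that("detection counts histogram matches the planted pattern", {
  m <- rbind(G1 = c(1, 2, 3),    # detected in all 3
             G2 = c(1, NA, 2),   # in 2
             G3 = c(NA, NA, 4),  # in 1
             G4 = c(NA, NA, NA)) # never: absent from histogram and total
  colnames(m) <- c("A_1", "A_2", "A_3")
  tab <- intensity_table(m, "lfq")
  res <- detection_counts(list(A = colnames(m)), tab)
  expect_equal(res$n_proteins, c(1L, 1L, 1L))
  expect_equal(unique(res$group_total), 3L)

  spec <- fixture_spec(n_proteins = 120, dropout_midpoint = 23,
                       contaminant_fraction = 0, reverse_fraction = 0,
                       site_fraction = 0, seed = 21)
  truth <- generate_fixture(spec, tempfile(fileext = ".txt"))
  tab <- to_intensity_table(filter_protein_groups(
    read_protein_groups(truth$path, "lfq")))
  groups <- groups_at_level(build_design(sample_names(tab)), 0)
  res <- detection_counts(groups, tab)
  for (g in names(groups)) {
    planted <- rowSums(!truth$missing_mask[, groups[[g]], drop = FALSE])
    sub <- res[res$group == g, ]
    expect_equal(sub$n_proteins,
                 vapply(sub$times_detected, function(k) sum(planted == k),
                        integer(1L)))
    expect_equal(unique(sub$group_total), sum(planted > 0))
  }
})

test_that("detected proteins per sample, totals and group averages", {
  m <- rbind(G1 = c(1, 2, NA, NA), G2 = c(3, NA, NA, NA),
             G3 = c(5, 6, NA, NA))
  colnames(m) <- c("A_1", "A_2", "B_1", "B_2")
  tab <- intensity_table(m, "lfq")
  res <- detected_per_sample(list(A = c("A_1", "A_2"),
                                  B = c("B_1", "B_2")), tab)
  expect_equal(res$n_detected, c(3L, 2L, 0L, 0L))
  expect_equal(res$group_total, c(3L, 3L, 0L, 0L))
  expect_equal(res$group_average, c(2.5, 2.5, 0, 0))
})

test_that("Venn regions are disjoint, complete and match brute-force set algebra", {
  m <- rbind(G1 = c(1, 1, 1), G2 = c(2, 2, NA), G3 = c(3, NA, NA),
             G4 = c(NA, 4, 4))
  colnames(m) <- c("s1", "s2", "s3")
  tab <- intensity_table(m, "lfq")
  res <- venn_within_group(colnames(m), tab)
  regions <- setNames(strsplit(res$proteins, ";", fixed = TRUE), res$region)
  regions <- lapply(regions, function(x) x[nzchar(x)])
  expect_equal(sort(regions[["s1&s2&s3"]]), "G1")
  expect_equal(sort(regions[["s1&s2"]]), "G2")
  expect_equal(sort(regions[["s1"]]), "G3")
  expect_equal(sort(regions[["s2&s3"]]), "G4")
  # disjoint and complete
  all_ids <- unlist(regions)
  expect_equal(anyDuplicated(all_ids), 0L)
  expect_setequal(all_ids, c("G1", "G2", "G3", "G4"))
  expect_equal(attr(res, "style"), "classic")

  # two identical samples: only the full intersection is populated
  m2 <- rbind(G1 = c(1, 1), G2 = c(2, 2))
  colnames(m2) <- c("x", "y")
  res2 <- venn_within_group(c("x", "y"), intensity_table(m2, "lfq"))
  expect_equal(res2$n_proteins[res2$region == "x&y"], 2L)
  expect_true(all(res2$n_proteins[res2$region != "x&y"] == 0L))
})

test_that("randomized Venn regions agree with direct set algebra for k = 4..6", {
  set.seed(22)
  for (k in 4:6) {
    m <- matrix(rnorm(60 * k, 25, 2), 60, k)
    m[matrix(runif(60 * k) < 0.3, 60, k)] <- NA
    tab <- make_tab(m)
    res <- venn_within_group(colnames(tab$matrix), tab)
    expect_equal(attr(res, "style"), "bar")
    sets <- lapply(colnames(tab$matrix),
                   function(s) protein_ids(tab)[!is.na(tab$matrix[, s])])
    names(sets) <- colnames(tab$matrix)
    for (r in seq_len(nrow(res))) {
      members <- strsplit(res$region[r], "&", fixed = TRUE)[[1L]]
      expected <- Reduce(intersect, sets[members])
      for (other in setdiff(names(sets), members)) {
        expected <- setdiff(expected, sets[[other]])
      }
      got <- strsplit(res$proteins[r], ";", fixed = TRUE)[[1L]]
      expect_setequal(got[nzchar(got)], expected)
    }
  }
})

test_that("more than six Venn sets is an unsupported-cardinality error", {
  m <- matrix(1, 3, 7)
  tab <- make_tab(m)
  expect_error(venn_within_group(colnames(tab$matrix), tab),
               class = "unsupported_cardinality_error")
  groups7 <- setNames(as.list(colnames(tab$matrix)), paste0("g", 1:7))
  expect_error(venn_between_groups(groups7, tab, pol),
               class = "unsupported_cardinality_error")
})

test_that("group Venn applies the detection threshold per group", {
  # 3-sample groups: protein must be detected in all 3 to enter the set
  m <- rbind(G1 = c(1, 1, 1, 2, 2, 2),   # above in both
             G2 = c(1, 1, 1, NA, NA, 2), # above only in A
             G3 = c(1, NA, NA, NA, 2, 2))
  colnames(m) <- c("A_1", "A_2", "A_3", "B_1", "B_2", "B_3")
  tab <- intensity_table(m, "lfq")
  res <- venn_between_groups(list(A = colnames(m)[1:3],
                                  B = colnames(m)[4:6]), tab, pol)
  regions <- setNames(strsplit(res$proteins, ";"), res$region)
  expect_setequal(regions[["A&B"]], "G1")
  expect_setequal(regions[["A"]], "G2")
  expect_equal(res$n_proteins[res$region == "B"], 0L)

  single <- venn_between_groups(list(A = colnames(m)[1:3]), tab, pol)
  expect_equal(single$n_proteins, 2L)  # G1 and G2 above threshold in A
})

test_that("PCA uses complete-case proteins and separates planted clusters", {
  set.seed(23)
  base <- rnorm(100, 25, 1)
  m <- sapply(1:6, function(j) base + rnorm(100, 0, 0.1))
  m[1:50, 4:6] <- m[1:50, 4:6] + 4  # strong cluster shift
  colnames(m) <- c("A_1", "A_2", "A_3", "B_1", "B_2", "B_3")
  rownames(m) <- paste0("G", 1:100)
  m[60, 1] <- NA  # incomplete protein must be excluded
  tab <- intensity_table(m, "lfq")
  groups <- list(A = colnames(m)[1:3], B = colnames(m)[4:6])
  res <- pca_overview(groups, tab)
  expect_equal(attr(res, "n_proteins_used"), 99L)
  ev <- attr(res, "explained_variance")
  expect_true(all(ev >= 0) && sum(ev) <= 1 + 1e-12)
  # PC1 separates the groups (sign is arbitrary up to reflection)
  pc1_a <- res$PC1[res$group == "A"]
  pc1_b <- res$PC1[res$group == "B"]
  expect_true(max(pc1_a) < min(pc1_b) || min(pc1_a) > max(pc1_b))

  # duplicated samples project to identical coordinates
  m2 <- cbind(X_1 = base, X_2 = base, Y_1 = base + 1)
  rownames(m2) <- paste0("G", 1:100)
  res2 <- pca_overview(list(X = c("X_1", "X_2"), Y = "Y_1"),
                       intensity_table(m2, "lfq"))
  expect_equal(res2$PC1[1], res2$PC1[2], tolerance = 1e-9)

  few <- intensity_table(rbind(G1 = c(s1 = 1, s2 = 2)), "lfq")
  expect_error(pca_overview(list(g = c("s1", "s2")), few), "fewer than 2")
})

test_that("intensity histogram counts every observed value exactly once", {
  set.seed(24)
  m <- matrix(rnorm(400, 25, 2), 100, 4)
  m[sample(400, 60)] <- NA
  colnames(m) <- c("A_1", "A_2", "B_1", "B_2")
  rownames(m) <- paste0("G", 1:100)
  tab <- intensity_table(m, "lfq")
  groups <- list(A = c("A_1", "A_2"), B = c("B_1", "B_2"))
  res <- intensity_histogram(groups, tab, bins = 20)
  for (s in colnames(m)) {
    expect_equal(sum(res$count[res$sample == s]), sum(!is.na(m[, s])))
  }
  # group mean marker equals the mean over the group's observed values
  expect_equal(unique(res$group_mean_intensity[res$group == "A"]),
               mean(m[, 1:2], na.rm = TRUE))
  # bin edges identical across samples (shared, reproducible binning)
  edges <- unique(res[, c("bin_left", "bin_right")])
  expect_equal(nrow(edges), 20L)
})

test_that("relative SD is computed on the linear scale for thresholded proteins", {
  m <- rbind(G1 = c(3, 3, 3),            # constant: rsd 0
             G2 = c(1, 2, 3),            # hand-computed below
             G3 = c(5, NA, NA))          # below threshold: excluded
  colnames(m) <- c("A_1", "A_2", "A_3")
  tab <- intensity_table(m, "lfq")
  res <- relative_sd(list(A = colnames(m)), tab, pol)
  expect_setequal(res$protein, c("G1", "G2"))
  expect_equal(res$rsd_percent[res$protein == "G1"], 0)
  lin <- 2^c(1, 2, 3)
  expect_equal(res$rsd_percent[res$protein == "G2"],
               sd(lin) / mean(lin) * 100, tolerance = 1e-12)
  expect_equal(unique(res$n_below_10), 1L)
  expect_equal(unique(res$n_below_30), 1L)
})

test_that("replicate scatter pairs carry r2 and per-sample unique proteins", {
  set.seed(25)
  m <- matrix(rnorm(200, 25, 2), 100, 2)
  colnames(m) <- c("A_1", "A_2")
  rownames(m) <- paste0("G", 1:100)
  m[1, 2] <- NA   # G1 unique to A_1
  m[2, 1] <- NA   # G2 unique to A_2
  tab <- intensity_table(m, "lfq")
  res <- scatter_replicates(list(A = colnames(m)), tab)
  expect_equal(nrow(res), 1L)
  expect_equal(res$n_shared, 98L)
  both <- !is.na(m[, 1]) & !is.na(m[, 2])
  expect_equal(res$r_squared, pearson_r2(m[both, 1], m[both, 2]),
               tolerance = 1e-12)
  expect_equal(res$unique_x, "G1")
  expect_equal(res$unique_y, "G2")

  # a duplicated sample correlates perfectly with itself
  m2 <- cbind(B_1 = m[, 1], B_2 = m[, 1])
  res2 <- scatter_replicates(list(B = c("B_1", "B_2")),
                             intensity_table(m2, "lfq"))
  expect_equal(res2$r_squared, 1)
})

test_that("experiment comparison is consistent with the categorization rules", {
  set.seed(26)
  m <- matrix(rnorm(600, 25, 2), 100, 6)
  m[matrix(runif(600) < 0.25, 100, 6)] <- NA
  colnames(m) <- c("A_1", "A_2", "A_3", "B_1", "B_2", "B_3")
  rownames(m) <- paste0("G", 1:100)
  tab <- intensity_table(m, "lfq")
  groups <- list(A = colnames(m)[1:3], B = colnames(m)[4:6])
  res <- experiment_comparison(groups, tab, pol)
  da <- rowSums(!is.na(m[, 1:3]))
  db <- rowSums(!is.na(m[, 4:6]))
  expected <- categorize_detection(da, 3, db, 3, pol)
  names(expected) <- rownames(m)
  expect_setequal(res$protein, names(expected)[expected != "not_considered"])
  expect_equal(res$category, unname(expected[res$protein]))
  comp <- res[res$category == "comparable", ]
  expect_equal(unique(res$r_squared),
               pearson_r2(comp$mean_a, comp$mean_b), tolerance = 1e-12)

  # a group compared against a copy of itself correlates perfectly
  m3 <- cbind(m[, 1:3], C_1 = m[, 1], C_2 = m[, 2], C_3 = m[, 3])
  res3 <- experiment_comparison(list(A = colnames(m3)[1:3],
                                     C = colnames(m3)[4:6]),
                                intensity_table(m3, "lfq"), pol)
  expect_equal(unique(res3$r_squared), 1)
})

test_that("rank percentiles run from 0 at the top to 100 at the bottom", {
  m <- rbind(G1 = c(30, 30), G2 = c(20, 20), G3 = c(10, 10))
  colnames(m) <- c("A_1", "A_2")
  tab <- intensity_table(m, "lfq")
  res <- rank_plot(colnames(m), tab)
  expect_equal(res$protein, c("G1", "G2", "G3"))
  expect_equal(res$rank_percentile, c(0, 50, 100))

  single <- intensity_table(rbind(G1 = c(A_1 = 5, A_2 = 6)), "lfq")
  expect_equal(rank_plot(c("A_1", "A_2"), single)$rank_percentile, 0)

  res_pw <- rank_plot(colnames(m), tab,
                      pathways = list(path1 = c("g1", "G3")))
  expect_equal(res_pw$pathway, c("path1", NA, "path1"))
  expect_equal(unique(res_pw$pathway_median_rank[!is.na(res_pw$pathway)]), 50)
  expect_equal(unique(res_pw$pathway_n_detected[!is.na(res_pw$pathway)]), 2L)
})

test_that("pathway analysis tests only above-threshold group pairs", {
  m <- rbind(G1 = c(1, 2, 3, 1, 2, 3),        # identical groups -> p = 1
             G2 = c(1, 2, 3, NA, NA, 5))      # below threshold in B
  colnames(m) <- c("A_1", "A_2", "A_3", "B_1", "B_2", "B_3")
  tab <- intensity_table(m, "lfq")
  groups <- list(A = colnames(m)[1:3], B = colnames(m)[4:6])
  res <- pathway_analysis(groups, tab, list(pw = c("G1", "G2")), pol)
  expect_equal(res$p_value[res$protein == "G1"], 1)
  expect_true(is.na(res$p_value[res$protein == "G2"]))
  expect_equal(res$p_value[res$protein == "G1"],
               independent_t_test(m[1, 1:3], m[1, 4:6])$p)
})

test_that("GO analysis builds the 2x2 table over the measured background", {
  set.seed(27)
  m <- matrix(rnorm(200, 25, 2), 100, 2)
  colnames(m) <- c("A_1", "A_2")
  rownames(m) <- paste0("G", 1:100)
  m[51:70, ] <- NA  # 20 proteins never detected
  tab <- intensity_table(m, "lfq")
  groups <- list(A = colnames(m))

  # planted enrichment: term = 10 detected proteins
  res <- go_analysis(groups, tab, list(term1 = paste0("G", 1:10)))
  expect_equal(res$n_term_detected, 10L)
  expect_equal(res$term_size, 10L)
  expect_equal(res$p_value, fisher_one_tailed(10, 0, 70, 20),
               tolerance = 1e-12)
  expect_equal(res$p_value, brute_hyper_upper(10, 10, 90, 80),
               tolerance = 1e-12)
  expect_lt(res$p_value, 0.15)

  # term disjoint from the measured proteins
  res0 <- go_analysis(groups, tab, list(none = c("ZZZ1", "ZZZ2")))
  expect_equal(res0$n_term_detected, 0L)
  expect_equal(res0$p_value, 1)
  expect_equal(res0$term_size, 2L)
})

test_that("volcano partitions proteins and reports unique sides", {
  set.seed(28)
  m <- matrix(rnorm(600, 25, 0.5), 100, 6)
  colnames(m) <- c("A_1", "A_2", "A_3", "B_1", "B_2", "B_3")
  rownames(m) <- paste0("G", 1:100)
  m[1, 4:6] <- NA              # unique in A
  m[2, 1:3] <- NA              # unique in B
  m[3, c(2, 3, 4, 5, 6)] <- NA # below threshold both -> excluded
  tab <- intensity_table(m, "lfq")
  res <- volcano(colnames(m)[1:3], colnames(m)[4:6], tab, pol,
                 name_a = "A", name_b = "B")
  expect_equal(nrow(res), 100L)
  expect_true(all(res$category %in% c("comparable", "unique_in_A",
                                      "unique_in_B", "excluded")))
  expect_equal(res$category[1:3], c("unique_in_A", "unique_in_B", "excluded"))
  expect_true(is.na(res$p_value[1]))  # unique proteins are not tested
  expect_equal(res$mean_a[1], mean(m[1, 1:3]))
  expect_true(is.na(res$mean_b[1]))
  expect_lte(sum(res$annotated), 10L)
  comp <- res[res$category == "comparable", ]
  expect_equal(comp$adj_p_value, benjamini_hochberg(comp$p_value))
  # null data: no excess of significant calls
  expect_lt(mean(comp$adj_p_value < 0.05), 0.05)
})

test_that("volcano pathway-annotation mode marks pathway members", {
  set.seed(29)
  m <- matrix(rnorm(240, 25, 0.5), 40, 6)
  colnames(m) <- c("A_1", "A_2", "A_3", "B_1", "B_2", "B_3")
  rownames(m) <- paste0("G", 1:40)
  tab <- intensity_table(m, "lfq")
  res <- volcano(colnames(m)[1:3], colnames(m)[4:6], tab, pol,
                 pathways = list(pw = c("G5", "G6")))
  expect_setequal(res$protein[res$annotated], c("G5", "G6"))
})
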