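# Plot-ready data behind every analysis of the catalogue, computed at a
# chosen level of the analysis design.

.detected <- function(tab) !is.na(tab$matrix)

.check_groups <- function(groups, tab) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  unknown <- setdiff(unlist(groups), sample_names(tab))
  if (length(unknown) > 0L) {
    stop("group samples not in table: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
}

#' Detection-count histograms per group
#'
#' For each group, how many proteins are detected in exactly k of its samples
#' (k = 1..group size), plus the total number of proteins detected at least
#' once in the group.
#'
#' @param groups Named list of sample-name vectors, e.g. from
#'   [groups_at_level()].
#' @param tab An [intensity_table()].
#' @return data.frame with columns \code{group}, \code{times_detected},
#'   \code{n_proteins}, \code{group_total}.
#' @export
detection_counts <- function(groups, tab) {
  .check_groups(groups, tab)
  det <- .detected(tab)
  do.call(rbind, lapply(names(groups), function(g) {
    counts <- rowSums(det[, groups[[g]], drop = FALSE])
    n <- length(groups[[g]])
    k <- seq_len(n)
    data.frame(group = g,
               times_detected = k,
               n_proteins = vapply(k, function(kk) sum(counts == kk),
                                   integer(1L)),
               group_total = sum(counts > 0L),
               stringsAsFactors = FALSE)
  }))
}

#' Detected proteins per sample and per group
#'
#' Per-sample detected-protein counts, with each group's total (proteins
#' detected in at least one of its samples) and the group's average
#' per-sample count (the gray dashed line of the figure).
#'
#' @inheritParams detection_counts
#' @return data.frame with columns \code{group}, \code{sample},
#'   \code{n_detected}, \code{group_total}, \code{group_average}.
#' @export
detected_per_sample <- function(groups, tab) {
  .check_groups(groups, tab)
  det <- .detected(tab)
  do.call(rbind, lapply(names(groups), function(g) {
    s <- groups[[g]]
    per_sample <- colSums(det[, s, drop = FALSE])
    data.frame(group = g, sample = s,
               n_detected = as.integer(per_sample),
               group_total = sum(rowSums(det[, s, drop = FALSE]) > 0L),
               group_average = mean(per_sample),
               stringsAsFactors = FALSE)
  }))
}

# All 2^k - 1 disjoint regions of k named sets. Region names join the member
# set names with "&"; exclusive regions only (their union is the sets' union).
.venn_regions <- function(sets) {
  k <- length(sets)
  if (k > 6L) {
    stop(structure(class = c("unsupported_cardinality_error", "error",
                             "condition"),
                   list(message = paste0("Venn diagrams support at most 6 ",
                                         "sets, got ", k),
                        call = NULL)))
  }
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  patterns <- apply(member, 1L, function(row) paste(which(row), collapse = ","))
  regions <- list()
  for (mask in seq_len(2^k - 1L)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) > 0L)
    key <- paste(names(sets)[idx], collapse = "&")
    regions[[key]] <- universe[patterns == paste(idx, collapse = ",")]
  }
  regions
}

.venn_result <- function(sets) {
  regions <- .venn_regions(sets)
  res <- data.frame(region = names(regions),
                    degree = lengths(strsplit(names(regions), "&",
                                              fixed = TRUE)),
                    n_proteins = lengths(regions),
                    proteins = vapply(regions, paste, character(1L),
                                      collapse = ";"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "style") <- if (length(sets) <= 3L) "classic" else "bar"
  attr(res, "sets") <- sets
  res
}

#' Venn regions of detected proteins across the samples of one group
#'
#' One set per sample: the proteins detected (raw intensity > 0) in it. At
#' most 6 samples (the bar-style limit); a classic circle diagram is used for
#' up to 3.
#'
#' @param group_samples Character vector of sample names (one group).
#' @param tab An [intensity_table()].
#' @return data.frame with one row per nonempty-pattern region: \code{region}
#'   (set names joined by \code{&}), \code{degree}, \code{n_proteins},
#'   \code{proteins} (\code{;}-joined ids). Attribute \code{style} is
#'   \code{"classic"} or \code{"bar"}.
#' @export
venn_within_group <- function(group_samples, tab) {
  .check_groups(list(g = group_samples), tab)
  det <- .detected(tab)
  sets <- lapply(group_samples, function(s) protein_ids(tab)[det[, s]])
  names(sets) <- group_samples
  .venn_result(sets)
}

#' Venn regions of above-threshold proteins across groups
#'
#' One set per group: the proteins whose detection count reaches the
#' [required_count()] for that group's size. At most 6 groups.
#'
#' @inheritParams detection_counts
#' @param policy A [threshold_policy()].
#' @return As [venn_within_group()].
#' @export
venn_between_groups <- function(groups, tab, policy = threshold_policy()) {
  .check_groups(groups, tab)
  det <- .detected(tab)
  sets <- lapply(groups, function(s) {
    counts <- rowSums(det[, s, drop = FALSE])
    protein_ids(tab)[counts >= required_count(policy, length(s))]
  })
  .venn_result(sets)
}

#' PCA overview of samples
#'
#' Principal component analysis on the complete-case matrix: only proteins
#' detected in every sample of the table enter. Samples are projected onto
#' the first two components and labeled with their group.
#'
#' @inheritParams detection_counts
#' @param n_components Number of components to return (>= 2).
#' @return data.frame with columns \code{sample}, \code{group},
#'   \code{PC1}, \code{PC2}, ...; attribute \code{explained_variance}
#'   (fractions) and \code{n_proteins_used}.
#' @export
pca_overview <- function(groups, tab, n_components = 2) {
  .check_groups(groups, tab)
  m <- tab$matrix
  complete <- rowSums(is.na(m)) == 0L
  if (sum(complete) < 2L) {
    stop("fewer than 2 proteins detected in all samples; PCA not possible",
         call. = FALSE)
  }
  if (ncol(m) < 2L) stop("PCA needs at least 2 samples", call. = FALSE)
  pc <- stats::prcomp(t(m[complete, , drop = FALSE]), center = TRUE,
                      scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  grp <- rep(NA_character_, ncol(m))
  names(grp) <- colnames(m)
  for (g in names(groups)) grp[groups[[g]]] <- g
  out <- data.frame(sample = colnames(m), group = grp[colnames(m)],
                    stringsAsFactors = FALSE, row.names = NULL)
  for (j in seq_len(k)) out[[paste0("PC", j)]] <- pc$x[, j]
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  attr(out, "explained_variance") <- ev[seq_len(k)]
  attr(out, "n_proteins_used") <- sum(complete)
  out
}

#' Binned intensity histograms per sample
#'
#' Per-sample histogram of log2 intensities on bin edges shared across the
#' whole table (so samples are comparable), plus each group's mean intensity
#' (the gray dashed line of the figure).
#'
#' @inheritParams detection_counts
#' @param bins Number of equal-width bins over the table's intensity range.
#' @return data.frame with columns \code{group}, \code{sample},
#'   \code{bin_left}, \code{bin_right}, \code{count},
#'   \code{group_mean_intensity}.
#' @export
intensity_histogram <- function(groups, tab, bins = 25) {
  .check_groups(groups, tab)
  all_vals <- tab$matrix[!is.na(tab$matrix)]
  if (length(all_vals) == 0L) stop("table has no observed intensities",
                                   call. = FALSE)
  edges <- seq(min(all_vals), max(all_vals), length.out = bins + 1L)
  do.call(rbind, lapply(names(groups), function(g) {
    s <- groups[[g]]
    gmean <- mean(tab$matrix[, s], na.rm = TRUE)
    do.call(rbind, lapply(s, function(sm) {
      v <- tab$matrix[, sm]
      v <- v[!is.na(v)]
      h <- graphics::hist(v, breaks = edges, plot = FALSE,
                          include.lowest = TRUE, right = TRUE)
      data.frame(group = g, sample = sm,
                 bin_left = edges[-length(edges)],
                 bin_right = edges[-1L],
                 count = h$counts,
                 group_mean_intensity = gmean,
                 stringsAsFactors = FALSE)
    }))
  }))
}

#' Relative standard deviation of proteins within groups
#'
#' For every above-threshold protein of each group: the mean log2 intensity
#' and the relative SD in percent. The relative SD is computed on the linear
#' intensity scale (2^log2), since a coefficient of variation of log values
#' is not scale-meaningful. Counts of proteins below the 10/20/30 percent
#' reference lines are attached per group.
#'
#' @inheritParams venn_between_groups
#' @return data.frame with columns \code{group}, \code{protein},
#'   \code{mean_log2_intensity}, \code{rsd_percent}, \code{n_below_10},
#'   \code{n_below_20}, \code{n_below_30} (group-level counts repeated per
#'   row).
#' @export
relative_sd <- function(groups, tab, policy = threshold_policy()) {
  .check_groups(groups, tab)
  det <- .detected(tab)
  do.call(rbind, lapply(names(groups), function(g) {
    s <- groups[[g]]
    counts <- rowSums(det[, s, drop = FALSE])
    keep <- counts >= required_count(policy, length(s)) & counts >= 2L
    if (!any(keep)) return(NULL)
    sub <- tab$matrix[keep, s, drop = FALSE]
    lin <- 2^sub
    mu <- rowMeans(lin, na.rm = TRUE)
    sd_ <- apply(lin, 1L, stats::sd, na.rm = TRUE)
    rsd <- sd_ / mu * 100
    data.frame(group = g, protein = rownames(sub),
               mean_log2_intensity = rowMeans(sub, na.rm = TRUE),
               rsd_percent = rsd,
               n_below_10 = sum(rsd < 10),
               n_below_20 = sum(rsd < 20),
               n_below_30 = sum(rsd < 30),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Replicate scatter comparisons within groups
#'
#' For every ordered sample pair within a group: the squared Pearson
#' correlation over pairwise-complete log2 intensities, the number of shared
#' proteins, and the proteins detected in only one of the two samples.
#'
#' @inheritParams detection_counts
#' @return data.frame with columns \code{group}, \code{sample_x},
#'   \code{sample_y}, \code{n_shared}, \code{r_squared},
#'   \code{n_unique_x}, \code{n_unique_y}, \code{unique_x}, \code{unique_y}
#'   (\code{;}-joined ids).
#' @export
scatter_replicates <- function(groups, tab) {
  .check_groups(groups, tab)
  det <- .detected(tab)
  ids <- protein_ids(tab)
  rows <- list()
  for (g in names(groups)) {
    s <- groups[[g]]
    if (length(s) < 2L) next
    for (i in seq_len(length(s) - 1L)) {
      for (j in seq((i + 1L), length(s))) {
        dx <- det[, s[i]]
        dy <- det[, s[j]]
        both <- dx & dy
        r2 <- if (sum(both) >= 2L) {
          tryCatch(pearson_r2(tab$matrix[both, s[i]], tab$matrix[both, s[j]]),
                   error = function(e) NA_real_)
        } else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, sample_x = s[i], sample_y = s[j],
          n_shared = sum(both), r_squared = r2,
          n_unique_x = sum(dx & !dy), n_unique_y = sum(dy & !dx),
          unique_x = paste(ids[dx & !dy], collapse = ";"),
          unique_y = paste(ids[dy & !dx], collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Group-versus-group intensity comparison with thresholding
#'
#' For every group pair, proteins are categorized with
#' [categorize_detection()]; mutually comparable proteins contribute their
#' group-mean intensities (mean over non-missing values) and the squared
#' Pearson correlation, unique proteins are listed per side, and
#' below-threshold proteins are absent.
#'
#' @inheritParams venn_between_groups
#' @return data.frame with one row per retained protein and pair:
#'   \code{group_a}, \code{group_b}, \code{protein}, \code{category}
#'   (\code{comparable}/\code{unique_in_A}/\code{unique_in_B}),
#'   \code{mean_a}, \code{mean_b}, \code{r_squared} (over the pair's
#'   comparable proteins, repeated).
#' @export
experiment_comparison <- function(groups, tab, policy = threshold_policy()) {
  .check_groups(groups, tab)
  if (length(groups) < 2L) {
    stop("need at least two groups to compare", call. = FALSE)
  }
  det <- .detected(tab)
  ids <- protein_ids(tab)
  gn <- names(groups)
  rows <- list()
  for (i in seq_len(length(gn) - 1L)) {
    for (j in seq((i + 1L), length(gn))) {
      sa <- groups[[gn[i]]]
      sb <- groups[[gn[j]]]
      da <- rowSums(det[, sa, drop = FALSE])
      db <- rowSums(det[, sb, drop = FALSE])
      cat_ <- categorize_detection(da, length(sa), db, length(sb), policy)
      keep <- cat_ != "not_considered"
      if (!any(keep)) next
      ma <- rowMeans(tab$matrix[, sa, drop = FALSE], na.rm = TRUE)
      mb <- rowMeans(tab$matrix[, sb, drop = FALSE], na.rm = TRUE)
      comp <- cat_ == "comparable"
      r2 <- if (sum(comp) >= 2L) {
        tryCatch(pearson_r2(ma[comp], mb[comp]),
                 error = function(e) NA_real_)
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        group_a = gn[i], group_b = gn[j], protein = ids[keep],
        category = cat_[keep],
        mean_a = ifelse(da[keep] > 0L, ma[keep], NA_real_),
        mean_b = ifelse(db[keep] > 0L, mb[keep], NA_real_),
        r_squared = r2, stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' Intensity rank plot data for one group
#'
#' Proteins detected in the group are sorted by group-mean log2 intensity,
#' descending; the rank percentile runs from 0\% at the highest intensity to
#' 100\% at the lowest (a single protein gets 0\%). Pathway members are
#' flagged, and each pathway's median rank percentile and detected-member
#' count are attached.
#'
#' @param group_samples Character vector of sample names (one group).
#' @param tab An [intensity_table()].
#' @param pathways Named list of character vectors of gene symbols
#'   (case-insensitive match), or \code{NULL}.
#' @return data.frame with columns \code{protein}, \code{mean_intensity},
#'   \code{rank_percentile}, \code{pathway} (\code{NA} if none),
#'   \code{pathway_median_rank}, \code{pathway_n_detected}.
#' @export
rank_plot <- function(group_samples, tab, pathways = NULL) {
  .check_groups(list(g = group_samples), tab)
  mu <- rowMeans(tab$matrix[, group_samples, drop = FALSE], na.rm = TRUE)
  mu <- mu[!is.nan(mu)]
  if (length(mu) == 0L) stop("no protein detected in the group",
                             call. = FALSE)
  ord <- order(mu, decreasing = TRUE)
  mu <- mu[ord]
  n <- length(mu)
  pct <- if (n == 1L) 0 else 100 * (seq_len(n) - 1L) / (n - 1L)
  out <- data.frame(protein = names(mu), mean_intensity = unname(mu),
                    rank_percentile = pct,
                    pathway = NA_character_,
                    pathway_median_rank = NA_real_,
                    pathway_n_detected = NA_integer_,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(pathways) && length(pathways) > 0L) {
    upper_ids <- toupper(out$protein)
    for (pw in names(pathways)) {
      hit <- upper_ids %in% toupper(pathways[[pw]])
      if (!any(hit)) next
      out$pathway[hit] <- pw
      out$pathway_median_rank[hit] <- stats::median(out$rank_percentile[hit])
      out$pathway_n_detected[hit] <- sum(hit)
    }
  }
  out
}

#' Pathway protein intensities and pairwise group tests
#'
#' For each protein of the selected pathways measured in the table: the mean
#' intensity in every group, and for each group pair a two-sided independent
#' t-test p-value when the protein is above the detection threshold in both
#' groups (and has at least two observations in each).
#'
#' @inheritParams venn_between_groups
#' @param pathways Named list of gene-symbol vectors.
#' @return data.frame with columns \code{pathway}, \code{protein},
#'   \code{group_a}, \code{group_b}, \code{mean_a}, \code{mean_b},
#'   \code{p_value} (\code{NA} when a side is below threshold or has too few
#'   observations).
#' @export
pathway_analysis <- function(groups, tab, pathways,
                             policy = threshold_policy()) {
  .check_groups(groups, tab)
  stopifnot(is.list(pathways), length(pathways) >= 1L)
  det <- .detected(tab)
  ids_upper <- toupper(protein_ids(tab))
  gn <- names(groups)
  rows <- list()
  for (pw in names(pathways)) {
    members <- which(ids_upper %in% toupper(pathways[[pw]]))
    for (pi in members) {
      for (i in seq_len(length(gn) - 1L)) {
        for (j in seq((i + 1L), length(gn))) {
          sa <- groups[[gn[i]]]
          sb <- groups[[gn[j]]]
          va <- tab$matrix[pi, sa]
          vb <- tab$matrix[pi, sb]
          ok <- above_threshold(sum(det[pi, sa]), policy, length(sa)) &&
            above_threshold(sum(det[pi, sb]), policy, length(sb)) &&
            sum(!is.na(va)) >= 2L && sum(!is.na(vb)) >= 2L
          p <- if (ok) independent_t_test(va, vb)$p else NA_real_
          rows[[length(rows) + 1L]] <- data.frame(
            pathway = pw, protein = protein_ids(tab)[pi],
            group_a = gn[i], group_b = gn[j],
            mean_a = mean(va, na.rm = TRUE), mean_b = mean(vb, na.rm = TRUE),
            p_value = p, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

#' GO term detection counts and enrichment per group
#'
#' For each GO term and group: the number of term proteins detected in the
#' group (raw intensity > 0 in at least one of its samples), the term list
#' size, and a one-tailed Fisher exact p-value for enrichment of the term
#' among the group's detected proteins. The background is the set of measured
#' proteins (all rows of the filtered table).
#'
#' @inheritParams detection_counts
#' @param go_terms Named list of gene-symbol vectors (one entry per GO term).
#' @return data.frame with columns \code{term}, \code{group},
#'   \code{term_size} (list length), \code{n_term_measured},
#'   \code{n_term_detected}, \code{n_detected_total}, \code{p_value}.
#' @export
go_analysis <- function(groups, tab, go_terms) {
  .check_groups(groups, tab)
  stopifnot(is.list(go_terms), length(go_terms) >= 1L)
  det <- .detected(tab)
  ids_upper <- toupper(protein_ids(tab))
  n_bg <- length(ids_upper)
  do.call(rbind, lapply(names(go_terms), function(term) {
    in_term <- ids_upper %in% toupper(go_terms[[term]])
    do.call(rbind, lapply(names(groups), function(g) {
      detected_g <- rowSums(det[, groups[[g]], drop = FALSE]) > 0L
      a <- sum(in_term & detected_g)
      b <- sum(in_term & !detected_g)
      c_ <- sum(!in_term & detected_g)
      d_ <- sum(!in_term & !detected_g)
      data.frame(term = term, group = g,
                 term_size = length(go_terms[[term]]),
                 n_term_measured = sum(in_term),
                 n_term_detected = a,
                 n_detected_total = sum(detected_g),
                 p_value = fisher_one_tailed(a, b, c_, d_),
                 stringsAsFactors = FALSE)
    }))
  }))
}

#' Volcano analysis of two groups
#'
#' Every protein is categorized with [categorize_detection()]. Comparable
#' proteins with at least two observations per group get a moderated t-test
#' with intensity-variance trend ([moderated_t_fit()]) and Benjamini-Hochberg
#' adjustment; unique proteins are listed per side with their within-group
#' mean intensities; everything else is \code{excluded}. Either the
#' \code{annotate_top} most significant comparable proteins (by adjusted p)
#' or the members of the given pathways are marked for annotation.
#'
#' @param group_a,group_b Character vectors of sample names.
#' @param tab An [intensity_table()].
#' @param policy A [threshold_policy()].
#' @param pathways Named list of gene-symbol vectors; when non-NULL, pathway
#'   members are annotated instead of the top hits.
#' @param annotate_top Number of most-significant proteins to annotate in
#'   top-hit mode.
#' @param name_a,name_b Group display names used in the output.
#' @return data.frame (class \code{volcano_result}) with one row per protein:
#'   \code{protein}, \code{category} (\code{comparable}, \code{unique_in_A},
#'   \code{unique_in_B}, \code{excluded}), \code{mean_a}, \code{mean_b},
#'   \code{log2_fc}, \code{p_value}, \code{adj_p_value},
#'   \code{neg_log10_p}, \code{neg_log10_adj_p}, \code{annotated}.
#'   Attributes \code{name_a}, \code{name_b}, \code{prior_df}.
#' @export
volcano <- function(group_a, group_b, tab, policy = threshold_policy(),
                    pathways = NULL, annotate_top = 10,
                    name_a = "A", name_b = "B") {
  .check_groups(list(a = group_a, b = group_b), tab)
  det <- .detected(tab)
  ids <- protein_ids(tab)
  da <- rowSums(det[, group_a, drop = FALSE])
  db <- rowSums(det[, group_b, drop = FALSE])
  cat_ <- categorize_detection(da, length(group_a), db, length(group_b),
                               policy)
  n_obs_ok <- da >= 2L & db >= 2L
  testable <- cat_ == "comparable" & n_obs_ok
  cat_out <- cat_
  cat_out[cat_ == "not_considered" |
            (cat_ == "comparable" & !n_obs_ok)] <- "excluded"
  ma <- rowMeans(tab$matrix[, group_a, drop = FALSE], na.rm = TRUE)
  mb <- rowMeans(tab$matrix[, group_b, drop = FALSE], na.rm = TRUE)
  out <- data.frame(protein = ids, category = cat_out,
                    mean_a = ifelse(da > 0L, ma, NA_real_),
                    mean_b = ifelse(db > 0L, mb, NA_real_),
                    log2_fc = NA_real_, p_value = NA_real_,
                    adj_p_value = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  prior_df <- NA_real_
  if (any(testable)) {
    fit <- moderated_t_fit(tab$matrix[testable, group_a, drop = FALSE],
                           tab$matrix[testable, group_b, drop = FALSE],
                           trend = TRUE)
    out$log2_fc[testable] <- fit$log2_fc
    out$p_value[testable] <- fit$p
    out$adj_p_value[testable] <- benjamini_hochberg(fit$p)
    prior_df <- attr(fit, "prior_df")
  }
  out$neg_log10_p <- -log10(out$p_value)
  out$neg_log10_adj_p <- -log10(out$adj_p_value)
  out$annotated <- FALSE
  if (!is.null(pathways) && length(pathways) > 0L) {
    out$annotated <- toupper(out$protein) %in%
      toupper(unlist(pathways)) & out$category != "excluded"
  } else if (any(testable)) {
    ord <- order(out$adj_p_value)
    top <- utils::head(ord[!is.na(out$adj_p_value[ord])], annotate_top)
    out$annotated[top] <- TRUE
  }
  attr(out, "name_a") <- name_a
  attr(out, "name_b") <- name_b
  attr(out, "prior_df") <- prior_df
  class(out) <- c("volcano_result", "data.frame")
  out
}
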