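# Synthetic MaxQuant-dialect proteinGroups generator with known ground truth.

#' Specification for a synthetic proteinGroups fixture
#'
#' Describes a simulated label-free experiment: a factorial design of cell
#' lines x treatments x replicates, per-protein base abundances drawn from a
#' log-normal model (normal on the log2 scale), per-sample systematic shifts,
#' replicate noise, intensity-dependent dropout (left-censoring: the lower a
#' protein's log2 intensity, the higher its dropout probability, via a
#' logistic curve), optional planted differential effects, and planted
#' contaminant/decoy/site-only flags.
#'
#' Sample names follow the \code{line_treatment_replicate} convention (e.g.
#' \code{"L1_T2_R1"}), so the design tree has depth 3.
#'
#' @param n_proteins Number of protein groups.
#' @param n_lines,n_treatments,n_replicates Factorial design dimensions.
#' @param base_mean,base_sd Mean and SD of per-protein base log2 intensity.
#' @param noise_sd Replicate noise SD, log2 units.
#' @param sample_shifts Per-sample systematic shifts (log2 units); either a
#'   numeric vector of length n_samples or \code{NULL} to draw them from
#'   \code{N(0, sample_shift_sd)}.
#' @param sample_shift_sd SD of drawn sample shifts.
#' @param dropout_midpoint Log2 intensity at which dropout probability is 50\%;
#'   \code{NULL} disables dropout entirely.
#' @param dropout_steepness Logistic steepness of the dropout curve, per log2
#'   unit.
#' @param effect_fraction Fraction of proteins carrying a planted effect.
#' @param effect_size Planted shift in log2 units.
#' @param effect_group Name of the level-0 group (cell line component, e.g.
#'   \code{"L2"}) whose samples receive the effect; defaults to the last line.
#' @param contaminant_fraction,reverse_fraction,site_fraction Fractions of
#'   rows flagged \code{"+"} as potential contaminant, reverse (decoy) or
#'   only-identified-by-site.
#' @param seed Integer seed; identical spec and seed give byte-identical
#'   files.
#' @return An object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(n_proteins = 1000,
                         n_lines = 2, n_treatments = 3, n_replicates = 2,
                         base_mean = 25, base_sd = 2,
                         noise_sd = 0.3,
                         sample_shifts = NULL, sample_shift_sd = 0.2,
                         dropout_midpoint = 21, dropout_steepness = 1,
                         effect_fraction = 0, effect_size = 1,
                         effect_group = NULL,
                         contaminant_fraction = 0.05,
                         reverse_fraction = 0.02,
                         site_fraction = 0.02,
                         seed = 1) {
  stopifnot(n_proteins >= 1, n_lines >= 1, n_treatments >= 1,
            n_replicates >= 1, noise_sd >= 0, base_sd >= 0,
            effect_fraction >= 0, effect_fraction <= 1)
  spec <- as.list(environment())
  structure(spec, class = "fixture_spec")
}

#' Sample names implied by a fixture spec
#'
#' @param spec A [fixture_spec()].
#' @return Character vector \code{"L<i>_T<j>_R<k>"} in column order.
#' @export
fixture_sample_names <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  grid <- expand.grid(rep = seq_len(spec$n_replicates),
                      trt = seq_len(spec$n_treatments),
                      line = seq_len(spec$n_lines))
  # order: line outermost, then treatment, then replicate
  grid <- grid[order(grid$line, grid$trt, grid$rep), ]
  paste0("L", grid$line, "_T", grid$trt, "_R", grid$rep)
}

#' Generate a synthetic proteinGroups file with ground truth
#'
#' Writes a tab-separated MaxQuant-dialect table with identifier columns, the
#' three quality-flag columns, and all three intensity flavors per sample
#' (\code{"Intensity "}, \code{"LFQ intensity "}, \code{"iBAQ "}; the three
#' flavors carry identical values, a deliberate simplification of real
#' MaxQuant output where nothing downstream depends on cross-flavor
#' differences). Returns the planted ground truth so tests can verify every
#' downstream module.
#'
#' @param spec A [fixture_spec()].
#' @param path Output file path.
#' @return Invisibly, a list with \code{path}, \code{sample_names},
#'   \code{log2_matrix} (planted true log2 intensities, \code{NA} where
#'   dropped out; rows = gene symbols, all rows incl. flagged ones),
#'   \code{missing_mask}, \code{flagged} (logical per row),
#'   \code{flag_type} (\code{""}, \code{"contaminant"}, \code{"reverse"} or
#'   \code{"site"}), \code{planted_effect} (logical per row) and
#'   \code{effect_samples}.
#' @export
generate_fixture <- function(spec, path) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  samples <- fixture_sample_names(spec)
  n_s <- length(samples)
  n_p <- spec$n_proteins

  shifts <- spec$sample_shifts
  if (is.null(shifts)) {
    shifts <- stats::rnorm(n_s, 0, spec$sample_shift_sd)
  }
  if (length(shifts) != n_s) {
    stop("sample_shifts must have length ", n_s, call. = FALSE)
  }

  base <- stats::rnorm(n_p, spec$base_mean, spec$base_sd)
  planted <- rep(FALSE, n_p)
  effect_samples <- character(0)
  if (spec$effect_fraction > 0) {
    planted[sample.int(n_p, round(spec$effect_fraction * n_p))] <- TRUE
    eg <- spec$effect_group %||% paste0("L", spec$n_lines)
    effect_samples <- samples[startsWith(samples, paste0(eg, "_"))]
    if (length(effect_samples) == 0L) {
      stop("effect_group \"", eg, "\" matches no samples", call. = FALSE)
    }
  }

  m <- matrix(base, n_p, n_s) +
    matrix(shifts, n_p, n_s, byrow = TRUE) +
    matrix(stats::rnorm(n_p * n_s, 0, spec$noise_sd), n_p, n_s)
  if (any(planted)) {
    m[planted, samples %in% effect_samples] <-
      m[planted, samples %in% effect_samples] + spec$effect_size
  }

  if (!is.null(spec$dropout_midpoint)) {
    p_drop <- stats::plogis(spec$dropout_steepness *
                              (spec$dropout_midpoint - m))
    drop <- matrix(stats::runif(n_p * n_s), n_p, n_s) < p_drop
    m[drop] <- NA_real_
  }

  # samples entirely empty would make the table degenerate; regenerate noise
  # cannot happen under sane specs, so just guard
  genes <- sprintf("GENE%04d", seq_len(n_p))
  rownames(m) <- genes
  colnames(m) <- samples

  flag_type <- rep("", n_p)
  n_con <- round(spec$contaminant_fraction * n_p)
  n_rev <- round(spec$reverse_fraction * n_p)
  n_site <- round(spec$site_fraction * n_p)
  pool <- sample.int(n_p)
  take <- function(n) {
    out <- utils::head(pool, n)
    pool <<- utils::tail(pool, length(pool) - n)
    out
  }
  flag_type[take(n_con)] <- "contaminant"
  flag_type[take(n_rev)] <- "reverse"
  flag_type[take(n_site)] <- "site"

  raw <- ifelse(is.na(m), 0, 2^m)
  fmt <- function(v) sprintf("%.12g", v)
  df <- data.frame(
    `Protein IDs` = sprintf("P%04d", seq_len(n_p)),
    `Majority protein IDs` = sprintf("P%04d", seq_len(n_p)),
    `Gene names` = genes,
    `Only identified by site` = ifelse(flag_type == "site", "+", ""),
    Reverse = ifelse(flag_type == "reverse", "+", ""),
    `Potential contaminant` = ifelse(flag_type == "contaminant", "+", ""),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  for (j in seq_len(n_s)) {
    df[[paste0("Intensity ", samples[j])]] <- fmt(raw[, j])
    df[[paste0("LFQ intensity ", samples[j])]] <- fmt(raw[, j])
    df[[paste0("iBAQ ", samples[j])]] <- fmt(raw[, j])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")

  invisible(list(path = path,
                 sample_names = samples,
                 log2_matrix = m,
                 missing_mask = is.na(m),
                 flagged = flag_type != "",
                 flag_type = flag_type,
                 planted_effect = planted,
                 effect_samples = effect_samples,
                 sample_shifts = shifts))
}
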