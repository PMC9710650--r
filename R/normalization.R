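# Normalization strategies on log2 intensity matrices.
#
# All methods operate on the log2 scale and never touch missing entries:
# the missing mask of the output is bit-identical to the input's.

.check_no_empty_samples <- function(x) {
  n_obs <- colSums(!is.na(x$matrix))
  if (any(n_obs == 0L)) {
    stop("sample(s) with all values missing: ",
         paste(colnames(x$matrix)[n_obs == 0L], collapse = ", "),
         call. = FALSE)
  }
}

#' Median normalization
#'
#' For each sample the median log2 intensity is computed; the mean of all
#' sample medians is subtracted from each sample median, and this per-sample
#' correction factor is then subtracted from every intensity of the sample.
#' Afterwards all sample medians coincide. Missing entries are untouched.
#'
#' @param x An [intensity_table()].
#' @return The normalized \code{intensity_table}.
#' @export
median_norm <- function(x) {
  stopifnot(inherits(x, "intensity_table"))
  .check_no_empty_samples(x)
  med <- apply(x$matrix, 2L, stats::median, na.rm = TRUE)
  corr <- med - mean(med)
  x$matrix <- sweep(x$matrix, 2L, corr, "-")
  x
}

#' Quantile normalization with optional missing-value handling
#'
#' Proteins are ranked by intensity within each sample; the mean intensity per
#' rank across samples is computed and assigned back to every protein of each
#' sample (tied ranks receive the average of the adjacent rank means). With
#' \code{handle_missing = TRUE}, missing cells are temporarily filled by
#' sampling with replacement from the same sample's observed intensities
#' (seeded), the complete matrix is normalized, and the missing cells are then
#' restored. Without missing handling, a matrix containing missing values is
#' refused rather than silently dropping rows.
#'
#' @param x An [intensity_table()].
#' @param handle_missing Fill missing values during normalization and restore
#'   them afterwards?
#' @param seed Integer seed for the missing-value sampling (required when
#'   \code{handle_missing} and the matrix has missing values).
#' @return The normalized \code{intensity_table}; its missing mask equals the
#'   input's.
#' @export
quantile_norm <- function(x, handle_missing = FALSE, seed = NULL) {
  stopifnot(inherits(x, "intensity_table"))
  .check_no_empty_samples(x)
  m <- x$matrix
  miss <- is.na(m)
  if (any(miss)) {
    if (!handle_missing) {
      stop("matrix contains missing values; use handle_missing = TRUE ",
           "(method quantile_norm_missing_handled)", call. = FALSE)
    }
    if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
    for (j in seq_len(ncol(m))) {
      idx <- which(miss[, j])
      if (length(idx) > 0L) {
        pool <- m[!miss[, j], j]
        m[idx, j] <- sample(pool, length(idx), replace = TRUE)
      }
    }
  }
  m <- .quantile_core(m)
  m[miss] <- NA_real_
  x$matrix <- m
  x
}

# Quantile normalization of a complete matrix; ties get the average of the
# rank means implied by their (fractional) average rank.
.quantile_core <- function(m) {
  if (nrow(m) < 1L) return(m)
  sorted <- apply(m, 2L, sort)
  if (is.null(dim(sorted))) sorted <- matrix(sorted, nrow = 1L)
  rank_means <- rowMeans(sorted)
  out <- m
  for (j in seq_len(ncol(m))) {
    r <- rank(m[, j], ties.method = "average")
    lo <- floor(r)
    hi <- ceiling(r)
    out[, j] <- (rank_means[lo] + rank_means[hi]) / 2
  }
  out
}

#' Tail-robust quantile normalization
#'
#' The sample-wise mean (over observed values) is subtracted from each sample
#' as an offset, [quantile_norm()] is applied to the centered matrix, and the
#' offsets are added back. Centering protects the distribution tails from the
#' over-flattening of plain quantile normalization.
#'
#' @inheritParams quantile_norm
#' @return The normalized \code{intensity_table}.
#' @export
trqn <- function(x, handle_missing = FALSE, seed = NULL) {
  stopifnot(inherits(x, "intensity_table"))
  .check_no_empty_samples(x)
  offsets <- colMeans(x$matrix, na.rm = TRUE)
  x$matrix <- sweep(x$matrix, 2L, offsets, "-")
  x <- quantile_norm(x, handle_missing = handle_missing, seed = seed)
  x$matrix <- sweep(x$matrix, 2L, offsets, "+")
  x
}

#' Tail-robust median normalization
#'
#' The sample-wise mean (over observed values) is subtracted as an offset,
#' [median_norm()] is applied, and the offsets are added back.
#'
#' @inheritParams median_norm
#' @return The normalized \code{intensity_table}.
#' @export
trmn <- function(x) {
  stopifnot(inherits(x, "intensity_table"))
  .check_no_empty_samples(x)
  offsets <- colMeans(x$matrix, na.rm = TRUE)
  x$matrix <- sweep(x$matrix, 2L, offsets, "-")
  x <- median_norm(x)
  x$matrix <- sweep(x$matrix, 2L, offsets, "+")
  x
}

#' Normalization method names
#'
#' @return Character vector of the six supported method names.
#' @export
normalization_methods <- function() {
  c("none", "median_norm", "quantile_norm_missing_handled",
    "trqn", "trqn_missing_handled", "trmn")
}

#' Apply a named normalization strategy
#'
#' Dispatches on the method name: \code{none} (identity), \code{median_norm},
#' \code{quantile_norm_missing_handled}, \code{trqn},
#' \code{trqn_missing_handled}, \code{trmn}.
#'
#' @param x An [intensity_table()].
#' @param method One of [normalization_methods()].
#' @param seed Integer seed used by the missing-value handling variants.
#' @return The normalized \code{intensity_table}.
#' @export
apply_normalization <- function(x, method, seed = NULL) {
  if (length(method) != 1L || !(method %in% normalization_methods())) {
    stop("unknown normalization method \"", method, "\"; valid methods: ",
         paste(normalization_methods(), collapse = ", "), call. = FALSE)
  }
  switch(method,
         none = x,
         median_norm = median_norm(x),
         quantile_norm_missing_handled =
           quantile_norm(x, handle_missing = TRUE, seed = seed),
         trqn = trqn(x, handle_missing = FALSE),
         trqn_missing_handled = trqn(x, handle_missing = TRUE, seed = seed),
         trmn = trmn(x))
}
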