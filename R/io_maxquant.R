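# Reading, validating and filtering MaxQuant proteinGroups tables.

#' Intensity column prefixes by flavor
#'
#' MaxQuant writes one intensity column per sample and flavor, named by an
#' exact prefix followed by the sample name: \code{"Intensity <sample>"},
#' \code{"LFQ intensity <sample>"}, \code{"iBAQ <sample>"}.
#'
#' @return Named character vector mapping flavor (\code{raw}, \code{lfq},
#'   \code{ibaq}) to column prefix.
#' @export
flavor_prefixes <- function() {
  c(raw = "Intensity ", lfq = "LFQ intensity ", ibaq = "iBAQ ")
}

.mq_flag_columns <- c("Only identified by site", "Reverse",
                      "Potential contaminant")

#' Read a MaxQuant proteinGroups table
#'
#' Loads a tab-separated proteinGroups-style file and identifies the per-sample
#' intensity columns of the requested flavor. Sample names are obtained by
#' stripping the flavor prefix from the column names. Every intensity cell
#' must parse as a non-negative finite number; a raw intensity of 0 encodes
#' "not detected".
#'
#' @param path Path to a tab-separated file with a header row.
#' @param flavor Intensity flavor: \code{"raw"} (column prefix
#'   \code{"Intensity "}), \code{"lfq"} (\code{"LFQ intensity "}) or
#'   \code{"ibaq"} (\code{"iBAQ "}).
#' @return An object of class \code{protein_groups}: a list with the parsed
#'   \code{data} (data.frame), \code{flavor}, \code{intensity_columns},
#'   \code{sample_names} and \code{source_path}.
#' @examples
#' spec <- fixture_spec(n_proteins = 20, seed = 1)
#' f <- generate_fixture(spec, tempfile(fileext = ".txt"))
#' pg <- read_protein_groups(f$path, flavor = "lfq")
#' pg$sample_names
#' @export
read_protein_groups <- function(path, flavor = c("raw", "lfq", "ibaq")) {
  flavor <- match.arg(flavor)
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, check.names = FALSE, quote = "",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  prefix <- flavor_prefixes()[[flavor]]
  int_cols <- names(df)[startsWith(names(df), prefix)]
  # "LFQ intensity x" must not be picked up as a raw "Intensity " column
  if (flavor == "raw") {
    int_cols <- setdiff(int_cols, names(df)[startsWith(names(df),
                                                       "LFQ intensity ")])
  }
  if (length(int_cols) == 0L) {
    stop("no intensity columns with prefix \"", prefix,
         "\" found in ", path, call. = FALSE)
  }
  for (cn in int_cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) | !is.finite(v) | v < 0)
    if (length(bad) > 0L) {
      stop("non-numeric or negative intensity in column \"", cn,
           "\", row ", bad[1L], " (value \"", df[[cn]][bad[1L]], "\")",
           call. = FALSE)
    }
    df[[cn]] <- v
  }
  structure(
    list(data = df,
         flavor = flavor,
         intensity_columns = int_cols,
         sample_names = substring(int_cols, nchar(prefix) + 1L),
         source_path = path),
    class = "protein_groups"
  )
}

#' @export
print.protein_groups <- function(x, ...) {
  cat("protein_groups table (", x$flavor, " intensities)\n", sep = "")
  cat("  ", nrow(x$data), " protein groups, ",
      length(x$sample_names), " samples\n", sep = "")
  cat("  samples: ", paste(utils::head(x$sample_names, 6L), collapse = ", "),
      if (length(x$sample_names) > 6L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Remove decoy, contaminant and site-only protein groups
#'
#' Drops every row flagged \code{"+"} in any of the three MaxQuant quality
#' columns \code{"Only identified by site"}, \code{"Reverse"} and
#' \code{"Potential contaminant"}. Absent flag columns are treated as
#' all-unflagged with a warning, so minimal synthetic tables are accepted.
#' Row order is preserved; an all-filtered (empty) result is legal.
#'
#' @param pg A \code{protein_groups} object from [read_protein_groups()].
#' @return The filtered \code{protein_groups} object.
#' @export
filter_protein_groups <- function(pg) {
  stopifnot(inherits(pg, "protein_groups"))
  df <- pg$data
  keep <- rep(TRUE, nrow(df))
  missing_cols <- setdiff(.mq_flag_columns, names(df))
  if (length(missing_cols) > 0L) {
    warning("flag column(s) not present, treated as unflagged: ",
            paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (cn in intersect(.mq_flag_columns, names(df))) {
    keep <- keep & (is.na(df[[cn]]) | trimws(df[[cn]]) != "+")
  }
  pg$data <- df[keep, , drop = FALSE]
  pg
}

#' Convert a protein-groups table to a log2 intensity table
#'
#' Builds the proteins x samples matrix of log2 intensities. Raw zeros become
#' missing values (a protein is "detected" in a sample iff its raw intensity
#' is strictly positive); positive intensities become \code{log2(value)}.
#' Protein identifiers are the first entry of the \code{"Gene names"} column;
#' rows sharing a gene symbol are aggregated by summing their raw intensities
#' before the log transform, and rows with an empty gene name fall back to the
#' first majority-protein ID.
#'
#' @param pg A filtered \code{protein_groups} object.
#' @return An [intensity_table()] object.
#' @export
to_intensity_table <- function(pg) {
  stopifnot(inherits(pg, "protein_groups"))
  if (length(pg$intensity_columns) == 0L) {
    stop("table has no samples", call. = FALSE)
  }
  df <- pg$data
  raw <- as.matrix(df[, pg$intensity_columns, drop = FALSE])
  colnames(raw) <- pg$sample_names
  ids <- .protein_identifiers(df)
  if (nrow(raw) > 0L && anyDuplicated(ids)) {
    raw <- rowsum(raw, group = ids, reorder = FALSE)
    ids <- rownames(raw)
  }
  rownames(raw) <- ids
  m <- ifelse(raw > 0, log2(raw), NA_real_)
  rownames(m) <- ids
  intensity_table(m, flavor = pg$flavor)
}

.protein_identifiers <- function(df) {
  first_token <- function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    vapply(strsplit(x, ";", fixed = TRUE),
           function(p) if (length(p) > 0L) trimws(p[[1L]]) else "",
           character(1L))
  }
  n <- nrow(df)
  ids <- if ("Gene names" %in% names(df)) first_token(df[["Gene names"]])
         else rep("", n)
  fallback_col <- intersect(c("Majority protein IDs", "Protein IDs"),
                            names(df))
  fallback <- if (length(fallback_col) > 0L) first_token(df[[fallback_col[1L]]])
              else paste0("protein_", seq_len(n))
  empty <- !nzchar(ids)
  ids[empty] <- fallback[empty]
  still <- !nzchar(ids)
  ids[still] <- paste0("protein_", which(still))
  ids
}

#' Log2 intensity table
#'
#' The central data container: a proteins x samples matrix of log2 intensities
#' with \code{NA} marking missing values (raw intensity 0, i.e. not detected),
#' tagged by intensity flavor. All statistics in the package exclude missing
#' entries.
#'
#' @param matrix Numeric matrix of log2 intensities with protein identifiers
#'   as row names and sample names as column names; \code{NA} = missing.
#' @param flavor One of \code{"raw"}, \code{"lfq"}, \code{"ibaq"}.
#' @return An object of class \code{intensity_table} with elements
#'   \code{matrix}, \code{flavor}, and accessors via \code{$}.
#' @export
intensity_table <- function(matrix, flavor = c("raw", "lfq", "ibaq")) {
  flavor <- match.arg(flavor)
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (is.null(rownames(matrix))) {
    rownames(matrix) <- paste0("protein_", seq_len(nrow(matrix)))
  }
  if (is.null(colnames(matrix))) {
    stop("intensity matrix needs sample names as column names", call. = FALSE)
  }
  if (anyDuplicated(rownames(matrix))) {
    stop("protein identifiers must be unique", call. = FALSE)
  }
  if (anyDuplicated(colnames(matrix))) {
    stop("sample names must be unique", call. = FALSE)
  }
  if (any(is.infinite(matrix))) {
    stop("non-missing intensities must be finite", call. = FALSE)
  }
  structure(list(matrix = matrix, flavor = flavor),
            class = "intensity_table")
}

#' @export
print.intensity_table <- function(x, ...) {
  cat("intensity_table (", x$flavor, ", log2): ",
      nrow(x$matrix), " proteins x ", ncol(x$matrix), " samples, ",
      sum(is.na(x$matrix)), " missing values\n", sep = "")
  invisible(x)
}

#' @rdname intensity_table
#' @param x An \code{intensity_table}.
#' @export
missing_mask <- function(x) {
  stopifnot(inherits(x, "intensity_table"))
  is.na(x$matrix)
}

#' @rdname intensity_table
#' @export
sample_names <- function(x) {
  stopifnot(inherits(x, "intensity_table"))
  colnames(x$matrix)
}

#' @rdname intensity_table
#' @export
protein_ids <- function(x) {
  stopifnot(inherits(x, "intensity_table"))
  rownames(x$matrix)
}

#' Reader interface for additional input formats
#'
#' [read_protein_groups()] covers the MaxQuant dialect. Other table formats
#' can be plugged in by constructing a list with class
#' \code{c("<myformat>", "protein_groups")} that provides the same fields:
#' \describe{
#'   \item{\code{data}}{data.frame with one row per protein group, numeric
#'     per-sample intensity columns (0 = not detected), and optionally the
#'     three MaxQuant flag columns using \code{"+"} for true.}
#'   \item{\code{sample_names}, \code{intensity_columns}}{parallel character
#'     vectors: sample names and the columns holding their intensities.}
#'   \item{\code{flavor}}{one of \code{"raw"}, \code{"lfq"}, \code{"ibaq"}.}
#' }
#' Any such object passes through [filter_protein_groups()] and
#' [to_intensity_table()] unchanged, which is the full contract the rest of
#' the pipeline relies on.
#'
#' @name reader-interface
NULL
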