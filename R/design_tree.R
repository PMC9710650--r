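# Tree-structured analysis design built from sample names.

#' Build the analysis design tree from sample names
#'
#' Sample names are split into separator-delimited components (for example
#' cell line / treatment / replicate); the path from root to leaf spells one
#' sample name. All names must decompose into the same number of components.
#'
#' @param sample_names Character vector of unique, nonempty sample names.
#' @param separator Component separator, default \code{"_"}.
#' @return An object of class \code{analysis_design} with elements
#'   \code{sample_names}, \code{components} (samples x depth character
#'   matrix), \code{separator}, \code{depth} and the nested \code{root} node.
#' @examples
#' d <- build_design(c("A_t1_r1", "A_t1_r2", "A_t2_r1"))
#' d$depth
#' groups_at_level(d, 1)
#' @export
build_design <- function(sample_names, separator = "_") {
  if (length(sample_names) < 1L) {
    stop("need at least one sample name", call. = FALSE)
  }
  if (any(!nzchar(sample_names))) {
    stop("sample names must be nonempty", call. = FALSE)
  }
  dup <- unique(sample_names[duplicated(sample_names)])
  if (length(dup) > 0L) {
    stop("duplicate sample names: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  parts <- strsplit(sample_names, separator, fixed = TRUE)
  lens <- lengths(parts)
  if (length(unique(lens)) > 1L) {
    mode_len <- as.integer(names(which.max(table(lens))))
    bad <- sample_names[lens != mode_len]
    stop("sample names decompose into different numbers of components; ",
         "offending names: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  depth <- lens[1L]
  components <- do.call(rbind, parts)
  rownames(components) <- sample_names
  structure(
    list(sample_names = sample_names,
         components = components,
         separator = separator,
         depth = depth,
         root = .build_node("", components, sample_names, separator)),
    class = "analysis_design"
  )
}

.build_node <- function(name, components, samples, separator) {
  if (ncol(components) == 0L) {
    return(list(name = name, sample = samples[1L], children = list()))
  }
  heads <- components[, 1L]
  children <- lapply(unique(heads), function(h) {
    sel <- heads == h
    .build_node(h, components[sel, -1L, drop = FALSE], samples[sel],
                separator)
  })
  list(name = name, sample = NULL, children = children)
}

#' @export
print.analysis_design <- function(x, ...) {
  cat("analysis_design: ", length(x$sample_names), " samples, depth ",
      x$depth, " (separator \"", x$separator, "\")\n", sep = "")
  for (l in seq_len(x$depth) - 1L) {
    g <- groups_at_level(x, l)
    cat("  level ", l, ": ", length(g), " group(s)\n", sep = "")
  }
  invisible(x)
}

#' Resolve a design level into sample groups
#'
#' A level slices the samples into groups named by the joined name components
#' up to and including that level (0-based). Level 0 groups by the first
#' component; the deepest level yields one group per sample. Groups always
#' partition the sample set, and samples within a group keep their input
#' order.
#'
#' @param design An [build_design()] object.
#' @param level Integer level, \code{0 <= level < design$depth}.
#' @return Named list mapping group name to the character vector of its
#'   sample names.
#' @export
groups_at_level <- function(design, level) {
  stopifnot(inherits(design, "analysis_design"))
  if (length(level) != 1L || is.na(level) || level != round(level) ||
      level < 0L || level >= design$depth) {
    stop("level must be an integer in [0, ", design$depth - 1L, "]",
         call. = FALSE)
  }
  keys <- apply(design$components[, seq_len(level + 1L), drop = FALSE], 1L,
                paste, collapse = design$separator)
  split(design$sample_names, factor(keys, levels = unique(keys)))
}
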