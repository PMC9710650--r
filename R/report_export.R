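# Pipeline driver: render analyses to PDF + CSV, QC report, configuration
# persistence, run log.

#' Names of the available analyses
#'
#' @return Character vector of analysis names accepted by the
#'   \code{analyses} config key.
#' @export
list_analyses <- function() {
  c("detection_counts", "detected_per_sample", "venn_diagrams",
    "venn_groups", "pca_overview", "intensity_histogram", "relative_sd",
    "scatter_replicates", "experiment_comparison", "rank", "pathway_analysis",
    "go_analysis", "volcano")
}

#' Default run configuration
#'
#' All settings of a pipeline run in one list: input file and intensity
#' flavor, design separator and level, threshold policy parameters,
#' normalization method and seed, pathway/GO list directories, the analyses
#' to run, the output directory and the global seed. [save_config()] persists
#' the list (plus the package version) so a run can be reproduced exactly.
#'
#' @param input_path Path to the proteinGroups-style table.
#' @param output_dir Output directory (created if needed).
#' @param ... Overrides for any default entry (partial lists are merged).
#' @return A named list of class \code{run_config}.
#' @export
default_config <- function(input_path = NULL, output_dir = NULL, ...) {
  cfg <- list(
    input = list(path = input_path, flavor = "lfq"),
    design = list(separator = "_", level = 0L),
    threshold = list(n_full = 3, n_half = 12, steepness = 1.0),
    normalization = list(method = "median_norm", seed = 1L),
    lists = list(pathways_dir = NULL, go_dir = NULL),
    analyses = list_analyses(),
    volcano = list(group_a = NULL, group_b = NULL, annotate_top = 10L),
    histogram_bins = 25L,
    output_dir = output_dir,
    seed = 1L
  )
  overrides <- list(...)
  for (k in names(overrides)) {
    if (is.list(cfg[[k]]) && is.list(overrides[[k]])) {
      cfg[[k]] <- utils::modifyList(cfg[[k]], overrides[[k]])
    } else {
      cfg[[k]] <- overrides[[k]]
    }
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Save / load a run configuration
#'
#' The configuration is written as YAML together with the package version, so
#' an analysis can be re-run later under identical settings. Loading warns
#' about unknown keys (e.g. from hand editing) but keeps them.
#'
#' @param config A [default_config()] list.
#' @param path File path (conventionally \code{config.yml}).
#' @return \code{save_config} returns \code{path} invisibly;
#'   \code{load_config} returns the \code{run_config}.
#' @export
save_config <- function(config, path) {
  out <- unclass(config)
  out$package_version <- as.character(utils::packageVersion("lfqpipe"))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$package_version <- NULL
  known <- names(default_config())
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    warning("unknown configuration key(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  cfg <- default_config()
  # NULL is a legal value (e.g. unset list directories), so assign via
  # [name] <- list(...) rather than modifyList, which would drop the key
  for (k in names(raw)) {
    if (is.list(cfg[[k]]) && is.list(raw[[k]])) {
      for (nm in names(raw[[k]])) cfg[[k]][nm] <- list(raw[[k]][[nm]])
    } else {
      cfg[k] <- list(raw[[k]])
    }
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Read pathway / GO term lists from a directory
#'
#' Each plain-text file in the directory is one term: the filename (without
#' extension) is the term name and each line holds one gene symbol.
#'
#' @param dir Directory path, or \code{NULL} for no lists.
#' @return Named list of character vectors, or \code{NULL}.
#' @export
read_term_lists <- function(dir) {
  if (is.null(dir)) return(NULL)
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) return(NULL)
  out <- lapply(files, function(f) {
    lines <- trimws(readLines(f, warn = FALSE))
    lines[nzchar(lines)]
  })
  names(out) <- tools::file_path_sans_ext(basename(files))
  out
}

# Resolve input -> normalized intensity table + design context.
.prepare_run <- function(config) {
  pg <- read_protein_groups(config$input$path, flavor = config$input$flavor)
  pg <- filter_protein_groups(pg)
  tab <- to_intensity_table(pg)
  tab <- apply_normalization(tab, config$normalization$method,
                             seed = config$normalization$seed)
  design <- build_design(sample_names(tab),
                         separator = config$design$separator)
  groups <- groups_at_level(design, config$design$level)
  policy <- threshold_policy(n_full = config$threshold$n_full,
                             n_half = config$threshold$n_half,
                             steepness = config$threshold$steepness)
  list(tab = tab, design = design, groups = groups, policy = policy,
       pathways = read_term_lists(config$lists$pathways_dir),
       go_terms = read_term_lists(config$lists$go_dir))
}

# One entry per analysis: compute(ctx, config) -> data.frame,
# plot(result) draws on the current device.
.analysis_registry <- function() {
  list(
    detection_counts = list(
      compute = function(ctx, cfg) detection_counts(ctx$groups, ctx$tab),
      plot = plot_detection_counts),
    detected_per_sample = list(
      compute = function(ctx, cfg) detected_per_sample(ctx$groups, ctx$tab),
      plot = plot_detected_per_sample),
    venn_diagrams = list(
      compute = function(ctx, cfg) {
        res <- lapply(names(ctx$groups), function(g) {
          r <- venn_within_group(ctx$groups[[g]], ctx$tab)
          r$group <- g
          r
        })
        out <- do.call(rbind, res)
        attr(out, "style") <- attr(res[[1L]], "style")
        attr(out, "sets") <- attr(res[[1L]], "sets")
        out
      },
      plot = function(res) {
        p <- ggplot2::ggplot(res,
               ggplot2::aes(x = .data$region, y = .data$n_proteins)) +
          ggplot2::geom_col(fill = "steelblue") +
          ggplot2::facet_wrap(~ .data$group, scales = "free_x") +
          ggplot2::labs(x = "intersection region", y = "proteins",
                        title = "Sample Venn regions per group") +
          ggplot2::theme_bw() +
          ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                             hjust = 1))
        print(p)
      }),
    venn_groups = list(
      compute = function(ctx, cfg)
        venn_between_groups(ctx$groups, ctx$tab, ctx$policy),
      plot = function(res) plot_venn(res, title = "Group Venn (thresholded)")),
    pca_overview = list(
      compute = function(ctx, cfg) pca_overview(ctx$groups, ctx$tab),
      plot = plot_pca_overview),
    intensity_histogram = list(
      compute = function(ctx, cfg)
        intensity_histogram(ctx$groups, ctx$tab, bins = cfg$histogram_bins),
      plot = plot_intensity_histogram),
    relative_sd = list(
      compute = function(ctx, cfg)
        relative_sd(ctx$groups, ctx$tab, ctx$policy),
      plot = plot_relative_sd),
    scatter_replicates = list(
      compute = function(ctx, cfg) scatter_replicates(ctx$groups, ctx$tab),
      plot = plot_scatter_replicates),
    experiment_comparison = list(
      compute = function(ctx, cfg) {
        if (length(ctx$groups) < 2L) {
          stop("experiment_comparison needs >= 2 groups", call. = FALSE)
        }
        experiment_comparison(ctx$groups, ctx$tab, ctx$policy)
      },
      plot = plot_experiment_comparison),
    rank = list(
      compute = function(ctx, cfg) {
        out <- do.call(rbind, lapply(names(ctx$groups), function(g) {
          r <- rank_plot(ctx$groups[[g]], ctx$tab, ctx$pathways)
          r$group <- g
          r
        }))
        out
      },
      plot = function(res) plot_rank(res[res$group == res$group[1L], ],
                                     res$group[1L])),
    pathway_analysis = list(
      compute = function(ctx, cfg) {
        if (is.null(ctx$pathways)) {
          stop("no pathway lists configured (lists$pathways_dir)",
               call. = FALSE)
        }
        pathway_analysis(ctx$groups, ctx$tab, ctx$pathways, ctx$policy)
      },
      plot = plot_pathway_analysis),
    go_analysis = list(
      compute = function(ctx, cfg) {
        if (is.null(ctx$go_terms)) {
          stop("no GO term lists configured (lists$go_dir)", call. = FALSE)
        }
        go_analysis(ctx$groups, ctx$tab, ctx$go_terms)
      },
      plot = plot_go_analysis),
    volcano = list(
      compute = function(ctx, cfg) {
        gn <- names(ctx$groups)
        ga <- cfg$volcano$group_a %||% gn[1L]
        gb <- cfg$volcano$group_b %||% gn[2L]
        if (is.na(gb)) stop("volcano needs two groups", call. = FALSE)
        if (!all(c(ga, gb) %in% gn)) {
          stop("volcano groups not found at the selected level: ",
               ga, ", ", gb, call. = FALSE)
        }
        volcano(ctx$groups[[ga]], ctx$groups[[gb]], ctx$tab, ctx$policy,
                pathways = ctx$pathways,
                annotate_top = cfg$volcano$annotate_top,
                name_a = ga, name_b = gb)
      },
      plot = plot_volcano)
  )
}

.write_analysis <- function(name, res, plot_fun, out_dir) {
  csv_path <- file.path(out_dir, paste0(name, ".csv"))
  pdf_path <- file.path(out_dir, paste0(name, ".pdf"))
  utils::write.csv(res, csv_path, row.names = FALSE, fileEncoding = "UTF-8")
  grDevices::pdf(pdf_path, width = 8, height = 6)
  on.exit(grDevices::dev.off(), add = TRUE)
  plot_fun(res)
  invisible(csv_path)
}

#' Run the configured analyses
#'
#' Imports and filters the input table, normalizes it, resolves the design
#' level into groups, and runs every analysis named in \code{config$analyses}.
#' Each analysis writes one PDF figure and one CSV holding the plotted data;
#' a failing analysis is logged and skipped so the remaining analyses still
#' run. The full configuration (with the package version) and a plain-text
#' log (timestamps, input checksum, per-analysis status) are saved alongside.
#'
#' @param config A [default_config()] list with at least \code{input$path}
#'   and \code{output_dir} set.
#' @return The output directory, invisibly. The per-analysis results are
#'   attached as attribute \code{"results"}.
#' @export
run_pipeline <- function(config) {
  stopifnot(!is.null(config$input$path), !is.null(config$output_dir))
  if (!(config$normalization$method %in% normalization_methods())) {
    stop("unknown normalization method \"", config$normalization$method,
         "\"; valid methods: ",
         paste(normalization_methods(), collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(config$analyses, list_analyses())
  if (length(unknown) > 0L) {
    stop("unknown analysis name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " lfqpipe ",
           utils::packageVersion("lfqpipe"), " run started"),
    paste0("input: ", config$input$path, " (md5 ",
           unname(tools::md5sum(config$input$path)), ")"),
    paste0("normalization: ", config$normalization$method,
           ", design level: ", config$design$level,
           ", seed: ", config$seed))

  set.seed(as.integer(config$seed) %% .Machine$integer.max)
  ctx <- .prepare_run(config)
  registry <- .analysis_registry()
  results <- list()
  for (name in config$analyses) {
    entry <- registry[[name]]
    status <- tryCatch({
      res <- entry$compute(ctx, config)
      if (is.null(res) || nrow(res) == 0L) {
        stop("analysis produced no rows", call. = FALSE)
      }
      .write_analysis(name, res, entry$plot, out_dir)
      results[[name]] <- res
      "ok"
    }, error = function(e) paste0("ERROR: ", conditionMessage(e)))
    log_lines <- c(log_lines,
                   paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ",
                          name, ": ", status))
  }
  save_config(config, file.path(out_dir, "config.yml"))
  log_lines <- c(log_lines,
                 paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                        " run finished"))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(structure(out_dir, results = results))
}

#' Generate the multi-page QC report
#'
#' Bundles the quality-control views (detected proteins per sample, detection
#' counts, intensity histograms, replicate scatter correlations, relative SD
#' and the PCA overview) into a single multi-page PDF, one analysis per page,
#' computed on exactly the same data as the standalone analyses.
#'
#' @param config A [default_config()] list with \code{input$path} and
#'   \code{output_dir} set.
#' @return Path of the written PDF, invisibly; the page results are attached
#'   as attribute \code{"results"}.
#' @export
qc_report <- function(config) {
  stopifnot(!is.null(config$input$path), !is.null(config$output_dir))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  ctx <- .prepare_run(config)
  if (nrow(ctx$tab$matrix) == 0L) {
    stop("empty intensity table; cannot generate QC report", call. = FALSE)
  }
  qc_names <- c("detected_per_sample", "detection_counts",
                "intensity_histogram", "scatter_replicates", "relative_sd",
                "pca_overview")
  registry <- .analysis_registry()
  results <- lapply(qc_names, function(nm) {
    registry[[nm]]$compute(ctx, config)
  })
  names(results) <- qc_names
  pdf_path <- file.path(config$output_dir, "qc_report.pdf")
  grDevices::pdf(pdf_path, width = 8, height = 6)
  on.exit(grDevices::dev.off(), add = TRUE)
  for (nm in qc_names) registry[[nm]]$plot(results[[nm]])
  invisible(structure(pdf_path, results = results))
}
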