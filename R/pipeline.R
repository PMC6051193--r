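#' Build and validate a pipeline run configuration
#'
#' A run configuration drives [run_pipeline()]: either a `simulate` block
#' (passed to [sim_config()]) or an `input` block (`fastq` + `fasta`, or
#' `fastq` + `sam` for externally aligned data), plus preparation, mapping and
#' composition settings. `validate_run_config()` fills defaults and reports
#' all problems at once; `read_run_config()` loads a YAML file.
#'
#' @param ... Configuration fields: `seed`, `simulate`, `input`, `prep`,
#'   `map`, `window`, `out_dir`.
#' @return A validated configuration of class `rtm_run_config`.
#' @export
run_config <- function(...) {
  validate_run_config(list(...))
}

#' @rdname run_config
#' @param path YAML configuration file.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname run_config
#' @param cfg A named list of configuration fields.
#' @export
validate_run_config <- function(cfg) {
  errors <- character(0)
  note <- function(msg) errors <<- c(errors, msg)
  known <- c("seed", "simulate", "input", "prep", "map", "window", "out_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    note(paste("unknown config field(s):", paste(unknown, collapse = ", ")))
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$window <- as.integer(cfg$window %||% 10L)
  if (cfg$window < 1) note("window must be >= 1")
  if (is.null(cfg$simulate) && is.null(cfg$input)) {
    note("either a 'simulate' or an 'input' block is required")
  }
  if (!is.null(cfg$simulate) && !is.null(cfg$input)) {
    note("'simulate' and 'input' blocks are mutually exclusive")
  }
  sim_defaults <- NULL
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    if (isTRUE(sim_args)) sim_args <- list()
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    sim_defaults <- tryCatch(do.call(sim_config, sim_args),
                             error = function(e) {
                               note(paste("simulate:", conditionMessage(e)))
                               NULL
                             })
    cfg$simulate <- sim_defaults
  }
  if (!is.null(cfg$input)) {
    if (is.null(cfg$input$fastq)) {
      note("input$fastq is required")
    } else if (!file.exists(cfg$input$fastq)) {
      note(paste("input$fastq does not exist:", cfg$input$fastq))
    }
    if (is.null(cfg$input$fasta) && is.null(cfg$input$sam)) {
      note("input needs 'fasta' (built-in exact mapping) or 'sam' (external alignment)")
    }
    for (f in c("fasta", "sam")) {
      if (!is.null(cfg$input[[f]]) && !file.exists(cfg$input[[f]])) {
        note(paste0("input$", f, " does not exist: ", cfg$input[[f]]))
      }
    }
    cfg$input$mode <- cfg$input$mode %||% "genome"
    if (!cfg$input$mode %in% c("genome", "transcriptome")) {
      note("input$mode must be 'genome' or 'transcriptome'")
    }
  }
  prep <- cfg$prep %||% list()
  prep$pattern <- prep$pattern %||%
    (if (!is.null(sim_defaults)) sim_defaults$barcode_pattern else "NNNXXXXNN")
  prep$samples <- unlist(prep$samples) %||%
    (if (!is.null(sim_defaults)) sim_defaults$sample_table else c(TTGT = "sample1"))
  prep$barcode_mismatches <- prep$barcode_mismatches %||% 0L
  prep$marker <- prep$marker %||%
    (if (!is.null(sim_defaults)) sim_defaults$marker else "CAGTCCGACGATC")
  prep$marker_mismatches <- prep$marker_mismatches %||% 0L
  prep$adapter <- prep$adapter %||%
    (if (!is.null(sim_defaults)) sim_defaults$adapter else "AGATCGGAAGAGC")
  prep$min_overlap <- prep$min_overlap %||% 3L
  prep$max_error_rate <- prep$max_error_rate %||% 0
  prep$min_insert <- prep$min_insert %||% 15L
  prep$include_unassigned <- isTRUE(prep$include_unassigned)
  scheme <- tryCatch(
    barcode_scheme(prep$pattern, prep$samples, prep$barcode_mismatches),
    error = function(e) { note(paste("prep:", conditionMessage(e))); NULL })
  marker <- tryCatch(
    marker_spec(prep$marker, prep$marker_mismatches),
    error = function(e) { note(paste("prep:", conditionMessage(e))); NULL })
  cfg$prep <- prep
  map <- cfg$map %||% list()
  map$engine <- map$engine %||%
    (if (!is.null(cfg$input$sam)) "sam" else "exact")
  if (!map$engine %in% c("exact", "sam")) note("map$engine must be 'exact' or 'sam'")
  if (map$engine == "sam" && is.null(cfg$simulate) && is.null(cfg$input$sam)) {
    note("map$engine = 'sam' requires input$sam")
  }
  map$min_len <- map$min_len %||% 15L
  map$min_mapq <- map$min_mapq %||% 0L
  cfg$map <- map
  if (length(errors) > 0) {
    stop("invalid run configuration:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  }
  cfg$scheme <- scheme
  cfg$marker_spec <- marker
  structure(cfg, class = "rtm_run_config")
}

#' Run the full read-through-marking pipeline
#'
#' Executes preparation (barcode/UMI extraction, marker classification,
#' adapter trimming), mapping (built-in exact mapper or SAM/BAM ingestion),
#' cDNA-start assignment, UMI collapse and the per-group composition analysis.
#' Both marker groups traverse the identical downstream path; the
#' classification only labels reads. Reads with an `UNASSIGNED` sample are
#' excluded after preparation unless `prep$include_unassigned` is set.
#'
#' @param cfg An `rtm_run_config` (from [run_config()] or
#'   [read_run_config()]), or a plain list that will be validated.
#' @return An object of class `rtm_report`; see [glance.rtm_report()]. When
#'   `cfg$out_dir` is set, stats, BED files, matrices and the resolved
#'   configuration are also written there.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "rtm_run_config")) cfg <- validate_run_config(cfg)
  sim <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- simulate_library(cfg$simulate)
    reads <- sim$reads
    refs <- sim$refs
  } else {
    reads <- read_fastq(cfg$input$fastq)
    refs <- if (!is.null(cfg$input$fasta)) {
      read_reference_fasta(cfg$input$fasta, mode = cfg$input$mode)
    } else {
      NULL
    }
  }
  prep <- prepare_reads(reads, cfg$scheme, cfg$marker_spec,
                        adapter = cfg$prep$adapter,
                        min_insert_len = cfg$prep$min_insert,
                        min_overlap = cfg$prep$min_overlap,
                        max_error_rate = cfg$prep$max_error_rate,
                        include_unassigned = cfg$prep$include_unassigned)
  kept <- prep$reads
  if (!cfg$prep$include_unassigned) {
    kept <- kept[kept$sample != UNASSIGNED, , drop = FALSE]
  }
  if (cfg$map$engine == "exact") {
    if (is.null(refs)) stop("exact mapping requires reference sequences",
                            call. = FALSE)
    mapped <- exact_map(kept, refs, min_len = cfg$map$min_len)
    alignments <- mapped$alignments
    map_stats <- mapped$stats
  } else {
    alignments <- read_sam_alignments(cfg$input$sam, min_mapq = cfg$map$min_mapq)
    map_stats <- tibble::tibble(n_input = nrow(kept), too_short = NA_integer_,
                                mapped = nrow(alignments),
                                unmapped = NA_integer_,
                                multimapped = NA_integer_)
  }
  starts <- assign_cdna_starts(alignments)
  dedup <- collapse_umis(starts)
  mf <- marker_fraction(dedup)
  comp <- NULL
  contrast <- NULL
  if (!is.null(refs)) {
    comp <- list(
      read_through = compute_composition(dedup$uniques, refs, w = cfg$window,
                                         group = FLAG_RT),
      remaining = compute_composition(dedup$uniques, refs, w = cfg$window,
                                      group = FLAG_REM)
    )
    contrast <- compare_groups(comp$read_through, comp$remaining)
  }
  report <- structure(list(
    prep = prep,
    map_stats = map_stats,
    dedup = dedup,
    marker_fraction = mf,
    composition = comp,
    contrast = contrast,
    sim_truth = if (!is.null(sim)) sim$truth else NULL,
    config = cfg,
    version = as.character(packageVersion("rtmark")),
    config_hash = rlang::hash(unclass(cfg)[setdiff(names(cfg), "out_dir")])
  ), class = "rtm_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.rtm_report <- function(x, ...) {
  cat("<rtm_report>\n")
  print(glance(x))
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x An `rtm_report`.
#' @param ... Unused.
#' @return One-row tibble with read counts through the stages, the marker
#'   fraction over unique cDNAs and raw reads, and the position +1 argmax base
#'   per group (when composition was computed).
#' @export
glance.rtm_report <- function(x, ...) {
  g <- glance(x$dedup)
  out <- tibble::tibble(
    n_input = x$prep$stats$n_input,
    n_prepared = x$prep$stats$n_emitted,
    n_mapped = x$map_stats$mapped,
    n_unique_cdnas = g$unique_cdnas,
    marker_fraction_unique = g$marker_fraction_unique,
    marker_fraction_raw = g$marker_fraction_raw
  )
  if (!is.null(x$contrast)) {
    out <- dplyr::bind_cols(out, glance(x$contrast))
  }
  out
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  readr::write_tsv(report$prep$stats$by_group, p("prep_groups.tsv"))
  readr::write_tsv(report$prep$stats$discards, p("prep_discards.tsv"))
  write_starts_bed(report$dedup$uniques, p("unique_cdnas.bed"))
  readr::write_tsv(report$dedup$stats, p("dedup_stats.tsv"))
  readr::write_tsv(report$marker_fraction, p("marker_fraction.tsv"))
  if (!is.null(report$composition)) {
    for (nm in names(report$composition)) {
      readr::write_tsv(tidy(report$composition[[nm]]),
                       p(sprintf("composition_%s.tsv", nm)))
    }
    readr::write_tsv(report$contrast$by_base, p("contrast_by_base.tsv"))
    readr::write_tsv(report$contrast$by_offset, p("contrast_by_offset.tsv"))
  }
  json <- list(
    version = report$version,
    config_hash = report$config_hash,
    prep = list(
      n_input = report$prep$stats$n_input,
      n_emitted = report$prep$stats$n_emitted,
      discards = report$prep$stats$discards,
      by_group = report$prep$stats$by_group
    ),
    mapping = report$map_stats,
    dedup = report$dedup$stats,
    marker_fraction = report$marker_fraction
  )
  jsonlite::write_json(json, p("report.json"), auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  resolved <- unclass(report$config)
  resolved$scheme <- NULL
  resolved$marker_spec <- NULL
  if (!is.null(resolved$simulate)) {
    resolved$simulate <- unclass(resolved$simulate)
    resolved$simulate$scheme <- NULL
  }
  yaml::write_yaml(resolved, p("resolved_config.yaml"))
  invisible(out_dir)
}
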