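#' Collapse PCR duplicates by UMI and start position
#'
#' Reads sharing the grouping key `(sample, ref_name, strand, pos, umi)` are
#' collapsed to a single unique cDNA whose `support` is the number of reads
#' collapsed. The key deliberately includes strand (sense/antisense
#' coincidences stay separate) and sample (no cross-experiment merging); UMIs
#' are compared by exact equality only. The collapsed record's `marker_flag`
#' is the majority flag of its reads, ties resolved to `REMAINING` (a
#' read-through and a truncated cDNA of the same molecule start at different
#' positions, so within-key flag conflicts can only be coincidences).
#'
#' @param starts Start-site tibble from [assign_cdna_starts()]: columns
#'   `ref_name`, `pos`, `strand`, `umi`, `sample`, `marker_flag`.
#' @return An object of class `rtm_dedup`: list with `uniques` (tibble of
#'   unique cDNAs with `support`) and `stats` (per sample x flag: `reads_in`,
#'   `unique_cdnas`, `duplication_rate`).
#' @export
collapse_umis <- function(starts) {
  assert_cols(starts, c("ref_name", "pos", "strand", "umi", "sample",
                        "marker_flag"), "starts")
  uniques <- starts |>
    dplyr::group_by(.data$sample, .data$ref_name, .data$strand, .data$pos,
                    .data$umi) |>
    dplyr::summarise(
      support = dplyr::n(),
      n_rt = sum(.data$marker_flag == FLAG_RT),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      marker_flag = ifelse(.data$n_rt * 2L > .data$support, FLAG_RT, FLAG_REM)
    ) |>
    dplyr::select("ref_name", "pos", "strand", "sample", "umi",
                  "marker_flag", "support")
  stats <- uniques |>
    dplyr::group_by(.data$sample, .data$marker_flag) |>
    dplyr::summarise(
      reads_in = sum(.data$support),
      unique_cdnas = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(duplication_rate = .data$reads_in / .data$unique_cdnas)
  raw_by_flag <- dplyr::count(starts, .data$sample, .data$marker_flag,
                              name = "n_reads")
  structure(list(uniques = uniques, stats = stats, raw_by_flag = raw_by_flag),
            class = "rtm_dedup")
}

#' @export
print.rtm_dedup <- function(x, ...) {
  cat(sprintf("<rtm_dedup> %d unique cDNAs from %d reads\n",
              nrow(x$uniques), sum(x$stats$reads_in)))
  print(x$stats)
  invisible(x)
}

#' @export
tidy.rtm_dedup <- function(x, ...) x$uniques

#' @export
glance.rtm_dedup <- function(x, ...) {
  mf <- marker_fraction(x)
  tibble::tibble(
    reads_in = sum(x$stats$reads_in),
    unique_cdnas = sum(x$stats$unique_cdnas),
    duplication_rate = sum(x$stats$reads_in) / sum(x$stats$unique_cdnas),
    marker_fraction_unique = sum(mf$n_rt_unique) / sum(mf$n_unique),
    marker_fraction_raw = sum(mf$n_rt_raw) / sum(mf$n_raw)
  )
}

#' Read-through (marker) fraction per sample
#'
#' The headline statistic of read-through marking: the fraction of cDNAs
#' carrying the 5'-marker. Reported both over unique cDNAs (after UMI
#' collapse) and over raw mapped reads (before collapse); `NA` when a sample
#' has no cDNAs.
#'
#' @param dedup An `rtm_dedup` object from [collapse_umis()].
#' @return Tibble with one row per sample: `n_unique`, `n_rt_unique`,
#'   `frac_unique`, `n_raw`, `n_rt_raw`, `frac_raw`.
#' @export
marker_fraction <- function(dedup) {
  stopifnot(inherits(dedup, "rtm_dedup"))
  u <- dedup$uniques |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      n_unique = dplyr::n(),
      n_rt_unique = sum(.data$marker_flag == FLAG_RT),
      .groups = "drop"
    )
  r <- dedup$raw_by_flag |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      n_raw = sum(.data$n_reads),
      n_rt_raw = sum(.data$n_reads[.data$marker_flag == FLAG_RT]),
      .groups = "drop"
    )
  out <- dplyr::full_join(u, r, by = "sample")
  out |>
    dplyr::mutate(
      frac_unique = ifelse(.data$n_unique > 0,
                           .data$n_rt_unique / .data$n_unique, NA_real_),
      frac_raw = ifelse(.data$n_raw > 0,
                        .data$n_rt_raw / .data$n_raw, NA_real_)
    ) |>
    dplyr::select("sample", "n_unique", "n_rt_unique", "frac_unique",
                  "n_raw", "n_rt_raw", "frac_raw")
}
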