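#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ file (plain or gzipped).
#' @return Tibble with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble::tibble(
    read_id = names(ss),
    sequence = toupper(as.character(ss)),
    quality = as.character(S4Vectors::mcols(ss)$qualities)
  )
}

#' Write reads to FASTQ
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality`.
#' @param path Output path (`.gz` for gzip).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  assert_cols(reads, c("read_id", "sequence", "quality"), "reads")
  ss <- Biostrings::DNAStringSet(reads$sequence)
  names(ss) <- reads$read_id
  Biostrings::writeXStringSet(
    ss, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

#' Prepare raw reads: barcode, marker, adapter, length filter
#'
#' Runs the read-preparation cascade: UMI/barcode extraction
#' ([extract_barcode()]), sample assignment ([demultiplex()]), 5'-marker
#' classification and stripping ([classify_marker()]), 3'-adapter trimming
#' ([trim_adapter()]), and an insert-length filter. Counts are exactly
#' conserved: `n_input == nrow(reads(prep)) + sum(discards)`.
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality` (see
#'   [read_fastq()]).
#' @param scheme A [barcode_scheme()].
#' @param marker A [marker_spec()].
#' @param adapter 3'-adapter DNA string, or `NULL` to skip trimming.
#' @param min_insert_len Minimum insert length kept (default 15); shorter
#'   inserts are discarded and counted as `TOO_SHORT_INSERT`.
#' @param min_overlap,max_error_rate Adapter-matching parameters, see
#'   [trim_adapter()].
#' @param include_unassigned Include reads whose sample is `UNASSIGNED` in the
#'   per-group statistics (they are always emitted; default `FALSE`).
#' @return An object of class `rtm_prep`: a list with `reads` (tibble of
#'   prepared inserts: `read_id`, `umi`, `sample`, `marker_flag`, `insert`,
#'   `insert_quality`) and `stats` (see [glance.rtm_prep()]).
#' @export
prepare_reads <- function(reads, scheme, marker = marker_spec(),
                          adapter = "AGATCGGAAGAGC", min_insert_len = 15L,
                          min_overlap = 3L, max_error_rate = 0,
                          include_unassigned = FALSE) {
  assert_cols(reads, c("read_id", "sequence", "quality"), "reads")
  n_input <- nrow(reads)
  bc <- extract_barcode(reads, scheme)
  n_short_barcode <- sum(bc$too_short)
  kept <- bc[!bc$too_short, , drop = FALSE]
  kept$sample <- demultiplex(kept$expcode, scheme)
  kept <- classify_marker(kept, marker)
  if (!is.null(adapter)) {
    kept <- trim_adapter(kept, adapter, min_overlap = min_overlap,
                         max_error_rate = max_error_rate)
  }
  long_enough <- stringi::stri_length(kept$sequence) >= min_insert_len
  n_short_insert <- sum(!long_enough)
  kept <- kept[long_enough, , drop = FALSE]
  prepared <- tibble::tibble(
    read_id = kept$read_id,
    umi = kept$umi,
    sample = kept$sample,
    marker_flag = kept$marker_flag,
    insert = kept$sequence,
    insert_quality = kept$quality
  )
  group_src <- if (include_unassigned) prepared else
    prepared[prepared$sample != UNASSIGNED, , drop = FALSE]
  by_group <- dplyr::count(group_src, .data$sample, .data$marker_flag,
                           name = "n")
  stats <- list(
    n_input = n_input,
    n_emitted = nrow(prepared),
    discards = tibble::tibble(
      reason = c("TOO_SHORT_BARCODE", "TOO_SHORT_INSERT"),
      n = c(n_short_barcode, n_short_insert)
    ),
    by_group = by_group
  )
  structure(list(reads = prepared, stats = stats), class = "rtm_prep")
}

#' @export
print.rtm_prep <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<rtm_prep> %d reads in, %d emitted, %d discarded\n",
              s$n_input, s$n_emitted, sum(s$discards$n)))
  print(s$by_group)
  invisible(x)
}

#' @rdname prepare_reads
#' @param x An `rtm_prep` object.
#' @param ... Unused.
#' @export
tidy.rtm_prep <- function(x, ...) x$reads

#' One-row summary of a prepared read set
#'
#' @param x An `rtm_prep` object.
#' @param ... Unused.
#' @return One-row tibble: input/emitted/discard counts and the fraction of
#'   emitted reads flagged `READ_THROUGH`.
#' @export
glance.rtm_prep <- function(x, ...) {
  s <- x$stats
  n_rt <- sum(x$reads$marker_flag == FLAG_RT)
  tibble::tibble(
    n_input = s$n_input,
    n_emitted = s$n_emitted,
    n_discarded = sum(s$discards$n),
    frac_read_through = if (s$n_emitted > 0) n_rt / s$n_emitted else NA_real_
  )
}

#' Write prepared reads as an annotated FASTQ
#'
#' Encodes the prep metadata in the read name as
#' `<id>#<umi>#<sample>#<RT|RE>` (the first whitespace-delimited token of the
#' original id is kept, since aligners drop FASTQ comments). [read_sam_alignments()]
#' recovers the metadata from this convention.
#'
#' @param prep An `rtm_prep` object.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_prepared_fastq <- function(prep, path) {
  stopifnot(inherits(prep, "rtm_prep"))
  r <- prep$reads
  ids <- annotate_read_ids(r$read_id, r$umi, r$sample, r$marker_flag)
  write_fastq(tibble::tibble(read_id = ids, sequence = r$insert,
                             quality = r$insert_quality), path)
}

annotate_read_ids <- function(read_id, umi, sample, marker_flag) {
  base <- sub("\\s.*$", "", read_id)
  if (any(grepl("#", base, fixed = TRUE)) || any(grepl("#", sample, fixed = TRUE))) {
    stop("read ids and sample names must not contain '#'", call. = FALSE)
  }
  paste(base, umi, sample, ifelse(marker_flag == FLAG_RT, "RT", "RE"), sep = "#")
}

parse_annotated_ids <- function(ids) {
  parts <- stringi::stri_split_fixed(ids, "#")
  ok <- lengths(parts) == 4
  if (!all(ok)) {
    stop("read name(s) lack the '#umi#sample#flag' annotation: ",
         paste(head(ids[!ok], 3), collapse = ", "), call. = FALSE)
  }
  m <- matrix(unlist(parts), ncol = 4, byrow = TRUE)
  tibble::tibble(
    read_id = m[, 1],
    umi = m[, 2],
    sample = m[, 3],
    marker_flag = ifelse(m[, 4] == "RT", FLAG_RT, FLAG_REM)
  )
}
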