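#' Exact-match alignment of inserts against a small reference set
#'
#' A deliberately strict aligner for synthetic references: an insert is
#' reported only when it occurs exactly once across the reference set
#' (`"genome"` mode searches both strands, `"transcriptome"` mode the sense
#' strand only). Zero occurrences count as unmapped, more than one as
#' multimapped (discarded, counted). Real libraries should be aligned
#' externally and ingested with [read_sam_alignments()]; this mapper exists so
#' that simulated end-to-end runs are hermetic.
#'
#' Occurrences are distinct `(reference, strand, position)` triples; a
#' palindromic insert hitting the same locus on both strands therefore counts
#' twice. Coordinates are 0-based half-open; a minus-strand alignment's
#' `start`/`end` are on the forward reference.
#'
#' @param reads An `rtm_prep` object, or a tibble with column `insert` (plus
#'   optional metadata columns `read_id`, `umi`, `sample`, `marker_flag`).
#' @param refs An [reference_set()].
#' @param min_len Minimum insert length attempted (default 15); shorter
#'   inserts are counted `too_short`.
#' @return An object of class `rtm_map`: list with `alignments` (tibble:
#'   `read_id`, `ref_name`, `start`, `end`, `strand`, metadata) and `stats`
#'   (one-row tibble: `n_input`, `too_short`, `mapped`, `unmapped`,
#'   `multimapped`).
#' @export
exact_map <- function(reads, refs, min_len = 15L) {
  stopifnot(inherits(refs, "rtm_refs"))
  if (inherits(reads, "rtm_prep")) reads <- reads$reads
  assert_cols(reads, "insert", "reads")
  n_input <- nrow(reads)
  len <- stringi::stri_length(reads$insert)
  keep <- len >= min_len
  too_short <- sum(!keep)
  query <- reads[keep, , drop = FALSE]
  hits <- count_occurrences(unique(query$insert), refs)
  per_read <- dplyr::left_join(
    tibble::tibble(row = seq_len(nrow(query)), insert = query$insert),
    hits$counts, by = "insert"
  )
  uniq <- per_read[per_read$n_occ == 1L, , drop = FALSE]
  aln1 <- dplyr::inner_join(uniq, hits$single, by = "insert")
  meta_cols <- intersect(c("read_id", "umi", "sample", "marker_flag"),
                         names(query))
  alignments <- dplyr::bind_cols(
    query[aln1$row, meta_cols, drop = FALSE],
    tibble::tibble(ref_name = aln1$ref_name, start = aln1$start,
                   end = aln1$end, strand = aln1$strand)
  )
  alignments <- alignments[order(aln1$row), , drop = FALSE]
  stats <- tibble::tibble(
    n_input = n_input,
    too_short = too_short,
    mapped = nrow(alignments),
    unmapped = sum(per_read$n_occ == 0L),
    multimapped = sum(per_read$n_occ > 1L)
  )
  structure(list(alignments = tibble::as_tibble(alignments), stats = stats),
            class = "rtm_map")
}

# All exact occurrences of each insert across refs. Returns counts per insert
# and, for inserts with exactly one occurrence, that occurrence's coordinates.
# Candidate positions come from a prefix k-mer index of each reference;
# candidates are then verified over the full insert length.
count_occurrences <- function(inserts, refs) {
  if (length(inserts) == 0) {
    empty <- tibble::tibble(insert = character(), ref_name = character(),
                            start = integer(), end = integer(),
                            strand = character())
    return(list(counts = tibble::tibble(insert = character(), n_occ = integer()),
                single = empty))
  }
  k <- min(stringi::stri_length(inserts))
  queries <- tibble::tibble(insert = inserts,
                            kmer = stringi::stri_sub(inserts, 1L, k),
                            len = stringi::stri_length(inserts),
                            strand = "+")
  if (refs$mode == "genome") {
    rc <- revcomp(inserts)
    queries <- dplyr::bind_rows(
      queries,
      tibble::tibble(insert = inserts, kmer = stringi::stri_sub(rc, 1L, k),
                     len = stringi::stri_length(inserts), strand = "-",
                     rc_insert = rc)
    )
  }
  occ <- vector("list", length(refs))
  for (i in seq_along(refs)) {
    nm <- names(refs)[i]
    s <- refs$seq[[i]]
    L <- stringi::stri_length(s)
    if (L < k) next
    index <- tibble::tibble(
      pos = 0:(L - k),
      kmer = stringi::stri_sub(s, 1:(L - k + 1L), length = k)
    )
    cand <- dplyr::inner_join(queries, index, by = "kmer",
                              relationship = "many-to-many")
    if (nrow(cand) == 0) next
    cand <- cand[cand$pos + cand$len <= L, , drop = FALSE]
    if (nrow(cand) == 0) next
    found <- stringi::stri_sub(s, cand$pos + 1L, length = cand$len)
    target <- ifelse(cand$strand == "+", cand$insert, cand$rc_insert %||% cand$insert)
    ok <- found == target
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0) next
    occ[[i]] <- tibble::tibble(insert = cand$insert, ref_name = nm,
                               start = as.integer(cand$pos),
                               end = as.integer(cand$pos + cand$len),
                               strand = cand$strand)
  }
  occ <- dplyr::bind_rows(occ)
  if (nrow(occ) == 0) {
    occ <- tibble::tibble(insert = character(), ref_name = character(),
                          start = integer(), end = integer(),
                          strand = character())
  }
  counts <- dplyr::count(occ, .data$insert, name = "n_occ")
  counts <- dplyr::left_join(tibble::tibble(insert = inserts), counts,
                             by = "insert")
  counts$n_occ[is.na(counts$n_occ)] <- 0L
  single_ins <- counts$insert[counts$n_occ == 1L]
  single <- occ[occ$insert %in% single_ins, , drop = FALSE]
  list(counts = counts, single = single)
}

#' @export
print.rtm_map <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<rtm_map> %d reads: %d mapped, %d unmapped, %d multimapped, %d too short\n",
              s$n_input, s$mapped, s$unmapped, s$multimapped, s$too_short))
  invisible(x)
}

#' @export
tidy.rtm_map <- function(x, ...) x$alignments

#' @export
glance.rtm_map <- function(x, ...) x$stats

#' Ingest alignments from SAM/BAM
#'
#' Reads primary, mapped records with `MAPQ >= min_mapq` and recovers the prep
#' metadata either from tags `XU` (UMI), `XB` (sample) and `XF` (`RT`/`RE`) or
#' from the `<id>#<umi>#<sample>#<RT|RE>` read-name convention written by
#' [write_prepared_fastq()]. 1-based SAM coordinates are converted to the
#' package's 0-based half-open convention. Soft clips do not consume reference,
#' so the reported start is the first aligned base, as required for cDNA-start
#' assignment.
#'
#' @param path SAM or BAM file (SAM is converted in a temporary directory).
#' @param min_mapq Minimum mapping quality kept (records with missing MAPQ
#'   pass when `min_mapq` is 0).
#' @return Tibble of alignments (`read_id`, `ref_name`, `start`, `end`,
#'   `strand`, `umi`, `sample`, `marker_flag`).
#' @export
read_sam_alignments <- function(path, min_mapq = 0L) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "mapq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    tag = c("XU", "XB", "XF")
  )
  ga <- GenomicAlignments::readGAlignments(path, param = param)
  mc <- S4Vectors::mcols(ga)
  tags_ok <- !is.null(mc$XU) && !is.null(mc$XB) && !is.null(mc$XF) &&
    !anyNA(mc$XU) && !anyNA(mc$XB) && !anyNA(mc$XF)
  if (tags_ok) {
    meta <- tibble::tibble(
      read_id = mc$qname, umi = mc$XU, sample = mc$XB,
      marker_flag = ifelse(mc$XF == "RT", FLAG_RT, FLAG_REM)
    )
  } else {
    meta <- parse_annotated_ids(mc$qname)
  }
  keep <- if (min_mapq > 0) !is.na(mc$mapq) & mc$mapq >= min_mapq else
    rep(TRUE, length(ga))
  tibble::tibble(
    read_id = meta$read_id,
    ref_name = as.character(GenomicAlignments::seqnames(ga)),
    start = GenomicAlignments::start(ga) - 1L,
    end = GenomicAlignments::end(ga),
    strand = as.character(GenomicAlignments::strand(ga)),
    umi = meta$umi,
    sample = meta$sample,
    marker_flag = meta$marker_flag
  )[keep, , drop = FALSE]
}

#' Assign cDNA start sites from alignments
#'
#' The cDNA start is the reference coordinate of the read's first aligned
#' nucleotide: the alignment start on the plus strand, `end - 1` on the minus
#' strand. This is the operative signal of truncation-based CLIP: for
#' truncated cDNAs it sits at the crosslink site, for read-through cDNAs at
#' the RNase cleavage site.
#'
#' @param alignments Tibble of alignments (from [exact_map()] via `tidy()`, or
#'   [read_sam_alignments()]), or an `rtm_map` object.
#' @return Tibble of start sites: `ref_name`, `pos`, `strand` plus metadata
#'   columns carried through.
#' @export
assign_cdna_starts <- function(alignments) {
  if (inherits(alignments, "rtm_map")) alignments <- alignments$alignments
  assert_cols(alignments, c("ref_name", "start", "end", "strand"), "alignments")
  out <- alignments
  out$pos <- as.integer(ifelse(alignments$strand == "+", alignments$start,
                               alignments$end - 1L))
  out$start <- NULL
  out$end <- NULL
  dplyr::relocate(tibble::as_tibble(out), dplyr::any_of("read_id"),
                  "ref_name", "pos", "strand")
}

#' BED6 output and input of start sites
#'
#' Start sites are written as single-nucleotide intervals `[pos, pos + 1)`
#' (BED is 0-based half-open), with `name = umi|sample|marker_flag`, the
#' `score` column carrying `support` when present (1 otherwise), and the
#' strand column set. `read_starts_bed()` inverts `write_starts_bed()`
#' exactly.
#'
#' @param starts Tibble with `ref_name`, `pos`, `strand`, `umi`, `sample`,
#'   `marker_flag` and optionally `support`.
#' @param path BED file path.
#' @return `write_starts_bed()`: `path` invisibly; `read_starts_bed()`: a
#'   start-site tibble with `support`.
#' @export
write_starts_bed <- function(starts, path) {
  assert_cols(starts, c("ref_name", "pos", "strand", "umi", "sample",
                        "marker_flag"), "starts")
  score <- if ("support" %in% names(starts)) starts$support else
    rep(1L, nrow(starts))
  gr <- GenomicRanges::GRanges(
    seqnames = starts$ref_name,
    ranges = IRanges::IRanges(start = starts$pos + 1L, width = 1L),
    strand = starts$strand
  )
  S4Vectors::mcols(gr)$name <- paste(starts$umi, starts$sample,
                                     starts$marker_flag, sep = "|")
  S4Vectors::mcols(gr)$score <- score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_starts_bed
#' @export
read_starts_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  name <- S4Vectors::mcols(gr)$name
  parts <- stringi::stri_split_fixed(name, "|")
  if (any(lengths(parts) != 3)) {
    stop("BED name column is not umi|sample|marker_flag", call. = FALSE)
  }
  m <- matrix(unlist(parts), ncol = 3, byrow = TRUE)
  tibble::tibble(
    ref_name = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr) - 1L,
    strand = as.character(GenomicRanges::strand(gr)),
    umi = m[, 1],
    sample = m[, 2],
    marker_flag = m[, 3],
    support = as.integer(S4Vectors::mcols(gr)$score)
  )
}
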