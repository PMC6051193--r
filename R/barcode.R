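#' Barcode scheme
#'
#' Declarative layout of the 5' barcode added by the reverse-transcription
#' primer: `N` marks a random UMI position, `X` a fixed experimental-barcode
#' position. The pattern is read 5' to 3' from the first base of the read.
#'
#' @param pattern String over `{N, X}`, e.g. `"NNNXXXXNN"` (5-nt UMI split
#'   around a 4-nt experimental barcode).
#' @param sample_table Named character vector mapping experimental-barcode
#'   sequence to sample name, e.g. `c(TTGT = "sample1")`. May be empty only
#'   when the pattern has no `X`.
#' @param max_barcode_mismatches Maximum Hamming distance tolerated when
#'   assigning an observed barcode to a sample.
#' @return An object of class `rtm_scheme`.
#' @export
#' @examples
#' barcode_scheme("NNNXXXXNN", c(TTGT = "s1"))
barcode_scheme <- function(pattern, sample_table = character(),
                           max_barcode_mismatches = 0L) {
  if (!is.character(pattern) || length(pattern) != 1 || nchar(pattern) == 0) {
    stop("pattern must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(pattern, "")[[1]]
  if (!all(chars %in% c("N", "X"))) {
    stop("pattern may only contain N (UMI) and X (barcode)", call. = FALSE)
  }
  n_pos <- which(chars == "N")
  x_pos <- which(chars == "X")
  sample_table <- unlist(sample_table) %||% character()
  mm <- as.integer(max_barcode_mismatches)
  if (mm < 0) stop("max_barcode_mismatches must be >= 0", call. = FALSE)
  if (length(x_pos) > 0 && length(sample_table) > 0) {
    keys <- names(sample_table)
    if (is.null(keys) || any(nchar(keys) != length(x_pos))) {
      stop("every sample_table barcode must have length ",
           length(x_pos), " (the number of X in the pattern)", call. = FALSE)
    }
    if (anyDuplicated(keys)) stop("duplicate barcodes in sample_table", call. = FALSE)
    if (length(keys) > 1) {
      for (i in seq_along(keys)[-1]) {
        d <- hamming_to(keys[seq_len(i - 1)], keys[i])
        if (any(d <= mm)) {
          stop("sample_table barcodes within max_barcode_mismatches of each other: ",
               keys[i], " vs ", keys[seq_len(i - 1)][which(d <= mm)[1]],
               call. = FALSE)
        }
      }
    }
  }
  structure(list(pattern = pattern, n_pos = n_pos, x_pos = x_pos,
                 sample_table = sample_table,
                 max_barcode_mismatches = mm),
            class = "rtm_scheme")
}

#' @export
print.rtm_scheme <- function(x, ...) {
  cat(sprintf("<rtm_scheme> pattern %s (UMI %d nt, barcode %d nt), %d sample(s), mm <= %d\n",
              x$pattern, length(x$n_pos), length(x$x_pos),
              length(x$sample_table), x$max_barcode_mismatches))
  invisible(x)
}

# Characters of x at fixed 1-based positions, concatenated per element.
chars_at <- function(x, pos) {
  if (length(pos) == 0) return(rep("", length(x)))
  cols <- lapply(pos, function(j) stringi::stri_sub(x, j, j))
  do.call(paste0, cols)
}

#' Extract UMI and experimental barcode from reads
#'
#' Splits each read into the UMI (bases at `N` positions), the experimental
#' barcode (bases at `X` positions) and the remaining read. Reads not strictly
#' longer than the pattern are flagged for discard (`TOO_SHORT_BARCODE`).
#'
#' @param reads Tibble with columns `read_id`, `sequence`, `quality`.
#' @param scheme An [barcode_scheme()] object.
#' @return Tibble with columns `read_id`, `umi`, `expcode`, `sequence`,
#'   `quality` (barcode removed) and logical `too_short`.
#' @export
extract_barcode <- function(reads, scheme) {
  stopifnot(inherits(scheme, "rtm_scheme"))
  assert_cols(reads, c("read_id", "sequence", "quality"), "reads")
  plen <- nchar(scheme$pattern)
  len <- stringi::stri_length(reads$sequence)
  too_short <- len <= plen
  prefix <- stringi::stri_sub(reads$sequence, 1, plen)
  tibble::tibble(
    read_id = reads$read_id,
    umi = ifelse(too_short, NA_character_, chars_at(prefix, scheme$n_pos)),
    expcode = ifelse(too_short, NA_character_, chars_at(prefix, scheme$x_pos)),
    sequence = ifelse(too_short, NA_character_,
                      stringi::stri_sub(reads$sequence, plen + 1L)),
    quality = ifelse(too_short, NA_character_,
                     stringi::stri_sub(reads$quality, plen + 1L)),
    too_short = too_short
  )
}

#' Assign observed barcodes to samples
#'
#' Each barcode is assigned to the sample whose key is nearest in Hamming
#' distance, provided the distance is at most `max_barcode_mismatches` and the
#' nearest key is unique; otherwise `"UNASSIGNED"`. Schemes without `X`
#' positions assign everything to the single declared sample, or `"sample1"`
#' if the table is empty.
#'
#' @param expcode Character vector of observed experimental barcodes.
#' @param scheme An [barcode_scheme()] object.
#' @return Character vector of sample names.
#' @export
demultiplex <- function(expcode, scheme) {
  stopifnot(inherits(scheme, "rtm_scheme"))
  if (length(scheme$x_pos) == 0) {
    single <- if (length(scheme$sample_table) >= 1) scheme$sample_table[[1]] else "sample1"
    return(rep(single, length(expcode)))
  }
  keys <- names(scheme$sample_table)
  if (length(keys) == 0) return(rep(UNASSIGNED, length(expcode)))
  code <- ifelse(is.na(expcode), "", expcode)
  d <- vapply(keys, function(k) hamming_to(code, k), integer(length(code)))
  d <- matrix(d, nrow = length(code))
  best <- apply(d, 1, min)
  n_best <- rowSums(d == best)
  hit <- best <= scheme$max_barcode_mismatches & n_best == 1
  out <- rep(UNASSIGNED, length(code))
  if (any(hit)) {
    idx <- apply(d[hit, , drop = FALSE], 1, which.min)
    out[hit] <- unname(scheme$sample_table[idx])
  }
  out
}
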