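#' 5'-marker specification
#'
#' The marker is an RNA oligonucleotide ligated to the 5' end of RNA fragments
#' before reverse transcription. Because it is not complementary to any PCR
#' primer it is sequenced as part of the read, so a read beginning with the
#' marker must come from a cDNA that read through the crosslink site. The
#' default is the DNA form of the marker used in the read-through-marking
#' protocol (RNA CAGUCCGACGAUC).
#'
#' @param sequence DNA string, the marker as it appears at the read 5' end.
#' @param max_mismatches Hamming mismatches tolerated over the marker prefix
#'   (default 0: exact prefix match).
#' @return An object of class `rtm_marker`.
#' @export
#' @examples
#' marker_spec()
marker_spec <- function(sequence = "CAGTCCGACGATC", max_mismatches = 0L) {
  sequence <- toupper(sequence)
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0) {
    stop("marker sequence must be a single non-empty string", call. = FALSE)
  }
  if (!is_dna(sequence)) stop("marker must be DNA (A/C/G/T/N)", call. = FALSE)
  mm <- as.integer(max_mismatches)
  if (mm < 0 || mm >= nchar(sequence)) {
    stop("max_mismatches must be in [0, marker length)", call. = FALSE)
  }
  structure(list(sequence = sequence, max_mismatches = mm),
            class = "rtm_marker")
}

#' @export
print.rtm_marker <- function(x, ...) {
  cat(sprintf("<rtm_marker> %s (mm <= %d)\n", x$sequence, x$max_mismatches))
  invisible(x)
}

#' Classify reads by 5'-marker presence and strip the marker
#'
#' A read whose first `nchar(marker)` bases are within `max_mismatches` of the
#' marker sequence, and which extends beyond the marker, is flagged
#' `READ_THROUGH` and the marker prefix is removed; every other read is
#' flagged `REMAINING` and left unchanged. Classification is total: a read
#' exactly equal to the marker (nothing after it) stays `REMAINING` and is
#' later dropped by the insert-length filter rather than emitted empty.
#'
#' @param reads Tibble with columns `sequence` and `quality` (other columns
#'   are passed through).
#' @param marker A [marker_spec()] object.
#' @return The input tibble with `marker_flag` added and `sequence`/`quality`
#'   stripped of the marker where flagged.
#' @export
classify_marker <- function(reads, marker = marker_spec()) {
  stopifnot(inherits(marker, "rtm_marker"))
  assert_cols(reads, c("sequence", "quality"), "reads")
  mlen <- nchar(marker$sequence)
  seqs <- reads$sequence
  len <- stringi::stri_length(seqs)
  if (marker$max_mismatches == 0L) {
    prefix_hit <- stringi::stri_sub(seqs, 1, mlen) == marker$sequence
  } else {
    prefix_hit <- hamming_to(seqs, marker$sequence) <= marker$max_mismatches
  }
  hit <- !is.na(prefix_hit) & prefix_hit & len > mlen
  out <- reads
  out$marker_flag <- ifelse(hit, FLAG_RT, FLAG_REM)
  out$sequence <- ifelse(hit, stringi::stri_sub(seqs, mlen + 1L), seqs)
  out$quality <- ifelse(hit, stringi::stri_sub(reads$quality, mlen + 1L),
                        reads$quality)
  out
}
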