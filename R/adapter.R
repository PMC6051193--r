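#' Trim the 3' sequencing adapter
#'
#' Finds, for each read, the leftmost position `i` (0-based) at which the read
#' suffix `sequence[i:]` aligns against a prefix of the adapter with at least
#' `min_overlap` overlapping bases and a mismatch fraction of at most
#' `max_error_rate`, and truncates the read to `[0, i)`. Reads without such a
#' position are returned unchanged. With `max_error_rate = 0` this reduces to:
#' the leftmost full occurrence of the adapter, or failing that the longest
#' read suffix equal to an adapter prefix of length `>= min_overlap`.
#'
#' @param reads Tibble with columns `sequence` and `quality` (other columns
#'   pass through).
#' @param adapter Adapter DNA string.
#' @param min_overlap Minimum overlap length (default 3).
#' @param max_error_rate Maximum mismatch fraction within the overlap
#'   (default 0, exact matching).
#' @return The input tibble with `sequence`/`quality` truncated.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 3L, max_error_rate = 0) {
  assert_cols(reads, c("sequence", "quality"), "reads")
  cut <- adapter_cut_index(reads$sequence, adapter, min_overlap, max_error_rate)
  out <- reads
  out$sequence <- stringi::stri_sub(reads$sequence, 1L, cut)
  out$quality <- stringi::stri_sub(reads$quality, 1L, cut)
  out
}

#' Adapter cut positions
#'
#' Lower-level interface to [trim_adapter()]: returns, per sequence, the
#' number of bases kept (equivalently the 0-based cut index `i`); sequences
#' without an adapter hit return their own length.
#'
#' @inheritParams trim_adapter
#' @param sequences Character vector of read sequences.
#' @return Integer vector of kept-prefix lengths.
#' @export
adapter_cut_index <- function(sequences, adapter, min_overlap = 3L,
                              max_error_rate = 0) {
  adapter <- toupper(adapter)
  alen <- nchar(adapter)
  if (alen == 0) stop("adapter must be non-empty", call. = FALSE)
  min_overlap <- as.integer(min_overlap)
  if (min_overlap < 1 || min_overlap > alen) {
    stop("min_overlap must be in [1, adapter length]", call. = FALSE)
  }
  if (max_error_rate < 0 || max_error_rate >= 1) {
    stop("max_error_rate must be in [0, 1)", call. = FALSE)
  }
  rlen <- stringi::stri_length(sequences)
  if (max_error_rate == 0) {
    cut <- rlen
    full <- stringi::stri_locate_first_fixed(sequences, adapter)[, 1]
    found <- !is.na(full)
    cut[found] <- full[found] - 1L
    partial_lens <- if (alen - 1L >= min_overlap) seq(alen - 1L, min_overlap) else integer(0)
    for (L in partial_lens) {
      pref <- substr(adapter, 1L, L)
      hit <- !found & rlen >= L &
        stringi::stri_sub(sequences, rlen - L + 1L, rlen) == pref
      cut[hit] <- rlen[hit] - L
      found <- found | hit
    }
    return(as.integer(cut))
  }
  a <- utf8ToInt(adapter)
  vapply(sequences, function(s) {
    n <- nchar(s)
    if (n < min_overlap) return(n)
    sv <- utf8ToInt(s)
    for (i in 0:(n - min_overlap)) {
      L <- min(n - i, alen)
      mm <- sum(sv[(i + 1):(i + L)] != a[1:L])
      if (mm <= max_error_rate * L + 1e-9) return(i)
    }
    n
  }, integer(1), USE.NAMES = FALSE)
}
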