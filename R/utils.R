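DNA_BASES <- c("A", "C", "G", "T")

FLAG_RT <- "READ_THROUGH"
FLAG_REM <- "REMAINING"
UNASSIGNED <- "UNASSIGNED"

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the alphabet A/C/G/T/N.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AANT"))
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

# Hamming distance of each string in `x` to `target`, comparing the first
# nchar(target) characters. Characters missing because a string is shorter
# than target count as mismatches (so do Ns, via plain inequality).
hamming_to <- function(x, target) {
  L <- stringi::stri_length(target)
  mm <- integer(length(x))
  for (j in seq_len(L)) {
    cj <- stringi::stri_sub(x, j, j)
    mm <- mm + (cj != stringi::stri_sub(target, j, j))
  }
  mm
}

# Random DNA strings: n strings of length len, i.i.d. from base_probs.
random_dna <- function(n, len, base_probs = rep(0.25, 4)) {
  if (n == 0L) return(character(0))
  chars <- sample(DNA_BASES, n * len, replace = TRUE, prob = base_probs)
  if (len == 0L) return(rep("", n))
  m <- matrix(chars, nrow = n, ncol = len)
  do.call(paste0, asplit(m, 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

is_dna <- function(x) !stringi::stri_detect_regex(x, "[^ACGTN]")
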