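#' Strand-aware sequence windows around cDNA starts
#'
#' Returns, for each start site, the genomic sequence covering offsets
#' `-w ... -1, +1 ... +w` around the cDNA's first nucleotide (there is no
#' offset 0; offset +1 is the first nucleotide of the cDNA, matching the
#' "position 1" convention of sequence logos over start sites). On the plus
#' strand this is `ref[pos - w, pos + w)`; on the minus strand the reverse
#' complement of `ref[pos - w + 1, pos + w + 1)`. In both cases the character
#' at 0-based index `w` is the cDNA's first nucleotide. Out-of-bounds
#' positions yield `N`.
#'
#' @param refs An [reference_set()].
#' @param starts Tibble with `ref_name`, `pos`, `strand`.
#' @param w Window half-width (>= 1).
#' @return Character vector of windows, each `2 * w` long.
#' @export
window_sequences <- function(refs, starts, w) {
  assert_cols(starts, c("ref_name", "pos", "strand"), "starts")
  w <- as.integer(w)
  if (w < 1) stop("w must be >= 1", call. = FALSE)
  plus <- starts$strand == "+"
  out <- character(nrow(starts))
  if (any(plus)) {
    out[plus] <- ref_slice(refs, starts$ref_name[plus],
                           starts$pos[plus] - w, starts$pos[plus] + w)
  }
  if (any(!plus)) {
    out[!plus] <- revcomp(ref_slice(refs, starts$ref_name[!plus],
                                    starts$pos[!plus] - w + 1L,
                                    starts$pos[!plus] + w + 1L))
  }
  out
}

comp_offsets <- function(w) c(seq(-w, -1L), seq(1L, w))

#' Nucleotide composition around cDNA starts
#'
#' Accumulates per-offset base counts over the windows of a group of unique
#' cDNAs (the Weblogo input matrix). Each unique cDNA contributes once by
#' default, regardless of its PCR support; `weight_by_support = TRUE` weights
#' by collapsed read count instead. Window positions that fall outside the
#' reference contribute `N` and are excluded from that offset's column, so
#' column totals may be below `n_sites`.
#'
#' @param uniques Tibble of start sites (typically `tidy()` of an
#'   [collapse_umis()] result), with `ref_name`, `pos`, `strand` and, unless
#'   `group = NULL`, `marker_flag`.
#' @param refs An [reference_set()].
#' @param w Window half-width (default 10).
#' @param group `"READ_THROUGH"` or `"REMAINING"` to select one marker group,
#'   or `NULL` to use all rows.
#' @param weight_by_support Weight sites by their `support` column.
#' @return An object of class `rtm_composition`: list with `group`, `w`,
#'   `n_sites`, and `counts` (4 x 2w matrix, rows A/C/G/T, columns labelled by
#'   offset).
#' @export
compute_composition <- function(uniques, refs, w = 10L, group = NULL,
                                weight_by_support = FALSE) {
  stopifnot(inherits(refs, "rtm_refs"))
  if (inherits(uniques, "rtm_dedup")) uniques <- uniques$uniques
  if (!is.null(group)) {
    group <- match.arg(group, c(FLAG_RT, FLAG_REM))
    assert_cols(uniques, "marker_flag", "uniques")
    uniques <- uniques[uniques$marker_flag == group, , drop = FALSE]
  }
  w <- as.integer(w)
  offsets <- comp_offsets(w)
  counts <- matrix(0L, nrow = 4, ncol = 2L * w,
                   dimnames = list(DNA_BASES, as.character(offsets)))
  n_sites <- nrow(uniques)
  if (n_sites > 0) {
    win <- window_sequences(refs, uniques, w)
    wt <- if (weight_by_support && "support" %in% names(uniques)) {
      as.integer(uniques$support)
    } else {
      rep(1L, n_sites)
    }
    if (weight_by_support) n_sites <- sum(wt)
    for (j in seq_len(2L * w)) {
      ch <- stringi::stri_sub(win, j, j)
      for (b in DNA_BASES) counts[b, j] <- sum(wt[ch == b])
    }
  }
  structure(list(group = group %||% "ALL", w = w, n_sites = n_sites,
                 counts = counts),
            class = "rtm_composition")
}

#' Per-offset base frequencies of a composition matrix
#'
#' @param x An `rtm_composition`.
#' @return 4 x 2w matrix of frequencies; offsets whose column total is zero
#'   are `NA`.
#' @export
composition_freq <- function(x) {
  stopifnot(inherits(x, "rtm_composition"))
  tot <- colSums(x$counts)
  freq <- sweep(x$counts, 2, tot, "/")
  freq[, tot == 0] <- NA_real_
  freq
}

#' Information content of a base-frequency column
#'
#' Weblogo-style information content over the 4-letter alphabet:
#' `2 + sum(p * log2(p))` bits, with `0 * log2(0) = 0`. No small-sample
#' correction is applied by default.
#'
#' @param p Numeric vector of length 4 summing to 1 (or a matrix with such
#'   columns).
#' @param small_sample_correction Subtract the Weblogo small-sample bias term
#'   `3 / (2 * ln(2) * n)`; requires `n`.
#' @param n Number of sequences behind the column (used only for the
#'   correction).
#' @return Information content in bits, in `[0, 2]`; `NA` for undefined
#'   (all-`NA` or zero-total) columns.
#' @export
#' @examples
#' information_content(c(0.25, 0.25, 0.25, 0.25)) # 0 bits
#' information_content(c(1, 0, 0, 0))             # 2 bits
information_content <- function(p, small_sample_correction = FALSE, n = NULL) {
  if (is.matrix(p)) {
    return(apply(p, 2, information_content,
                 small_sample_correction = small_sample_correction, n = n))
  }
  if (anyNA(p)) return(NA_real_)
  if (abs(sum(p) - 1) > 1e-6) stop("frequencies must sum to 1", call. = FALSE)
  ic <- 2 + sum(ifelse(p > 0, p * log2(p), 0))
  if (small_sample_correction) {
    if (is.null(n)) stop("n required for the small-sample correction", call. = FALSE)
    ic <- ic - 3 / (2 * log(2) * n)
  }
  max(ic, 0)
}

#' @export
print.rtm_composition <- function(x, ...) {
  cat(sprintf("<rtm_composition> group %s, %s sites, offsets -%d..-1, +1..+%d\n",
              x$group, format(x$n_sites), x$w, x$w))
  invisible(x)
}

#' Tidy a composition matrix
#'
#' @param x An `rtm_composition`.
#' @param ... Unused.
#' @return Tibble with one row per offset and base: `offset`, `base`, `count`,
#'   `freq`, and the offset's `info_bits`.
#' @export
tidy.rtm_composition <- function(x, ...) {
  freq <- composition_freq(x)
  ic <- information_content(freq)
  offsets <- comp_offsets(x$w)
  tibble::tibble(
    group = x$group,
    offset = rep(offsets, each = 4),
    base = rep(DNA_BASES, times = length(offsets)),
    count = as.vector(x$counts),
    freq = as.vector(freq),
    info_bits = rep(unname(ic), each = 4)
  )
}

#' @export
glance.rtm_composition <- function(x, ...) {
  freq <- composition_freq(x)
  start_col <- as.character(1)
  tibble::tibble(
    group = x$group,
    n_sites = x$n_sites,
    argmax_start = if (all(is.na(freq[, start_col]))) NA_character_ else
      DNA_BASES[which.max(freq[, start_col])],
    info_bits_start = information_content(freq[, start_col])
  )
}

#' Contrast read-through vs remaining composition
#'
#' Per offset and base: frequency difference (read-through minus remaining)
#' and a pseudocount-stabilised log2 ratio (`+1` on each count, `+4` on the
#' column totals); plus each group's per-offset argmax base. This is the
#' descriptive comparison behind the observation that read-through cDNA starts
#' are adenosine-enriched while the remaining (truncation-dominated) starts
#' are thymidine/uridine-enriched at position +1.
#'
#' @param m_rt,m_rem `rtm_composition` objects for the `READ_THROUGH` and
#'   `REMAINING` groups, computed with the same `w`.
#' @return An object of class `rtm_contrast`: list with `by_base` and
#'   `by_offset` tibbles.
#' @export
compare_groups <- function(m_rt, m_rem) {
  stopifnot(inherits(m_rt, "rtm_composition"),
            inherits(m_rem, "rtm_composition"))
  if (m_rt$w != m_rem$w) stop("window widths differ", call. = FALSE)
  offsets <- comp_offsets(m_rt$w)
  f_rt <- composition_freq(m_rt)
  f_rem <- composition_freq(m_rem)
  tot_rt <- colSums(m_rt$counts)
  tot_rem <- colSums(m_rem$counts)
  lr <- log2(sweep(m_rt$counts + 1, 2, tot_rt + 4, "/")) -
    log2(sweep(m_rem$counts + 1, 2, tot_rem + 4, "/"))
  by_base <- tibble::tibble(
    offset = rep(offsets, each = 4),
    base = rep(DNA_BASES, times = length(offsets)),
    count_rt = as.vector(m_rt$counts),
    count_rem = as.vector(m_rem$counts),
    freq_rt = as.vector(f_rt),
    freq_rem = as.vector(f_rem),
    freq_diff = as.vector(f_rt - f_rem),
    log2_ratio = as.vector(lr)
  )
  argmax <- function(freq) {
    apply(freq, 2, function(col) {
      if (all(is.na(col))) NA_character_ else DNA_BASES[which.max(col)]
    })
  }
  by_offset <- tibble::tibble(
    offset = offsets,
    argmax_rt = unname(argmax(f_rt)),
    argmax_rem = unname(argmax(f_rem)),
    info_bits_rt = unname(information_content(f_rt)),
    info_bits_rem = unname(information_content(f_rem))
  )
  structure(list(by_base = by_base, by_offset = by_offset),
            class = "rtm_contrast")
}

#' @export
print.rtm_contrast <- function(x, ...) {
  cat("<rtm_contrast> per-offset argmax bases:\n")
  print(x$by_offset)
  invisible(x)
}

#' @export
tidy.rtm_contrast <- function(x, ...) x$by_base

#' @export
glance.rtm_contrast <- function(x, ...) {
  at1 <- x$by_offset[x$by_offset$offset == 1L, , drop = FALSE]
  tibble::tibble(argmax_rt_start = at1$argmax_rt,
                 argmax_rem_start = at1$argmax_rem)
}

#' Optional per-offset chi-square test between groups
#'
#' Descriptive logos are the primary output; this helper runs, per offset, a
#' chi-square test on the 4 x 2 count table (read-through vs remaining). Off
#' the default path by design.
#'
#' @inheritParams compare_groups
#' @return Tibble with `offset`, `statistic`, `p_value`.
#' @export
composition_chisq <- function(m_rt, m_rem) {
  stopifnot(inherits(m_rt, "rtm_composition"),
            inherits(m_rem, "rtm_composition"))
  if (m_rt$w != m_rem$w) stop("window widths differ", call. = FALSE)
  offsets <- comp_offsets(m_rt$w)
  res <- lapply(seq_along(offsets), function(j) {
    tab <- cbind(m_rt$counts[, j], m_rem$counts[, j])
    if (any(colSums(tab) == 0)) {
      return(tibble::tibble(offset = offsets[j], statistic = NA_real_,
                            p_value = NA_real_))
    }
    keep <- rowSums(tab) > 0
    ct <- suppressWarnings(stats::chisq.test(tab[keep, , drop = FALSE]))
    tibble::tibble(offset = offsets[j],
                   statistic = unname(ct$statistic),
                   p_value = ct$p.value)
  })
  dplyr::bind_rows(res)
}
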