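#' Logo-style plot of a composition matrix
#'
#' Stacked per-offset bars, scaled either by base frequency or by each base's
#' share of the offset's information content (the Weblogo convention, bar
#' height `freq * info_bits`).
#'
#' @param object An `rtm_composition`.
#' @param scale `"information"` (default) or `"frequency"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rtm_composition <- function(object, scale = c("information", "frequency"),
                                     ...) {
  scale <- match.arg(scale)
  td <- tidy(object)
  td$height <- if (scale == "information") td$freq * td$info_bits else td$freq
  ggplot2::ggplot(td, ggplot2::aes(x = factor(.data$offset,
                                              levels = comp_offsets(object$w)),
                                   y = .data$height, fill = .data$base)) +
    ggplot2::geom_col(width = 0.85) +
    ggplot2::scale_fill_manual(values = c(A = "#109648", C = "#255C99",
                                          G = "#F7B32B", T = "#D62839")) +
    ggplot2::labs(
      x = "offset from cDNA start (+1 = first nucleotide)",
      y = if (scale == "information") "information (bits)" else "frequency",
      fill = "base",
      title = sprintf("%s (n = %s sites)", object$group, format(object$n_sites))
    ) +
    ggplot2::theme_minimal()
}

#' Plot the read-through vs remaining composition contrast
#'
#' Per-offset, per-base frequency differences (read-through minus remaining).
#'
#' @param object An `rtm_contrast` from [compare_groups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rtm_contrast <- function(object, ...) {
  td <- object$by_base
  w <- max(td$offset)
  ggplot2::ggplot(td, ggplot2::aes(x = factor(.data$offset,
                                              levels = comp_offsets(w)),
                                   y = .data$freq_diff, fill = .data$base)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(A = "#109648", C = "#255C99",
                                          G = "#F7B32B", T = "#D62839")) +
    ggplot2::labs(x = "offset from cDNA start",
                  y = "frequency difference (read-through - remaining)",
                  fill = "base") +
    ggplot2::theme_minimal()
}
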