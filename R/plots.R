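#' Plot per-taxon difference profiles
#'
#' Bar panels of the mean 13C-minus-12C relative-abundance difference across
#' fractions, one facet per taxon, for the taxa called labelled (or all taxa
#' when none were called and \code{onlyLabelled = FALSE}). Fraction 1 (left)
#' is the heaviest. Purely presentational: the bars are exactly the
#' \code{\link{deltaProfiles}} entries.
#'
#' @param shifts a \code{\link{ShiftTable}}.
#' @param file optional path; when given the figure is written (PNG/SVG by
#'   extension) and the path returned invisibly.
#' @param onlyLabelled plot only taxa called labelled (default TRUE).
#' @param title optional panel title.
#' @return A ggplot object (invisibly the file path when \code{file} is
#'   given). With an empty selection an annotated placeholder panel is
#'   returned and a message logged.
#' @export
renderDeltaPlot <- function(shifts, file = NULL, onlyLabelled = TRUE,
                            title = NULL) {
  dp <- deltaProfiles(shifts)
  keep <- if (onlyLabelled) labelledTaxa(shifts) else rownames(dp)
  if (!length(keep)) {
    message("renderDeltaPlot: no taxa to plot; emitting placeholder panel")
    p <- ggplot2::ggplot() +
      ggplot2::annotate("text", x = 0, y = 0, label = "no shifted taxa") +
      ggplot2::theme_void() + ggplot2::ggtitle(title %||% "")
  } else {
    dp <- dp[keep, , drop = FALSE]
    df <- data.frame(taxon = rep(rownames(dp), ncol(dp)),
                     fraction = rep(seq_len(ncol(dp)), each = nrow(dp)),
                     delta = as.vector(dp))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = fraction, y = delta)) +
      ggplot2::geom_col(fill = "grey25") +
      ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
      ggplot2::facet_wrap(~taxon) +
      ggplot2::scale_x_continuous(breaks = seq_len(ncol(dp))) +
      ggplot2::labs(x = "gradient fraction (1 = heaviest)",
                    y = expression(Delta * " relative abundance (13C - 12C)"),
                    title = title) +
      ggplot2::theme_bw()
  }
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 8, height = 6, dpi = 150)
    return(invisible(file))
  }
  p
}
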