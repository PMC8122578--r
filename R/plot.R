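#' Plot the binned insertion landscape with a GC track
#'
#' Per-chromosome insertion density over fixed-width bins with the GC
#' fraction overlaid — a linear rendition of the circular landscape
#' view. Requires ggplot2.
#'
#' @param bins data.frame from [bin_landscape()].
#' @return a ggplot object.
#' @export
plot_landscape <- function(bins) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  mid <- (bins$bin_start + bins$bin_end) / 2
  scale <- max(bins$insertion_count, 1)
  df <- data.frame(chrom = bins$chrom, mid = mid / 1e6,
                   count = bins$insertion_count,
                   gc_scaled = bins$gc_fraction * scale)
  ggplot2::ggplot(df, ggplot2::aes(x = mid)) +
    ggplot2::geom_col(ggplot2::aes(y = count), fill = "grey35") +
    ggplot2::geom_line(ggplot2::aes(y = gc_scaled), colour = "firebrick") +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "insertions per bin",
                  title = "Tnt1 insertion landscape",
                  subtitle = "red line: GC fraction (scaled)") +
    ggplot2::theme_minimal()
}
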