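#' RSCU heatmap
#'
#' Samples-by-codons tile plot of RSCU values, codons grouped by amino
#' acid along the x axis.
#'
#' @param rscu_profiles RSCU tibble from [rscu()].
#' @param sample_order Optional sample ordering (e.g. by cluster).
#' @return A ggplot object.
#' @export
plot_rscu_heatmap <- function(rscu_profiles, sample_order = NULL) {
  long <- tidyr::pivot_longer(rscu_profiles, -"sample_id",
                              names_to = "codon", values_to = "rscu")
  aa <- codon_aa_map(sense = TRUE)
  long$codon <- factor(long$codon, levels = sense_codons()[order(aa[sense_codons()])])
  if (!is.null(sample_order)) {
    long$sample_id <- factor(long$sample_id, levels = sample_order)
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$codon, y = .data$sample_id,
                                     fill = .data$rscu)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "RSCU") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6))
}
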