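#' Plot the Pc distribution of one cohort
#'
#' Violin plus box plot of the per-gene composite correlation index, with the
#' number of transcripts analysed in the axis label.
#'
#' @param object A `pc_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pc_fit
#' @export
autoplot.pc_fit <- function(object, ...) {
  ok <- pc_values(object)
  ggplot2::ggplot(ok, ggplot2::aes(x = sprintf("G = %d", nrow(ok)), y = .data$pc)) +
    ggplot2::geom_violin(fill = "grey85", colour = NA) +
    ggplot2::geom_boxplot(width = 0.12, outlier.size = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "composite correlation index (Pc)") +
    ggplot2::theme_minimal()
}

#' Rank scatter of Pc values
#'
#' Genes ordered by Pc, one point per gene -- the whole-transcriptome view in
#' which retained (positive) and inverted (negative) coordination separate.
#'
#' @param pc A `pc_fit` or Pc tibble.
#' @return A ggplot object.
#' @export
plot_pc_scatter <- function(pc) {
  ok <- dplyr::arrange(pc_values(pc), .data$pc)
  ok$rank <- seq_len(nrow(ok))
  ggplot2::ggplot(ok, ggplot2::aes(.data$rank, .data$pc)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", linewidth = 0.3) +
    ggplot2::labs(x = "transcripts (ranked)", y = "Pc") +
    ggplot2::theme_minimal()
}

#' Compare Pc distributions of two cohorts
#'
#' Side-by-side violin/box plots of the analysed Pc values per cohort.
#'
#' @param object A `pc_comparison`.
#' @param pc_a,pc_b The Pc tables the comparison was built from (the
#'   comparison object stores summaries only).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pc_comparison
#' @export
autoplot.pc_comparison <- function(object, pc_a, pc_b, ...) {
  dat <- dplyr::bind_rows(
    dplyr::mutate(pc_values(pc_a), cohort = object$meta$labels[1]),
    dplyr::mutate(pc_values(pc_b), cohort = object$meta$labels[2])
  )
  ggplot2::ggplot(dat, ggplot2::aes(.data$cohort, .data$pc, fill = .data$cohort)) +
    ggplot2::geom_violin(colour = NA, alpha = 0.6) +
    ggplot2::geom_boxplot(width = 0.12, fill = "white", outlier.size = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "Pc",
                  subtitle = sprintf("raw Mann-Whitney p = %.2g", object$raw$p_value)) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Per-gene correlation-profile violins, young vs old
#'
#' Shows the distribution of a gene's Pearson correlations with all partners
#' in each condition (see [gene_r_profiles()]); a coordination inversion
#' appears as the two distributions mirroring each other.
#'
#' @param profiles Tibble from [gene_r_profiles()].
#' @param gene Optional gene name for the title.
#' @return A ggplot object.
#' @export
plot_gene_profiles <- function(profiles, gene = NULL) {
  long <- tidyr::pivot_longer(profiles, c("r_young", "r_old"),
                              names_to = "condition", values_to = "r",
                              names_prefix = "r_")
  long$condition <- factor(long$condition, levels = c("young", "old"))
  ggplot2::ggplot(long, ggplot2::aes(.data$condition, .data$r, fill = .data$condition)) +
    ggplot2::geom_violin(colour = NA, alpha = 0.7) +
    ggplot2::geom_boxplot(width = 0.1, fill = "white", outlier.size = 0.3) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "Pearson R with partners", title = gene) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
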