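#' Volcano plot of a DE table
#'
#' @param object A `stress_de` tibble from [run_de()] or [test_contrast()].
#' @param ... Unused.
#' @return A ggplot: log2 fold change against -log10 adjusted p, faceted by
#'   contrast, significant genes colored by direction.
#' @method autoplot stress_de
#' @export
autoplot.stress_de <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      neglog_q = -log10(pmax(.data$qvalue, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, .data$neglog_q,
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            none = "grey70")) +
    ggplot2::facet_wrap(ggplot2::vars(.data$contrast)) +
    ggplot2::labs(x = "log2 fold change vs CK",
                  y = expression(-log[10] ~ "adjusted p"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of response-mode composition
#'
#' @param mode_summary Tibble from [summarize_modes()] (the aggregate
#'   `unpredictable` row is dropped).
#' @return A ggplot of per-mode fractions.
#' @export
plot_mode_summary <- function(mode_summary) {
  df <- dplyr::filter(mode_summary, .data$meta_mode != "unpredictable")
  df$meta_mode <- factor(df$meta_mode, levels = .modes)
  ggplot2::ggplot(df, ggplot2::aes(.data$meta_mode, .data$fraction)) +
    ggplot2::geom_col(fill = "#27ae60") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "fraction of assigned genes") +
    ggplot2::theme_minimal()
}

#' Mode-fraction stability across top-N gene sets
#'
#' @param stability Result of [stability_check()].
#' @return A ggplot of mode fractions per top-N value.
#' @export
plot_stability <- function(stability) {
  df <- dplyr::filter(stability$fractions, .data$meta_mode != "unpredictable")
  df$meta_mode <- factor(df$meta_mode, levels = .modes)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$top_n), .data$fraction,
                                   group = .data$meta_mode,
                                   colour = .data$meta_mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "top-N genes per contrast", y = "mode fraction",
                  colour = "mode") +
    ggplot2::theme_minimal()
}

#' Fold-change heat map of candidate subgroups
#'
#' @param subgroups Tibble from [cluster_subgroups()].
#' @return A ggplot tile map of (CT, DT, CD) log2 fold changes, genes ordered
#'   by subgroup.
#' @export
plot_candidate_heatmap <- function(subgroups) {
  df <- subgroups |>
    dplyr::arrange(.data$subgroup, dplyr::desc(.data$l_cd)) |>
    dplyr::mutate(gene_id = factor(.data$gene_id, levels = .data$gene_id)) |>
    tidyr::pivot_longer(c("l_ct", "l_dt", "l_cd"),
                        names_to = "contrast", values_to = "log2fc") |>
    dplyr::mutate(contrast = factor(toupper(sub("l_", "", .data$contrast)),
                                    levels = c("CT", "DT", "CD")))
  ggplot2::ggplot(df, ggplot2::aes(.data$contrast, .data$gene_id,
                                   fill = .data$log2fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2980b9", mid = "white", high = "#c0392b") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$subgroup), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 FC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
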