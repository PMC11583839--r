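#' QC intensity distributions per injection, coloured by batch
#'
#' Box plots of log2 QC intensities in injection order — the standard visual
#' check for drift and batch shifts before and after normalization.
#'
#' @param dataset A `metabo_dataset`.
#' @return A ggplot object.
#' @export
plot_qc_boxes <- function(dataset) {
  d <- tidy(dataset) |>
    dplyr::filter(.data$class == "QC", !is.na(.data$intensity)) |>
    dplyr::mutate(sample_id = stats::reorder(.data$sample_id,
                                             .data$injection_order))
  ggplot2::ggplot(d, ggplot2::aes(.data$sample_id, log2(.data$intensity + 1),
                                  fill = .data$batch)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::labs(x = "QC injection", y = "log2 intensity", fill = "batch") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Missing-value summary scatter
#'
#' Per-sample missing rate against injection order with the outlier-triage
#' thresholds drawn in, mirroring the interactive triage view.
#'
#' @param dataset A `metabo_dataset`.
#' @param keep_below,remove_above Triage thresholds (defaults 0.5 / 0.8).
#' @return A ggplot object.
#' @export
plot_missing <- function(dataset, keep_below = 0.5, remove_above = 0.8) {
  prof <- missing_profile(dataset)$sample_rates |>
    dplyr::left_join(dataset$sample_info, by = c("sample_id", "class"))
  ggplot2::ggplot(prof, ggplot2::aes(.data$injection_order, .data$rate,
                                     colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(keep_below, remove_above),
                        linetype = "dashed") +
    ggplot2::labs(x = "injection order", y = "missing rate") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' PCA of samples
#'
#' Principal components of log2 intensities; points coloured by batch and
#' shaped by class. Before batch integration QC samples separate by batch;
#' afterwards they should overlap.
#'
#' @param dataset A `metabo_dataset` (complete matrix).
#' @param colour `"batch"` (default) or `"group"`.
#' @return A ggplot object.
#' @export
plot_pca <- function(dataset, colour = c("batch", "group")) {
  colour <- match.arg(colour)
  x <- t(log2(dataset$expression + 1))
  x <- x[, apply(x, 2, stats::sd) > 0, drop = FALSE]
  pc <- stats::prcomp(x, scale. = TRUE)
  pv <- 100 * pc$sdev[1:2]^2 / sum(pc$sdev^2)
  d <- dplyr::bind_cols(
    dataset$sample_info,
    tibble::tibble(PC1 = pc$x[, 1], PC2 = pc$x[, 2])
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2,
                                  colour = .data[[colour]],
                                  shape = .data$class)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", pv[1]),
                  y = sprintf("PC2 (%.1f%%)", pv[2])) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential analysis
#'
#' @param rows Tibble from [dam_analysis()].
#' @param fc_min,fdr_max Selection thresholds drawn as guides.
#' @return A ggplot object.
#' @export
plot_volcano <- function(rows, fc_min = 2, fdr_max = 0.05) {
  d <- dplyr::mutate(
    tibble::as_tibble(rows),
    selected = abs(.data$log2_fc) >= log2(fc_min) & .data$fdr <= fdr_max
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$log2_fc, -log10(.data$p_value),
                                  colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-log2(fc_min), log2(fc_min)),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c("FALSE" = "grey60",
                                            "TRUE" = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Enrichment dot plot
#'
#' Terms against -log10 FDR; dot size is the k/n overlap ratio.
#'
#' @param enrichment Tibble from [enrich_terms()].
#' @param fdr_max Terms with FDR above this are dropped from the display
#'   (default 1 = show all).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, fdr_max = 1) {
  d <- dplyr::filter(tibble::as_tibble(enrichment), .data$fdr <= fdr_max) |>
    dplyr::mutate(term_label = stats::reorder(.data$term_label, -.data$fdr))
  ggplot2::ggplot(d, ggplot2::aes(-log10(.data$fdr), .data$term_label,
                                  size = .data$ratio)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "-log10 FDR", y = NULL, size = "k/n") +
    ggplot2::theme_minimal()
}

#' Module overview plot
#'
#' Eigenmetabolite profiles across samples, one panel per module, with the
#' module's member count and hub count in the strip label.
#'
#' @param object A `metabo_modules` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metabo_modules
#' @export
autoplot.metabo_modules <- function(object, ...) {
  me <- object$eigenmetabolites
  if (ncol(me) == 0) stop("no modules to plot", call. = FALSE)
  sizes <- table(object$assignments$module)
  hubs <- table(object$assignments$module[object$assignments$is_hub])
  d <- tibble::as_tibble(me) |>
    dplyr::mutate(sample = dplyr::row_number()) |>
    tidyr::pivot_longer(-"sample", names_to = "module",
                        values_to = "eigenmetabolite") |>
    dplyr::mutate(panel = sprintf(
      "%s (n=%d, hubs=%d)", .data$module,
      as.integer(sizes[.data$module]),
      ifelse(is.na(hubs[.data$module]), 0L, as.integer(hubs[.data$module]))
    ))
  ggplot2::ggplot(d, ggplot2::aes(.data$sample, .data$eigenmetabolite)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::theme_minimal()
}
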