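# ggplot2 views of the main result types.

#' Plot windowed landscapes along the genome
#'
#' Line tracks of chosen window statistics per chromosome, with island
#' regions shaded.
#'
#' @param windows Output of [window_stats()] / [call_outliers()].
#' @param stats Statistics to facet.
#' @param islands Optional regions from [merge_islands()].
#' @return A ggplot object.
#' @export
plot_landscape <- function(windows, stats = c("fst", "dxy", "pi_all", "rho"),
                           islands = NULL) {
  long <- windows %>%
    dplyr::filter(!excluded) %>%
    dplyr::mutate(mid = (start + end) / 2) %>%
    tidyr::pivot_longer(dplyr::all_of(stats), names_to = "stat")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$mid / 1e6, y = value)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_grid(stat ~ chrom, scales = "free") +
    ggplot2::labs(x = "position (Mb)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(islands) && nrow(islands)) {
    p <- p + ggplot2::geom_rect(
      data = islands,
      ggplot2::aes(xmin = start / 1e6, xmax = end / 1e6),
      ymin = -Inf, ymax = Inf, fill = "firebrick", alpha = 0.25,
      inherit.aes = FALSE)
  }
  p
}

#' Histogram of per-site F_ST
#'
#' The study-design signature is a U shape with a fixed-difference spike.
#'
#' @param sites Output of [site_stats()].
#' @param bins Number of bins.
#' @return A ggplot object.
#' @export
plot_site_fst <- function(sites, bins = 40) {
  ggplot2::ggplot(dplyr::filter(sites, !is.na(.data$fst_site)),
                  ggplot2::aes(x = .data$fst_site)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey30") +
    ggplot2::labs(x = expression(site ~ F[ST]), y = "SNPs") +
    ggplot2::theme_minimal()
}

#' Ranked V_ST plot
#'
#' Genes by decreasing V_ST with outlier and CNDG status highlighted.
#'
#' @param vst_results Output of [call_cndg()].
#' @return A ggplot object.
#' @export
plot_vst <- function(vst_results) {
  df <- vst_results %>%
    dplyr::filter(!is.na(vst)) %>%
    dplyr::arrange(dplyr::desc(vst)) %>%
    dplyr::mutate(rank = dplyr::row_number(),
                  status = dplyr::case_when(cndg ~ "CNDG",
                                            top5 ~ "top 5%",
                                            TRUE ~ "background"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = vst,
                                   colour = .data$status)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "gene rank", y = expression(V[ST])) +
    ggplot2::theme_minimal()
}

#' Ordination plot of RDA sample scores
#'
#' Sample scores on the first two constrained axes, optionally coloured by
#' species (pass a named vector `species[sample_id]`).
#'
#' @param object A [fit_rda()] object.
#' @param ... Unused.
#' @param species Optional named character vector of species per sample.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot divscan_rda
#' @export
autoplot.divscan_rda <- function(object, ..., species = NULL) {
  df <- tibble::tibble(sample_id = rownames(object$sample_scores),
                       RDA1 = object$sample_scores[, 1],
                       RDA2 = if (ncol(object$sample_scores) > 1)
                         object$sample_scores[, 2] else 0)
  if (!is.null(species))
    df$species <- species[match(df$sample_id, names(species))]
  aes <- if (is.null(species))
    ggplot2::aes(x = .data$RDA1, y = .data$RDA2)
  else
    ggplot2::aes(x = .data$RDA1, y = .data$RDA2, colour = .data$species)
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("RDA1 (%.1f%%)",
                              100 * object$prop_explained[1]),
                  y = if (length(object$prop_explained) > 1)
                    sprintf("RDA2 (%.1f%%)", 100 * object$prop_explained[2])
                  else "RDA2") +
    ggplot2::theme_minimal()
}
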