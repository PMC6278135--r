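# ggplot2 views of the main result types.

#' Plot fitted class likelihoods and thresholds for the gene panel
#'
#' Draws the fitted PFA and PFB beta densities per gene on the methylation
#' percentage scale, with dashed vertical lines at the likelihood-ratio
#' thresholds (where the two densities cross).
#'
#' @param fits A `beta_fits` tibble from [fit_gene_panel()].
#' @param rule Optional [threshold_rule()] providing the thresholds to mark.
#' @return A ggplot object (density vs percent methylation, faceted by gene).
#' @export
plot_gene_likelihoods <- function(fits, rule = NULL) {
  grid <- seq(0.1, 99.9, by = 0.1)
  dens <- purrr::pmap_dfr(
    list(fits$gene, fits$class, fits$fit),
    function(gene, class, fit) {
      tibble::tibble(gene = gene, class = class, percent = grid,
                     density = dbeta(grid / 100, fit$alpha, fit$beta) / 100)
    }
  )
  p <- ggplot2::ggplot(dens,
                       ggplot2::aes(x = .data$percent, y = .data$density,
                                    colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene), scales = "free_y") +
    ggplot2::labs(x = "methylation (%)", y = "density", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(rule)) {
    thr <- tidy(rule)
    p <- p + ggplot2::geom_vline(
      data = thr, ggplot2::aes(xintercept = .data$threshold),
      linetype = "longdash"
    )
  }
  p
}

#' @rdname plot_gene_likelihoods
#' @param object A `pfb_classifier`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.pfb_classifier <- function(object, ...) {
  plot_gene_likelihoods(object$fits, object$rule)
}

#' Plot a copy-number profile
#'
#' Per-probe centered log2 ratios in genome order, faceted by chromosome,
#' with optional horizontal guides at the arm-call thresholds.
#'
#' @param object A `cn_profile` from [log2_profile()].
#' @param thresholds Log2 guides to draw (default +/- 0.15).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.cn_profile <- function(object, thresholds = c(-0.15, 0.15), ...) {
  profile <- object
  chrom_order <- intersect(valid_chromosomes(), unique(profile$chrom))
  df <- dplyr::mutate(tibble::as_tibble(profile),
                      chrom = factor(.data$chrom, levels = chrom_order))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$log2_ratio)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = thresholds, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = NULL, y = "log2 ratio",
                  title = paste("sample", attr(profile, "sample_id"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing.x = ggplot2::unit(0.5, "pt"))
}

#' Heatmap of marker-probe methylation by cluster
#'
#' Tile heatmap of beta values over the clustering probe set with samples
#' ordered by cluster assignment -- the usual companion figure to two-group
#' methylation clustering.
#'
#' @param beta Wide beta-value tibble.
#' @param assignment A `cluster_assignment` (optionally with subgroup
#'   labels from [assign_subgroup_labels()]).
#' @param markers Marker set to display.
#' @return A ggplot object.
#' @export
plot_methylation_heatmap <- function(beta, assignment, markers) {
  ids <- marker_ids(markers)
  ord <- assignment$sample_id[order(assignment$cluster)]
  long <- beta |>
    dplyr::filter(.data$probe_id %in% ids) |>
    tidyr::pivot_longer(-"probe_id", names_to = "sample_id",
                        values_to = "beta") |>
    dplyr::mutate(sample_id = factor(.data$sample_id, levels = ord))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$probe_id,
                                     fill = .data$beta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#2166AC", high = "#B2182B",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "beta") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
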