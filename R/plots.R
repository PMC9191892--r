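#' Plot percent ribosomal association by functional category
#'
#' Jittered strip plot of the estimated ribosome-associated percentage per
#' protein, coloured by functional category and facetted by condition, on a
#' log10 axis.
#'
#' @param association Output of [ribosome_association()] (or
#'   [association_test()]).
#' @param annotations Annotation tibble with `protein_id`, `category`.
#' @return A ggplot object.
#' @export
plot_association <- function(association, annotations) {
  dat <- association |>
    filter(.data$flag == "ok") |>
    left_join(annotations |> select("protein_id", "category"),
              by = "protein_id") |>
    mutate(category = factor(.data$category %||% "nonRBP",
                             levels = CATEGORIES),
           condition = factor(.data$condition, levels = CONDITIONS))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$category,
                                    y = .data$pct_ribosomal,
                                    colour = .data$category)) +
    ggplot2::geom_jitter(width = 0.25, alpha = 0.6, size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$condition)) +
    ggplot2::labs(x = NULL, y = "% ribosomal (log scale)",
                  colour = "category") +
    ggplot2::theme_minimal()
}

#' Heat map of clustered enrichment profiles
#'
#' @param object A [cluster_profiles()] result.
#' @param ... Unused.
#' @return A ggplot object: proteins (rows, ordered by cluster) by
#'   condition/fraction columns, coloured by centred log2 enrichment.
#' @exportS3Method ggplot2::autoplot
autoplot.profile_clusters <- function(object, ...) {
  cols <- object$distance_columns
  long <- object$profiles |>
    left_join(object$labels, by = "protein_id") |>
    arrange(.data$cluster, .data$protein_id) |>
    mutate(row = dplyr::row_number()) |>
    tidyr::pivot_longer(dplyr::all_of(cols), names_to = "column",
                        values_to = "value") |>
    mutate(column = factor(.data$column, levels = cols))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$column, y = .data$row,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = 0) +
    ggplot2::labs(x = NULL, y = "protein (by cluster)",
                  fill = "log2 enrichment") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5),
                   axis.text.y = ggplot2::element_blank())
}

#' Plot cumulative positional intensity curves
#'
#' Step curves of cumulative peptide intensity from N- to C-terminus for
#' the total sample and each gradient fraction of one protein, the visual
#' companion of [peptide_bias_test()].
#'
#' @param curves Output of [cumulative_curves()].
#' @return A ggplot object.
#' @export
plot_cumulative_curves <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$residue, y = .data$cdf,
                                       colour = .data$fraction)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "residue (N- to C-terminus)",
                  y = "cumulative intensity fraction",
                  colour = "sample") +
    ggplot2::theme_minimal()
}
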