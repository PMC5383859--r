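# ggplot2 views of the main result types.

#' Plot ordination scores coloured by site
#'
#' @param object An `ordination_result`.
#' @param colour_by Metadata column to colour by (default `site_id`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ordination_result <- function(object, colour_by = "site_id", ...) {
  df <- tidy(object)
  lab <- paste0("PC", 1:2, " (",
                format(object$pct_variance[1:2], digits = 3), "%)")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if (colour_by %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour_by]],
                                              shape = .data[[colour_by]]))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::labs(x = lab[1], y = lab[2]) + ggplot2::theme_minimal()
}

#' Plot DAPC assignment probabilities as stacked bars
#'
#' @param object A `dapc_result`.
#' @param samples Optional metadata tibble used to order individuals by site.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dapc_result <- function(object, samples = NULL, ...) {
  df <- tidy(object)
  if (!is.null(samples)) {
    ord <- dplyr::arrange(tibble::as_tibble(samples), .data$site_id)
    df$individual_id <- factor(df$individual_id, levels = ord$individual_id)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$individual_id,
                                   y = .data$probability,
                                   fill = factor(.data$cluster))) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "assignment probability", fill = "cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot pairwise F_ST against the permutation null
#'
#' @param object A `pairwise_result` tibble.
#' @param ... Unused.
#' @return A ggplot: observed F_ST with the null 95% interval per site pair.
#' @export
autoplot.pairwise_result <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      pair = paste(.data$site_a, .data$site_b, sep = " - "))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$null_lo95,
                                         ymax = .data$null_hi95),
                            colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed_fst,
                                     colour = .data$verdict)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "genome-wide F_ST") +
    ggplot2::theme_minimal()
}

#' Plot observed vs expected shared outlier counts
#'
#' @param object A `parallel_divergence_result` tibble.
#' @param ... Unused.
#' @return A ggplot comparing observed counts with the permutation-null mean
#'   and 95% CI for loci shared by exactly two and exactly three contrasts.
#' @export
autoplot.parallel_divergence_result <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(
      cols = c("observed_exactly2", "observed_exactly3",
               "expected2_mean", "expected3_mean"),
      names_to = "measure", values_to = "count") |>
    dplyr::mutate(
      sharing = ifelse(grepl("2", .data$measure), "2 contrasts", "3 contrasts"),
      kind = ifelse(grepl("observed", .data$measure), "observed", "expected"))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$quantile),
                                   y = .data$count, fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~sharing, scales = "free_y") +
    ggplot2::labs(x = "F_ST quantile", y = "shared outlier loci") +
    ggplot2::theme_minimal()
}
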