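# ggplot2 displays for the pipeline's result objects.

#' Plot a site-divergence profile
#'
#' Per-column divergence score (`-log10 p`) with the detection threshold and
#' optional reference positions highlighted.
#'
#' @param object A `site_divergence` tibble from [type2_site_scores()].
#' @param threshold Score threshold line (default 3, i.e. p < 0.001).
#' @param highlight Optional columns to mark (e.g. planted or known sites).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot site_divergence
#' @export
autoplot.site_divergence <- function(object, threshold = 3, highlight = NULL,
                                     ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$score)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$column, yend = 0),
                          colour = "grey50", na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "alignment column", y = expression(-log[10](p)),
                  title = "Type-II divergence profile") +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    p <- p + ggplot2::geom_point(
      data = dplyr::filter(df, .data$column %in% highlight),
      colour = "steelblue", size = 2, na.rm = TRUE
    )
  }
  p
}

#' Plot a peptide-mass-fingerprint match report
#'
#' Observed centroid peaks as a stem plot, coloured by whether they matched
#' a theoretical peptide form.
#'
#' @param object A `match_report` from [match_peaks()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot match_report
#' @export
autoplot.match_report <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(dplyr::select(object$matches, "observed", "intensity"),
                  matched = TRUE),
    dplyr::mutate(object$unmatched_observed, matched = FALSE)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$intensity,
                                   colour = .data$matched)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$observed, yend = 0)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "steelblue",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "centroid mass (Da)", y = "relative intensity",
                  colour = "matched",
                  title = sprintf("PMF matches: coverage %.0f%%",
                                  100 * object$coverage)) +
    ggplot2::theme_minimal()
}
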