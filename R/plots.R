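#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spectrum
#'
#' @param object An `nmr_spectrum`.
#' @param ... Unused.
#' @return A ggplot; the ppm axis is reversed, as spectra are conventionally
#'   drawn.
#' @export
autoplot.nmr_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ppm, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot a fingerprint as level bars over chemical shift
#'
#' @param object An `nmr_fingerprint`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nmr_fingerprint <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$center_ppm,
                                       y = .data$level)) +
    ggplot2::geom_col(width = 0.01) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "bucket centre (ppm)", y = "level (0 / 1-100)") +
    ggplot2::theme_minimal()
}

#' Plot ordination scores coloured by species
#'
#' @param object An `nmr_ordination`.
#' @param components Two component indices to draw (default 1:2).
#' @param ... Unused.
#' @return A ggplot with variance-explained percentages in the axis labels.
#' @export
autoplot.nmr_ordination <- function(object, components = 1:2, ...) {
  pcs <- paste0("PC", components)
  v <- object$var_explained_pct[components]
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data[[pcs[1]]], y = .data[[pcs[2]]],
                               colour = .data$species)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("%s (%.2f%%)", pcs[1], v[1]),
                  y = sprintf("%s (%.2f%%)", pcs[2], v[2]),
                  colour = "species") +
    ggplot2::theme_minimal()
}

#' Plot a TDI screen as allowed daily grams per sample
#'
#' @param object A `tdi_report`.
#' @param ... Unused.
#' @return A ggplot; flagged samples are highlighted.
#' @export
autoplot.tdi_report <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$max_daily_g))
  df$sample_id <- factor(df$sample_id, levels = rev(df$sample_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$max_daily_g,
                                   y = .data$sample_id,
                                   fill = .data$flagged)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "grams of product per day at the coumarin TDI",
                  y = NULL, fill = "exceeds TDI at serving") +
    ggplot2::theme_minimal()
}
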