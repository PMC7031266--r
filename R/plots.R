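#' Plot a distance-decay profile
#'
#' @param object A `decay_profile` from [expected_by_distance()].
#' @param ... Unused.
#' @return A ggplot (log-log decay curve).
#' @method autoplot decay_profile
#' @export
autoplot.decay_profile <- function(object, ...) {
  df <- object[object$distance_bins > 0 & object$mean_count > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance_bp,
                                   y = .data$mean_count)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "genomic distance (bp)", y = "mean contact count",
                  title = "Contact distance decay")
}

#' Plot an aggregate peak analysis grid
#'
#' @param object An `apa_result`.
#' @param ... Unused.
#' @return A ggplot heat map of the corner-scaled aggregate.
#' @method autoplot apa_result
#' @export
autoplot.apa_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset2, y = .data$offset1,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "bins from loop (anchor 2)",
                  y = "bins from loop (anchor 1)", fill = "O/corner",
                  title = sprintf("APA center score %.2f (%d loops)",
                                  object$center_score, object$n_loops_used))
}

#' Plot the TAD-separation score with called boundaries
#'
#' @param object A `tad_set`.
#' @param chrom Optional chromosome to show (default: all, facetted).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tad_set
#' @export
autoplot.tad_set <- function(object, chrom = NULL, ...) {
  sc <- object$scores
  bd <- object$boundaries
  if (!is.null(chrom)) {
    sc <- sc[sc$chrom == chrom, ]; bd <- bd[bd$chrom == chrom, ]
  }
  bs <- object$genome$bin_size
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$bin * bs, y = .data$score)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(data = bd, ggplot2::aes(xintercept = .data$start),
                        colour = "red", linetype = 2) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "TAD separation score",
                  title = "Insulation and called boundaries")
}

#' Plot a metagene signal profile
#'
#' @param object A `signal_profile`.
#' @param ... Unused.
#' @return A ggplot of the mean curve.
#' @method autoplot signal_profile
#' @export
autoplot.signal_profile <- function(object, ...) {
  ggplot2::ggplot(object$mean_curve,
                  ggplot2::aes(x = .data$position, y = .data$mean_value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from region centre (bp)",
                  y = "mean signal",
                  title = sprintf("Signal profile (%d regions)",
                                  object$n_regions))
}

#' Plot a compartment PC1 track
#'
#' @param object A `compartment_track`.
#' @param ... Unused.
#' @return A ggplot bar track, A compartment up, B down.
#' @method autoplot compartment_track
#' @export
autoplot.compartment_track <- function(object, ...) {
  df <- object[object$label != "masked", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start, y = .data$pc1,
                                   fill = .data$label)) +
    ggplot2::geom_col(width = df$end - df$start) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "PC1",
                  title = "A/B compartments")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
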