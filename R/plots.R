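#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_col geom_errorbar
#'   facet_wrap facet_grid labs theme_minimal autoplot vars
NULL

#' Plot a window track along the genome
#'
#' Manhattan-style view: window midpoints on the x axis, the statistic on
#' the y axis, one facet per chromosome.
#'
#' @param track A window track tibble (`chrom`, `start`, `end`, `value`).
#' @param highlight Optional region tibble drawn as shaded intervals.
#' @return A ggplot object.
#' @export
plot_track <- function(track, highlight = NULL) {
  stat <- attr(track, "statistic") %||% "value"
  p <- ggplot(track, aes(x = (.data$start + .data$end) / 2e6,
                         y = .data$value)) +
    geom_point(size = 0.4, na.rm = TRUE) +
    facet_wrap(vars(.data$chrom), scales = "free_x") +
    labs(x = "position (Mb)", y = stat) +
    theme_minimal()
  if (!is.null(highlight) && nrow(highlight)) {
    p <- p + ggplot2::geom_rect(
      data = highlight,
      aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "red",
      inherit.aes = FALSE
    )
  }
  p
}

#' Plot LD decay curves
#'
#' @param bins LD-decay tibble from [ld_decay()]; an optional `population`
#'   column draws one curve per population.
#' @return A ggplot object.
#' @export
plot_ld_decay <- function(bins) {
  m <- dplyr::mutate(bins, dist_kb = (.data$distance_low +
                                        .data$distance_high) / 2000)
  p <- ggplot(m, aes(x = .data$dist_kb, y = .data$mean_r2))
  p <- if ("population" %in% names(m)) {
    p + geom_line(aes(colour = .data$population), na.rm = TRUE)
  } else {
    p + geom_line(na.rm = TRUE)
  }
  p + labs(x = "distance (kb)", y = expression(mean ~ r^2)) +
    theme_minimal()
}

#' Plot effective population size trajectories
#'
#' @param ne Tibble from [ne_from_ld()]; an optional `population` column
#'   draws one trajectory per population.
#' @return A ggplot object.
#' @export
plot_ne <- function(ne) {
  m <- ne[!is.na(ne$ne), ]
  p <- ggplot(m, aes(x = .data$t, y = .data$ne))
  p <- if ("population" %in% names(m)) {
    p + geom_line(aes(colour = .data$population))
  } else {
    p + geom_line()
  }
  p + ggplot2::scale_x_log10() +
    labs(x = "generations ago", y = "Ne") + theme_minimal()
}

#' Plot the per-population diversity summary
#'
#' @param summary Tibble from [summarize_diversity()].
#' @return A ggplot object (mean with +/- sd bars, one facet per metric).
#' @export
plot_diversity <- function(summary) {
  ggplot(summary, aes(x = .data$population, y = .data$mean)) +
    geom_col(fill = "grey70") +
    geom_errorbar(aes(ymin = .data$mean - .data$sd,
                      ymax = .data$mean + .data$sd), width = 0.2) +
    facet_wrap(vars(.data$metric), scales = "free_y") +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.geno_pca <- function(object, group = NULL, ...) {
  sc <- object$scores
  if (!is.null(group)) sc$group <- group[sc$sample_id]
  p <- ggplot(sc, aes(x = .data$PC1, y = .data$PC2))
  p <- if (!is.null(group)) {
    p + geom_point(aes(colour = .data$group))
  } else {
    p + geom_point()
  }
  p + labs(
    x = sprintf("PC1 (%.2f%%)", object$explained[1]),
    y = sprintf("PC2 (%.2f%%)", object$explained[2])
  ) + theme_minimal()
}
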