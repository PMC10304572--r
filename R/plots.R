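#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#'   facet_grid theme_bw vars
#' @export
ggplot2::autoplot

# palette used for the stacked-dimer classes across all figures
CLASS_COLORS <- c(total = "grey40", H = "#d7261d", J = "#e8a513",
                  crossed_J = "#2b5fbf")

#' Two-panel aggregation time-series figure
#'
#' Mirrors the standard presentation of aggregation runs: the upper panel
#' shows block means of the total interacting-dimer count (grey) and of the
#' pi-stacked counts by class (H red, J yellow, crossed-J blue); the lower
#' panel shows the block-mean sum of dye-dye center distances.
#'
#' @param stats Per-frame statistics from [aggregate_stats()].
#' @param window Block-average window in ns (default 0.1).
#' @return A ggplot object.
#' @export
plot_aggregation <- function(stats, window = 0.1) {
  stopifnot(all(c("time", "n_interacting", "n_H", "n_J", "n_crossedJ",
                  "sum_rcc") %in% names(stats)))
  bl <- block_average(
    stats[, c("time", "n_interacting", "n_H", "n_J", "n_crossedJ", "sum_rcc")],
    window = window)
  counts <- tidyr::pivot_longer(
    bl[, c("time", "n_interacting", "n_H", "n_J", "n_crossedJ")],
    -"time", names_to = "series", values_to = "value")
  counts$series <- factor(
    c(n_interacting = "total", n_H = "H", n_J = "J", n_crossedJ = "crossed_J"
    )[counts$series],
    levels = names(CLASS_COLORS))
  counts$panel <- "dimer counts"
  rcc <- tibble::tibble(time = bl$time, series = factor("total", names(CLASS_COLORS)),
                        value = bl$sum_rcc, panel = "sum of rCC (Å)")
  df <- dplyr::bind_rows(counts, rcc)
  ggplot(df, aes(x = .data$time, y = .data$value, colour = .data$series)) +
    geom_line() +
    facet_grid(rows = vars(.data$panel), scales = "free_y") +
    ggplot2::scale_colour_manual(values = CLASS_COLORS, name = NULL) +
    labs(x = "time (ns)", y = NULL,
         title = sprintf("Aggregation time series (%.2g ns block means)", window)) +
    theme_bw()
}

#' Plot a radial distribution function
#'
#' @param rdf An `rdf_result` from [compute_rdf()].
#' @return A ggplot object.
#' @export
plot_rdf <- function(rdf) {
  ggplot(tibble::as_tibble(rdf), aes(x = .data$r, y = .data$g)) +
    geom_line() +
    labs(x = "r (Å)", y = "g(r)",
         title = sprintf("%s radial distribution (%d frames)",
                         sub("_", "-", attr(rdf, "pair_kind")),
                         attr(rdf, "n_frames_averaged"))) +
    theme_bw()
}

#' Plot a dimer approach potential energy scan
#'
#' @param object A `pes_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pes_scan
#' @export
autoplot.pes_scan <- function(object, ...) {
  g <- glance(object)
  ggplot(tidy(object), aes(x = .data$distance, y = .data$delta_e)) +
    geom_line() + geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    labs(x = "xanthene center separation (Å)",
         y = expression(Delta * E ~ "(kcal/mol)"),
         title = sprintf("well %.2f kcal/mol at %.2f Å (eps scale %.2f)",
                         g$well_depth, g$r_min_location, g$scale_factor)) +
    theme_bw()
}

#' Plot a torsion fit against its reference profile
#'
#' @param object A `torsion_fit`.
#' @param ... Unused.
#' @return A ggplot object showing the reference and fitted profiles with the
#'   minima regions shaded.
#' @method autoplot torsion_fit
#' @export
autoplot.torsion_fit <- function(object, ...) {
  prof <- tidyr::pivot_longer(object$profile[, c("angle", "reference", "fitted")],
                              -"angle", names_to = "curve", values_to = "energy")
  reg <- object$minima_regions
  # split wrapped regions at the grid boundary for drawing
  amin <- min(object$profile$angle); amax <- max(object$profile$angle)
  shades <- do.call(rbind, lapply(seq_len(nrow(reg)), function(i) {
    if (reg$end[i] >= reg$start[i]) {
      data.frame(xmin = reg$start[i], xmax = reg$end[i])
    } else {
      data.frame(xmin = c(reg$start[i], amin), xmax = c(amax, reg$end[i]))
    }
  }))
  ggplot(prof, aes(x = .data$angle, y = .data$energy)) +
    ggplot2::geom_rect(data = shades,
                       aes(xmin = .data$xmin, xmax = .data$xmax),
                       ymin = -Inf, ymax = Inf, alpha = 0.12,
                       inherit.aes = FALSE) +
    geom_line(aes(colour = .data$curve)) +
    labs(x = "dihedral angle (deg)", y = "energy (kcal/mol)",
         title = sprintf("max deviation in minima regions: %.3f kcal/mol%s",
                         object$max_dev_minima,
                         if (object$converged) " (converged)" else "")) +
    theme_bw()
}
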