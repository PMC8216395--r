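#' Plot a tissue mesh
#'
#' ggplot2 rendering of the cell polygons, filled by cell type, polarity
#' magnitude, age, or a supplied per-cell value; polarity vectors can be
#' overlaid as arrows (the standard way to inspect apico-basal
#' polarisation before lumen formation).
#'
#' @param mesh a [tissue_mesh()].
#' @param fill `"type"` (default), `"polarity"`, `"age"`, or a numeric
#'   vector with one value per cell.
#' @param arrows overlay polarity vectors (default FALSE).
#' @return A ggplot object.
#' @export
plot_tissue <- function(mesh, fill = "type", arrows = FALSE) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_tissue requires ggplot2")
  lens <- lengths(mesh$cells)
  ids <- rep.int(seq_along(mesh$cells), lens)
  v <- unlist(mesh$cells, use.names = FALSE)
  fillv <- if (is.numeric(fill)) {
    rep.int(fill, lens)
  } else if (identical(fill, "polarity")) {
    rep.int(sqrt(mesh$polarity[, 1]^2 + mesh$polarity[, 2]^2), lens)
  } else if (identical(fill, "age")) {
    rep.int(mesh$age, lens)
  } else {
    rep.int(mesh$type, lens)
  }
  df <- tibble::tibble(x = mesh$pos[v, 1], y = mesh$pos[v, 2],
                       cell = ids, fill = fillv)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, group = cell,
                                         fill = fill)) +
    ggplot2::geom_polygon(colour = "grey20", linewidth = 0.15) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = if (is.character(fill)) fill else "value") +
    ggplot2::theme_void()
  if (arrows) {
    cen <- cell_centroids(mesh)
    ad <- tibble::tibble(x = cen[, 1], y = cen[, 2],
                         xend = cen[, 1] + mesh$polarity[, 1],
                         yend = cen[, 2] + mesh$polarity[, 2])
    ad <- ad[is_epithelial(mesh$type), ]
    gg <- gg + ggplot2::geom_segment(
      data = ad,
      ggplot2::aes(x = x, y = y, xend = xend, yend = yend),
      inherit.aes = FALSE,
      arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm")),
      linewidth = 0.3, colour = "white")
  }
  gg
}

#' @rdname plot_tissue
#' @param object,... autoplot arguments (`object` is a `tissue_mesh` or a
#'   `tissue_run`, whose final mesh is drawn).
#' @exportS3Method ggplot2::autoplot
autoplot.tissue_mesh <- function(object, ...) plot_tissue(object, ...)

#' @rdname plot_tissue
#' @exportS3Method ggplot2::autoplot
autoplot.tissue_run <- function(object, ...) plot_tissue(object$mesh, ...)

#' Plot the statistics trajectory of a run
#'
#' Line panels of the main tracked quantities against simulated time:
#' cell counts, endothelial area fraction, lumen count, islet count and
#' the proliferating-fraction proxy.
#'
#' @param run a `tissue_run`.
#' @return A ggplot object.
#' @export
plot_run_stats <- function(run) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_run_stats requires ggplot2")
  s <- run$stats
  long <- tibble::tibble(
    time = rep(s$time, 5),
    metric = rep(c("cells", "endothelial fraction", "lumina", "islets",
                   "proliferating fraction"), each = nrow(s)),
    value = c(s$n_cells, s$endothelial_fraction, s$lumen_count,
              s$islet_count, s$prolif_fraction))
  ggplot2::ggplot(long, ggplot2::aes(x = time, y = value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = NULL) +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("x", "y", "cell", "fill", "xend", "yend",
                         "time", "value", "metric"))
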