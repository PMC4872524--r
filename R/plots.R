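# ggplot2 autoplot methods for the main result types.

#' Plot a solved flow field
#'
#' Raster of depth-averaged speed (log10 scale) over the fluid mask.
#'
#' @param object a [solve_field()] result.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot flow_field
#' @export
autoplot.flow_field <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = log10(pmax(.data$speed, 1e-6)))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 speed\n(um/s)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)",
                  title = sprintf("Depth-averaged flow field%s",
                                  if (object$valve_on) " (valve on)" else "")) +
    ggplot2::theme_minimal()
}

#' Plot traced particle trajectories
#'
#' Requires `store_paths = TRUE` in [trace_particles()].
#'
#' @param object a `particle_trace`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot particle_trace
#' @export
autoplot.particle_trace <- function(object, ...) {
  if (is.null(object$paths)) {
    rlang::abort("trace was run without store_paths = TRUE")
  }
  df <- dplyr::left_join(object$paths,
                         object$fates[, c("particle", "fate")], by = "particle")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, group = .data$particle,
                                   colour = .data$fate)) +
    ggplot2::geom_path(alpha = 0.6, linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", colour = "fate") +
    ggplot2::theme_minimal()
}

#' Plot trap-array occupancy
#'
#' @param object a [trap_array()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot trap_array
#' @export
autoplot.trap_array <- function(object, ...) {
  df <- dplyr::mutate(object$units,
                      state = dplyr::case_when(
                        .data$valve_on ~ "valve on",
                        !is.na(.data$occupied) ~ "occupied",
                        TRUE ~ "empty"))
  ggplot2::ggplot(df, ggplot2::aes(.data$unit, 1, fill = .data$state)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(`empty` = "white",
                                          `occupied` = "#2c7fb8",
                                          `valve on` = "#d95f0e")) +
    ggplot2::scale_y_continuous(NULL, breaks = NULL) +
    ggplot2::labs(x = "trap unit (upstream to downstream)") +
    ggplot2::theme_minimal()
}

#' Plot a localization table with identified clusters
#'
#' @param object a `cluster_report`.
#' @param table optionally, the localization table the report came from.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot cluster_report
#' @export
autoplot.cluster_report <- function(object, table = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(table)) {
    p <- p + ggplot2::geom_point(
      data = table, ggplot2::aes(.data$x_nm, .data$y_nm),
      size = 0.1, alpha = 0.2, colour = "grey40")
  }
  p + ggplot2::geom_point(
    data = object$clusters,
    ggplot2::aes(.data$x_nm, .data$y_nm, size = .data$diameter_nm),
    shape = 1, colour = "red") +
    ggplot2::scale_size_continuous(name = "diameter (nm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}

#' Plot a rendered localization map
#'
#' @param object a [render_map()] result.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot palm_map
#' @export
autoplot.palm_map <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$x_nm, .data$y_nm, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)", fill = "density") +
    ggplot2::theme_minimal()
}
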