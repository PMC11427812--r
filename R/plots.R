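#' Plot a spherical pore profile
#'
#' @param object `sphere_profile`.
#' @param ... Unused.
#' @return A ggplot of probe radius against the channel axis z.
#' @method autoplot sphere_profile
#' @export
autoplot.sphere_profile <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), .data$flag %in% c("ok", "boundary"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$radius)) +
    ggplot2::geom_line(colour = "#4477AA") +
    ggplot2::labs(x = "z (Å)", y = "probe radius (Å)") +
    ggplot2::theme_minimal()
}

#' Plot an ellipsoidal pore profile
#'
#' Larger (a) and smaller (b) ellipse radii along the channel axis; the
#' gap between the curves is the pore asymmetry a spherical probe misses.
#'
#' @param object `ellipse_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ellipse_profile
#' @export
autoplot.ellipse_profile <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), .data$flag %in% c("ok", "boundary"))
  long <- tidyr::pivot_longer(df, c("a", "b"), names_to = "axis",
                              values_to = "radius")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$z, y = .data$radius,
                                     colour = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(a = "#4477AA", b = "#EE7733"),
      labels = c(a = "larger radius a", b = "smaller radius b")
    ) +
    ggplot2::labs(x = "z (Å)", y = "ellipse radius (Å)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the per-slice resistance decomposition
#'
#' @param object `conductance_estimate`.
#' @param ... Unused.
#' @return A ggplot of slice resistance against z; constrictions appear as
#'   resistance maxima.
#' @method autoplot conductance_estimate
#' @export
autoplot.conductance_estimate <- function(object, ...) {
  ggplot2::ggplot(object$slices,
                  ggplot2::aes(x = .data$z, y = .data$R_slice)) +
    ggplot2::geom_line(colour = "#4477AA") +
    ggplot2::labs(x = "z (Å)", y = "slice resistance (Ω)",
                  subtitle = object$variant) +
    ggplot2::theme_minimal()
}

#' Plot a fitted conductivity surface
#'
#' Ratio of model conductivity to bulk over a grid of radii, with the
#' training records overlaid.
#'
#' @param object `conductivity_fit`.
#' @param max_radius Upper radius bound of the grid (A).
#' @param ... Unused.
#' @return A ggplot raster of `kappa / kappa_bulk`.
#' @method autoplot conductivity_fit
#' @export
autoplot.conductivity_fit <- function(object, max_radius = 15, ...) {
  grid <- tidyr::expand_grid(
    a = seq(0.5, max_radius, length.out = 80),
    b = seq(0.5, max_radius, length.out = 80)
  )
  grid <- dplyr::filter(grid, .data$a >= .data$b)
  grid$ratio <- conductivity_model(grid$a, grid$b, object$params,
                                   object$bulk) / object$bulk$kappa_bulk
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$a, y = .data$b,
                                     fill = .data$ratio)) +
    ggplot2::geom_raster() +
    ggplot2::geom_point(
      data = object$fitted,
      ggplot2::aes(x = .data$a_angstrom, y = .data$b_angstrom),
      inherit.aes = FALSE, colour = "black", size = 1
    ) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "a (Å)", y = "b (Å)",
                  fill = "κ/κ_bulk") +
    ggplot2::theme_minimal()
}
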