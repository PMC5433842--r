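#' Plot a rendered super-resolution image
#'
#' Intensity raster with z pseudo-color (rainbow over the configured z
#' range) where axial information is present.
#'
#' @param object A `storm_image` from [render_storm()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot storm_image
#' @export
autoplot.storm_image <- function(object, ...) {
  ny <- nrow(object$intensity); nx <- ncol(object$intensity)
  df <- tidyr::expand_grid(row = seq_len(ny), col = seq_len(nx))
  df$x_nm <- object$xlim[1L] + (df$col - 0.5) * object$pixel_nm
  df$y_nm <- object$ylim[1L] + (df$row - 0.5) * object$pixel_nm
  df$intensity <- as.vector(object$intensity[cbind(df$row, df$col)])
  df$z_nm <- as.vector(object$zmean[cbind(df$row, df$col)])
  df <- df[df$intensity > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$x_nm, .data$y_nm)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$z_nm,
                                      alpha = .data$intensity)) +
    ggplot2::scale_fill_gradientn(
      colours = rev(grDevices::rainbow(7L, end = 0.75)),
      limits = c(-object$z_range_nm, object$z_range_nm),
      oob = scales_squish, na.value = "grey70", name = "z (nm)") +
    ggplot2::scale_alpha_continuous(range = c(0, 1), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)")
}

# minimal squish (avoids importing scales just for one helper)
scales_squish <- function(x, range = c(0, 1), only.finite = TRUE) {
  pmin(pmax(x, range[1L]), range[2L])
}

#' Plot a cross-section profile and its Gaussian fit
#'
#' @param object A `profile_fit` from [cross_section_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot profile_fit
#' @export
autoplot.profile_fit <- function(object, ...) {
  h <- object$histogram
  p <- ggplot2::ggplot(h, ggplot2::aes(.data$position_nm, .data$count)) +
    ggplot2::geom_col(width = diff(h$position_nm[1:2] %||% c(0, 10)),
                      fill = "grey70") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "transverse position (nm)", y = "counts")
  if (!is.null(object$components)) {
    grid <- seq(min(h$position_nm), max(h$position_nm), length.out = 400L)
    curve <- rowSums(vapply(seq_len(nrow(object$components)), function(i) {
      ci <- object$components[i, ]
      ci$amplitude * exp(-(grid - ci$mean_nm)^2 / (2 * ci$sigma_nm^2))
    }, numeric(length(grid))))
    p <- p + ggplot2::geom_line(
      data = tibble(position_nm = grid, count = curve),
      colour = "darkgreen", linewidth = 0.8)
  }
  p
}

#' Plot a drift trace
#'
#' @param object A `drift_trace` from [track_fiducials()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot drift_trace
#' @export
autoplot.drift_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("dx_nm", "dy_nm"),
                            names_to = "axis", values_to = "drift_nm")
  ggplot2::ggplot(df, ggplot2::aes(.data$frame, .data$drift_nm,
                                   colour = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "frame", y = "drift (nm)")
}

#' Plot probe tiling along the target
#'
#' Probe sites as segments at their melting temperature, colored by strand.
#'
#' @param probes Probe tibble from [tile_target()].
#' @return A ggplot.
#' @export
plot_probe_tiling <- function(probes) {
  ggplot2::ggplot(probes) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$target_start,
                                       xend = .data$target_end,
                                       y = .data$tm_hybrid,
                                       yend = .data$tm_hybrid,
                                       colour = .data$strand),
                          linewidth = 2) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "target position (nt)",
                  y = "hybridizing-region Tm (°C)")
}
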