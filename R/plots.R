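# ggplot2 visualizations for the result types.

#' Plot a localization table
#'
#' Scatter of localizations, optionally colored by channel.
#'
#' @param locs Localization tibble.
#' @param point_size Point size (default 0.4).
#' @return A ggplot.
#' @export
plot_localizations <- function(locs, point_size = 0.4) {
  validate_locs(locs)
  p <- ggplot2::ggplot(locs, ggplot2::aes(x = .data$x_nm, y = .data$y_nm))
  if ("channel" %in% names(locs)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$channel),
                                 size = point_size, alpha = 0.6)
  } else {
    p <- p + ggplot2::geom_point(size = point_size, alpha = 0.6)
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rendered_image <- function(object, ...) {
  df <- tidyr::expand_grid(
    i = seq_len(nrow(object$counts)),
    j = seq_len(ncol(object$counts))
  )
  df$x <- object$origin[["x"]] + (df$i - 0.5) * object$pixel_size
  df$y <- object$origin[["y"]] + (df$j - 0.5) * object$pixel_size
  df$intensity <- object$counts[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)", fill = "counts") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.xcorr_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$delta, y = .data$C)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$displacement,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = expression(Delta ~ "(nm)"),
                  y = expression(C(Delta)),
                  title = sprintf("Apparent displacement %.0f nm",
                                  object$displacement)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.radial_fit <- function(object, r_prime = NULL, ...) {
  bin <- object$bins
  if (object$model == "disk") {
    xs <- seq(0, object$r_max, length.out = 200)
    model_df <- tibble::tibble(r = xs,
                               density = disk_projection_density(xs, object$r_max))
  } else {
    sim <- simulate_radial_clusters(2e4, "gaussian", mu_r = object$mu_r,
                                    sigma_r = object$sigma_r, seed = 1)
    d <- stats::density(sim$r_proj, from = 0)
    model_df <- tibble::tibble(r = d$x, density = d$y)
  }
  p <- ggplot2::ggplot()
  if (!is.null(r_prime)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble::tibble(r = r_prime),
      ggplot2::aes(x = .data$r, y = ggplot2::after_stat(density)),
      binwidth = bin, boundary = 0, fill = "grey80", colour = "grey40"
    )
  }
  p + ggplot2::geom_line(data = model_df,
                         ggplot2::aes(x = .data$r, y = .data$density),
                         colour = "red", linewidth = 0.8) +
    ggplot2::labs(x = "projected displacement r' (nm)", y = "density") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.frap_fit <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$R), size = 0.8, alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = "time after bleach (s)", y = "normalized recovery",
                  title = sprintf("Recovery half-time %.1f s", object$halftime)) +
    ggplot2::theme_minimal()
}
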