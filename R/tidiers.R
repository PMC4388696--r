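# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a paired-diameter line fit
#' @param x A `diameter_fit`.
#' @param ... Unused.
#' @return One row per coefficient-like quantity: `term`, `estimate`.
#' @export
tidy.diameter_fit <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept", "x_intercept", "radial_separation"),
    estimate = c(x$slope, x$intercept, x$x_intercept, x$radial_separation)
  )
}

#' @rdname tidy.diameter_fit
#' @export
glance.diameter_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n = x$n)
}

#' Tidy a channel registration fit
#' @param x A `registration_fit`.
#' @param ... Unused.
#' @export
tidy.registration_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a11", "a12", "a21", "a22", "tx", "ty"),
    estimate = c(x$linear[1, 1], x$linear[1, 2], x$linear[2, 1], x$linear[2, 2],
                 x$translation[1], x$translation[2])
  )
}

#' @rdname tidy.registration_fit
#' @export
glance.registration_fit <- function(x, ...) {
  tibble::tibble(rms_residual = x$rms_residual,
                 n_control_points = x$n_control_points)
}

#' Tidy a radial placement model fit
#' @param x A `radial_fit`.
#' @param ... Unused.
#' @export
tidy.radial_fit <- function(x, ...) {
  if (x$model == "gaussian") {
    tibble::tibble(term = c("mu_r", "sigma_r"),
                   estimate = c(x$mu_r, x$sigma_r))
  } else {
    tibble::tibble(term = c("r_max", "mean_r", "sd_r"),
                   estimate = c(x$r_max, x$mean_r, x$sd_r))
  }
}

#' @rdname tidy.radial_fit
#' @export
glance.radial_fit <- function(x, ...) {
  tibble::tibble(model = x$model, sse = x$sse, n_obs = x$n_obs, bins = x$bins)
}

#' Tidy a FRAP recovery fit
#' @param x A `frap_fit`.
#' @param ... Unused.
#' @export
tidy.frap_fit <- function(x, ...) {
  tibble::tibble(term = c("k", "halftime", "amplitude"),
                 estimate = c(x$k, x$halftime, x$amplitude))
}

#' @rdname tidy.frap_fit
#' @export
glance.frap_fit <- function(x, ...) {
  tibble::tibble(halftime = x$halftime, amplitude = x$amplitude,
                 n_traces = x$n_traces,
                 se_halftime = x$se_halftime %||% NA_real_)
}

#' Tidy a cross-correlation displacement result
#'
#' Returns the sampled correlation curve; use `glance()` for the apparent
#' displacement.
#' @param x An `xcorr_result`.
#' @param ... Unused.
#' @export
tidy.xcorr_result <- function(x, ...) {
  x$curve
}

#' @rdname tidy.xcorr_result
#' @export
glance.xcorr_result <- function(x, ...) {
  tibble::tibble(displacement = x$displacement, h = x$h, step = x$step,
                 flat = x$flat)
}
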