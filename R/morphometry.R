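# Band/ring morphometry in the cell frame: band width (Gaussian FWHM of the
# long-axis density), ring diameter (distance between the two most distal
# peaks of the short-axis projection), the ZapB-vs-FtsZ diameter relation,
# and group comparisons.

#' Measure band width (Gaussian FWHM along the long axis)
#'
#' Fits a Gaussian to the binned long-axis coordinate density and reports its
#' full width at half maximum, `2 sqrt(2 log 2) * sigma`. When the table
#' carries per-localization precision values, the mean localization precision
#' is subtracted in quadrature from the fitted sd before converting to FWHM,
#' so the reported width estimates the size of the underlying structure
#' rather than its noise-broadened image.
#'
#' @param locs Localization tibble in the cell frame.
#' @param roi Optional long-axis window `c(min, max)` nm; localizations
#'   outside it are ignored.
#' @param bin Histogram bin width, nm (default 15).
#' @param deconvolve Subtract mean localization precision in quadrature
#'   (default `TRUE`; only applies when a `precision_nm` column is present).
#' @return Band width (FWHM), nm. Degenerate input (all localizations at one
#'   coordinate) returns 0 with a warning.
#' @export
measure_band_width <- function(locs, roi = NULL, bin = 15, deconvolve = TRUE) {
  validate_locs(locs)
  x <- locs$x_nm
  if (!is.null(roi)) {
    keep <- x >= roi[1] & x <= roi[2]
    x <- x[keep]
  } else {
    keep <- rep(TRUE, length(x))
  }
  if (length(x) < 50) {
    stop("insufficient data: need >= 50 localizations in the ROI, have ",
         length(x), call. = FALSE)
  }
  if (diff(range(x)) < .Machine$double.eps^0.5) {
    warning("degenerate band: all localizations at one long-axis coordinate")
    return(0)
  }
  sigma <- .fit_gaussian_1d(x, bin)$sigma
  # binning contributes ~bin^2/12 to the fitted variance; remove it so the
  # width does not depend on the histogram resolution
  sigma <- sqrt(max(sigma^2 - bin^2 / 12, 0))
  if (deconvolve && "precision_nm" %in% names(locs)) {
    p <- mean(locs$precision_nm[keep], na.rm = TRUE)
    if (is.finite(p) && p < sigma) {
      sigma <- sqrt(sigma^2 - p^2)
    } else if (is.finite(p)) {
      warning("mean localization precision exceeds fitted sd; width set to 0")
      return(0)
    }
  }
  sd_to_fwhm(sigma)
}

# Least-squares Gaussian fit to a binned sample; returns mu, sigma, amplitude.
# Moment start values make convergence routine; failure raises a fit error.
.fit_gaussian_1d <- function(x, bin) {
  breaks <- seq(floor(min(x) / bin) * bin, max(x) + bin, by = bin)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  df <- data.frame(z = h$mids, d = h$density)
  start <- list(a = max(df$d), mu = mean(x), sigma = max(stats::sd(x), bin / 2))
  fit <- tryCatch(
    minpack.lm::nlsLM(d ~ a * exp(-(z - mu)^2 / (2 * sigma^2)),
                      data = df, start = start,
                      lower = c(a = 0, mu = -Inf, sigma = bin / 10),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Gaussian fit failed to converge: ",
                             conditionMessage(e), call. = FALSE)
  )
  cf <- stats::coef(fit)
  list(mu = unname(cf["mu"]), sigma = abs(unname(cf["sigma"])),
       amplitude = unname(cf["a"]))
}

#' Measure ring diameter from the short-axis projection
#'
#' Projects localizations onto the short axis, bins them (default 15 nm),
#' smooths the profile with a Gaussian kernel, identifies local maxima whose
#' topographic prominence is at least `prominence_frac` of the profile
#' maximum, and returns the distance between the two most distal qualifying
#' peaks.
#'
#' @param locs Localization tibble in the cell frame (>= 100 records).
#' @param bin Histogram bin width, nm (default 15).
#' @param smooth_sd Gaussian smoothing sd in bins (default 1).
#' @param prominence_frac Minimum peak prominence as a fraction of the
#'   profile maximum (default 0.1).
#' @param deconvolve Correct the peak positions for the inward shift caused
#'   by localization noise, binning and smoothing (default `TRUE`). For a
#'   ring of radius R, noise of scale sigma moves the peaks of the projected
#'   profile inward (the edge singularity of the projected annulus is
#'   one-sided); the correction inverts the peak position of the
#'   noise-convolved projected-annulus density at the known noise scale,
#'   `sigma_eff^2 = precision^2 + bin^2/12 + (smooth_sd * bin)^2`.
#' @return Diameter, nm (distance between outermost peak centers).
#'   Fewer than two qualifying peaks raises a condition of class
#'   `divlayers_no_diameter` so callers can record the cell as unmeasurable.
#' @export
measure_band_diameter <- function(locs, bin = 15, smooth_sd = 1,
                                  prominence_frac = 0.1, deconvolve = TRUE) {
  validate_locs(locs)
  y <- locs$y_nm
  if (length(y) < 100) {
    stop("insufficient data: need >= 100 localizations, have ", length(y),
         call. = FALSE)
  }
  breaks <- seq(floor(min(y) / bin) * bin, max(y) + bin, by = bin)
  h <- graphics::hist(y, breaks = breaks, plot = FALSE)
  profile <- h$counts
  if (smooth_sd > 0) {
    profile <- as.vector(.gauss_blur(matrix(profile, ncol = 1), smooth_sd))
  }
  peaks <- find_profile_peaks(profile)
  ok <- peaks$prominence >= prominence_frac * max(profile)
  if (sum(ok) < 2) {
    stop(structure(
      class = c("divlayers_no_diameter", "error", "condition"),
      list(message = "fewer than two qualifying peaks; no diameter measurable",
           call = NULL)
    ))
  }
  idx <- peaks$index[ok]
  raw <- h$mids[max(idx)] - h$mids[min(idx)]
  if (!deconvolve) {
    return(raw)
  }
  prec <- if ("precision_nm" %in% names(locs)) {
    mean(locs$precision_nm, na.rm = TRUE)
  } else {
    0
  }
  if (!is.finite(prec)) prec <- 0
  sigma_eff <- sqrt(prec^2 + bin^2 / 12 + (smooth_sd * bin)^2)
  2 * .annulus_radius_from_peak(raw / 2, sigma_eff)
}

# Peak position of the projected-annulus density (radius R) convolved with
# Gaussian noise of sd sigma:  g(y) = (1/pi) int_0^pi phi_sigma(y - R cos t) dt.
.annulus_peak_position <- function(R, sigma) {
  t <- seq(0, pi, length.out = 257)
  g <- function(y) {
    vapply(y, function(yy) mean(stats::dnorm(yy - R * cos(t), sd = sigma)),
           numeric(1))
  }
  stats::optimize(g, interval = c(0, R + sigma), maximum = TRUE)$maximum
}

# Invert .annulus_peak_position: the ring radius whose noise-convolved
# profile peaks at the observed position. Noise always shifts the peak
# inward, so R >= peak.
.annulus_radius_from_peak <- function(peak, sigma) {
  if (peak <= 0 || sigma <= 0) return(max(peak, 0))
  f <- function(R) .annulus_peak_position(R, sigma) - peak
  upper <- peak + 6 * sigma
  if (f(upper) < 0) return(peak)  # noise too large to invert; report as-is
  stats::uniroot(f, lower = peak, upper = upper, tol = 1e-3)$root
}

#' Local maxima of a 1-D profile with topographic prominence
#'
#' A peak is a strict local maximum (plateaus take their first index). Its
#' prominence is the peak height minus the higher of the two bases, where
#' each base is the minimum of the profile between the peak and the nearest
#' higher point (or the series end) on that side.
#'
#' @param profile Numeric vector.
#' @return Tibble with columns `index`, `height`, `prominence`.
#' @export
find_profile_peaks <- function(profile) {
  n <- length(profile)
  if (n < 1) {
    return(tibble::tibble(index = integer(), height = numeric(),
                          prominence = numeric()))
  }
  # density is zero outside the profile, so boundary maxima count as peaks
  padded <- c(0, profile, 0)
  idx <- which(diff(sign(diff(padded))) < 0)
  idx <- idx[idx >= 1 & idx <= n]
  # keep plateau starts: positions equal to previous are not separate peaks
  idx <- idx[profile[idx] > 0]
  prom <- vapply(idx, function(i) {
    h <- profile[i]
    left <- if (i > 1) profile[seq_len(i - 1)] else numeric(0)
    higher_l <- which(left > h)
    lbase <- if (length(higher_l) > 0) {
      min(profile[(max(higher_l)):(i - 1)])
    } else {
      min(left, 0)  # series edge: density is zero beyond it
    }
    right <- if (i < n) profile[(i + 1):n] else numeric(0)
    higher_r <- which(right > h)
    rbase <- if (length(higher_r) > 0) {
      min(profile[(i + 1):(i + min(higher_r))])
    } else {
      min(right, 0)
    }
    h - max(lbase, rbase)
  }, numeric(1))
  tibble::tibble(index = idx, height = profile[idx], prominence = prom)
}

#' Per-cell ring morphometry
#'
#' Applies [measure_band_width()] and [measure_band_diameter()] to each cell
#' and returns one row per cell; unmeasurable diameters (fewer than two
#' qualifying peaks) become `NA`.
#'
#' @param cells A list of localization tibbles (each already in its cell
#'   frame), or a single tibble with a `cell` column.
#' @param ... Passed on to the per-cell measurements.
#' @return Tibble with columns `cell`, `width_nm`, `diameter_nm`.
#' @export
ring_morphometry <- function(cells, ...) {
  if (is.data.frame(cells)) {
    stopifnot("cell" %in% names(cells))
    cells <- split(cells, cells$cell)
  }
  purrr::imap_dfr(cells, function(locs, id) {
    w <- tryCatch(measure_band_width(locs, ...), error = function(e) NA_real_)
    d <- tryCatch(measure_band_diameter(locs), error = function(e) NA_real_)
    tibble::tibble(cell = id, width_nm = w, diameter_nm = d)
  })
}

#' Summarize per-cell measurements as mean and standard error
#'
#' @param measurements Tibble from [ring_morphometry()].
#' @return One-row tibble with `n_cells`, `width_nm`, `se_width`,
#'   `diameter_nm`, `se_diameter` (means across cells, se = sd/sqrt(n)).
#' @export
summarize_rings <- function(measurements) {
  se <- function(v) stats::sd(v, na.rm = TRUE) / sqrt(sum(is.finite(v)))
  tibble::tibble(
    n_cells = nrow(measurements),
    width_nm = mean(measurements$width_nm, na.rm = TRUE),
    se_width = se(measurements$width_nm),
    diameter_nm = mean(measurements$diameter_nm, na.rm = TRUE),
    se_diameter = se(measurements$diameter_nm)
  )
}

#' Fit the paired-diameter relation between two ring species
#'
#' Ordinary least squares of the second species' ring diameter on the
#' first's, per cell. The x-intercept of the fitted line estimates the
#' constant diameter offset between the two structures; half of it is the
#' radial separation between the layers.
#'
#' @param pairs Data frame whose first two columns (or `x`/`y`) are the
#'   per-cell diameters (nm) of the reference species and the second species.
#' @param x,y Optional column names (defaults: first and second column).
#' @return Object of class `diameter_fit` with `slope`, `intercept`,
#'   `x_intercept`, `radial_separation`, `r_squared` and the underlying `lm`.
#' @export
fit_diameter_correlation <- function(pairs, x = names(pairs)[1], y = names(pairs)[2]) {
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 2)
  xv <- pairs[[x]]
  yv <- pairs[[y]]
  if (nrow(pairs) < 3 && nrow(pairs) != 2) {
    stop("need at least 2 diameter pairs", call. = FALSE)
  }
  if (stats::sd(xv) < .Machine$double.eps^0.5) {
    stop("degenerate fit: no variance in the x diameters", call. = FALSE)
  }
  fit <- stats::lm(yv ~ xv)
  cf <- stats::coef(fit)
  slope <- unname(cf[2])
  intercept <- unname(cf[1])
  x_int <- if (abs(slope) > .Machine$double.eps) -intercept / slope else NA_real_
  structure(
    list(
      slope = slope,
      intercept = intercept,
      x_intercept = x_int,
      radial_separation = x_int / 2,
      r_squared = suppressWarnings(summary(fit)$r.squared),
      n = nrow(pairs),
      lm = fit
    ),
    class = "diameter_fit"
  )
}

#' @export
print.diameter_fit <- function(x, ...) {
  cat(sprintf("<diameter_fit> y = %.2f x %+.1f (n = %d, R^2 = %.3f)\n",
              x$slope, x$intercept, x$n, x$r_squared))
  cat(sprintf("  x-intercept %.1f nm -> radial separation %.1f nm\n",
              x$x_intercept, x$radial_separation))
  invisible(x)
}

#' Compare two groups of per-cell measurements
#'
#' Welch two-sample t-test (two-sided). When both groups have zero variance,
#' p = 1 if the means agree and p = 0 otherwise, by convention.
#'
#' @param a,b Numeric vectors of per-cell measurements (each n >= 2).
#' @return One-row tibble with `statistic`, `df`, `p_value`.
#' @export
compare_groups <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    return(tibble::tibble(statistic = NA_real_, df = NA_real_, p_value = p))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value)
}
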