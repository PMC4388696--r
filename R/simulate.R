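# Ground-truth simulators for the analyses: cylindrical-shell ring bands,
# two-color channel pairs, radially placed chromosome clusters, iPALM layers
# over a dye-coated surface, fiducial-bead control points and FRAP traces.
#
# Every generator is deterministic given `seed` (via withr::with_seed);
# `seed = NULL` uses the session RNG stream.

.with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# FWHM of a Gaussian = 2*sqrt(2*log(2)) * sd
fwhm_to_sd <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
sd_to_fwhm <- function(sd) sd * 2 * sqrt(2 * log(2))

#' Simulate a ring/band localization table
#'
#' True molecule positions lie on a cylindrical shell of radius `diameter/2`
#' about the cell long axis (the x axis of the cell frame); long-axis
#' positions are Gaussian with full width at half maximum `band_width`.
#' In 2D mode the shell is projected onto the imaging (x-y) plane before
#' lateral localization noise is added; in 3D mode z is retained and axial
#' noise added. Background localizations are uniform over the field.
#'
#' @param diameter Ring diameter, nm.
#' @param band_width Band FWHM along the long axis, nm.
#' @param n_molecules Number of true molecules (default 600 per ring).
#' @param loc_precision Lateral localization sd, nm (default 20; roughly a
#'   45 nm image resolution).
#' @param z_precision Axial localization sd, nm (3D mode only; default 17).
#' @param background_density Background localizations per square micrometre
#'   of the field (default 0).
#' @param dims 2 (project out z) or 3 (keep z).
#' @param field_half Half-extent of the square field used for background and
#'   as the x range margin, nm.
#' @param seed Integer seed or `NULL`.
#' @return A localization tibble in the cell frame (channel `"1"`), with a
#'   `truth` attribute holding the noiseless molecule coordinates.
#' @export
simulate_ring_band <- function(diameter, band_width, n_molecules = 600,
                               loc_precision = 20, z_precision = 17,
                               background_density = 0, dims = 2,
                               field_half = max(1000, diameter), seed = NULL) {
  stopifnot(diameter > 0, band_width > 0, n_molecules >= 1,
            loc_precision >= 0, z_precision >= 0, background_density >= 0,
            dims %in% c(2, 3))
  .with_seed(seed, {
    r <- diameter / 2
    x <- stats::rnorm(n_molecules, 0, fwhm_to_sd(band_width))
    theta <- stats::runif(n_molecules, 0, 2 * pi)
    y <- r * cos(theta)
    z <- r * sin(theta)
    truth <- tibble::tibble(x_nm = x, y_nm = y, z_nm = z)
    obs <- tibble::tibble(
      x_nm = x + stats::rnorm(n_molecules, 0, loc_precision),
      y_nm = y + stats::rnorm(n_molecules, 0, loc_precision)
    )
    if (dims == 3) {
      obs$z_nm <- z + stats::rnorm(n_molecules, 0, z_precision)
    }
    n_bg <- stats::rpois(1, background_density * (2 * field_half / 1000)^2)
    if (n_bg > 0) {
      bg <- tibble::tibble(
        x_nm = stats::runif(n_bg, -field_half, field_half),
        y_nm = stats::runif(n_bg, -field_half, field_half)
      )
      if (dims == 3) bg$z_nm <- stats::runif(n_bg, -field_half, field_half)
      obs <- dplyr::bind_rows(obs, bg)
    }
    obs$frame <- seq_len(nrow(obs))
    obs$channel <- "1"
    obs$precision_nm <- rep(max(loc_precision, .Machine$double.eps), nrow(obs))
    attr(obs, "truth") <- truth
    obs
  })
}

#' Simulate a two-color localization pair
#'
#' Channel 1 is a ring sample; channel 2 is an independent detection of the
#' same true molecules, shifted by `shift_y` along the short axis, with
#' residual channel-registration error added to every channel-2 record.
#' `registration_sd` is the 2-D RMS registration error (per-axis Gaussian sd
#' `registration_sd/sqrt(2)`), matching the convention in which an 18 nm
#' registration error means an 18 nm RMS two-dimensional displacement.
#'
#' @inheritParams simulate_ring_band
#' @param shift_y Short-axis offset applied to channel 2, nm.
#' @param registration_sd 2-D RMS registration error, nm (default 18).
#' @param detection_efficiency Per-channel detection probability in (0, 1].
#' @param seed Integer seed or `NULL`.
#' @return A localization tibble with channels `"1"` and `"2"`; `truth`
#'   attribute as in [simulate_ring_band()].
#' @export
simulate_two_color <- function(diameter, band_width, n_molecules = 600,
                               loc_precision = 20, shift_y = 0,
                               registration_sd = 18, detection_efficiency = 1,
                               background_density = 0, seed = NULL) {
  stopifnot(shift_y >= 0 || shift_y < 0, registration_sd >= 0,
            detection_efficiency > 0, detection_efficiency <= 1)
  .with_seed(seed, {
    base <- simulate_ring_band(diameter, band_width, n_molecules,
                               loc_precision = 0, background_density = 0,
                               dims = 2, seed = NULL)
    truth <- attr(base, "truth")
    detect <- function(ch, dy, reg_sd) {
      keep <- stats::runif(nrow(truth)) < detection_efficiency
      n <- sum(keep)
      out <- tibble::tibble(
        x_nm = truth$x_nm[keep] + stats::rnorm(n, 0, loc_precision),
        y_nm = truth$y_nm[keep] + dy + stats::rnorm(n, 0, loc_precision),
        frame = seq_len(n),
        channel = ch,
        precision_nm = rep(max(loc_precision, .Machine$double.eps), n)
      )
      if (reg_sd > 0) {
        s <- reg_sd / sqrt(2)
        out$x_nm <- out$x_nm + stats::rnorm(n, 0, s)
        out$y_nm <- out$y_nm + stats::rnorm(n, 0, s)
      }
      out
    }
    ch1 <- detect("1", 0, 0)
    ch2 <- detect("2", shift_y, registration_sd)
    out <- dplyr::bind_rows(ch1, ch2)
    attr(out, "truth") <- truth
    out
  })
}

#' Simulate radially placed cluster centers
#'
#' Places cluster centers at radius r from the cell long axis with a uniform
#' angular position, and records the short-axis (2-D projected) displacement
#' each would show in an image. The cross-section coordinates are
#' `(y, z) = (r cos(phi), r sin(phi))`; the observed projected displacement
#' is `r_proj = |r cos(phi)|`.
#'
#' Two radial models are available: `"gaussian"` draws r from
#' `Normal(mu_r, sigma_r)` with negative draws rejected and redrawn;
#' `"disk"` samples (y, z) uniformly on the disk of radius `r_max`.
#'
#' @param n_clusters Number of clusters.
#' @param mode `"gaussian"` or `"disk"`.
#' @param mu_r,sigma_r Gaussian-radius mean and sd, nm.
#' @param r_max Disk radius, nm.
#' @param seed Integer seed or `NULL`.
#' @return Tibble with columns `r` (true radius), `phi` (angle) and
#'   `r_proj` (projected short-axis displacement), all nm except `phi` (rad).
#' @export
simulate_radial_clusters <- function(n_clusters, mode = c("gaussian", "disk"),
                                     mu_r = 280, sigma_r = 120, r_max = 419,
                                     seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_clusters >= 1)
  .with_seed(seed, {
    if (mode == "gaussian") {
      stopifnot(sigma_r > 0)
      r <- stats::rnorm(n_clusters, mu_r, sigma_r)
      while (any(r < 0)) {  # rejection keeps radii nonnegative (~1% at 280/120)
        bad <- r < 0
        r[bad] <- stats::rnorm(sum(bad), mu_r, sigma_r)
      }
      phi <- stats::runif(n_clusters, 0, 2 * pi)
      tibble::tibble(r = r, phi = phi, r_proj = abs(r * cos(phi)))
    } else {
      stopifnot(r_max > 0)
      y <- numeric(0)
      z <- numeric(0)
      while (length(y) < n_clusters) {  # rejection sampling on the disk
        m <- 2 * (n_clusters - length(y)) + 16
        yy <- stats::runif(m, -r_max, r_max)
        zz <- stats::runif(m, -r_max, r_max)
        ok <- yy^2 + zz^2 <= r_max^2
        y <- c(y, yy[ok])
        z <- c(z, zz[ok])
      }
      y <- y[seq_len(n_clusters)]
      z <- z[seq_len(n_clusters)]
      tibble::tibble(r = sqrt(y^2 + z^2),
                     phi = atan2(z, y) %% (2 * pi),
                     r_proj = abs(y))
    }
  })
}

#' Simulate iPALM molecule layers above a dye-coated surface
#'
#' Produces a 3-D localization table with a `"surface"` channel at z = 0
#' (Gaussian axial spread of the given FWHM, emulating the dye-coated
#' coverslip) and one protein layer per entry of `depths`, each Gaussian about
#' its depth with sd `z_precision`.
#'
#' @param depths Data frame (or tibble) with columns `z` (nm above the
#'   surface) and `n` (localization count), one row per layer; row names or a
#'   `channel` column name the layers, otherwise `"layer1"`, `"layer2"`, ...
#' @param z_precision Axial localization sd, nm (default 17).
#' @param surface_n Surface-dye localization count (default 2000).
#' @param surface_fwhm Surface axial FWHM, nm (default 10).
#' @param field_half Lateral half-extent, nm; x and y uniform on the square.
#' @param seed Integer seed or `NULL`.
#' @return A 3-D localization tibble with channels `"surface"` and the layer
#'   names.
#' @export
simulate_ipalm_layers <- function(depths, z_precision = 17, surface_n = 2000,
                                  surface_fwhm = 10, field_half = 500,
                                  seed = NULL) {
  depths <- tibble::as_tibble(depths)
  stopifnot(nrow(depths) >= 1, all(c("z", "n") %in% names(depths)),
            surface_fwhm > 0, surface_n >= 0, z_precision >= 0)
  if (!"channel" %in% names(depths)) {
    depths$channel <- paste0("layer", seq_len(nrow(depths)))
  }
  .with_seed(seed, {
    layer_tbl <- purrr::pmap_dfr(depths, function(z, n, channel, ...) {
      tibble::tibble(
        x_nm = stats::runif(n, -field_half, field_half),
        y_nm = stats::runif(n, -field_half, field_half),
        z_nm = stats::rnorm(n, z, z_precision),
        channel = channel
      )
    })
    surf <- tibble::tibble(
      x_nm = stats::runif(surface_n, -field_half, field_half),
      y_nm = stats::runif(surface_n, -field_half, field_half),
      z_nm = stats::rnorm(surface_n, 0, fwhm_to_sd(surface_fwhm)),
      channel = "surface"
    )
    out <- dplyr::bind_rows(surf, layer_tbl)
    out$frame <- seq_len(nrow(out))
    out
  })
}

#' Simulate fiducial-bead control-point pairs
#'
#' Each bead appears in both channels; the channel-2 position is an affine
#' transform of the channel-1 position plus isotropic Gaussian noise,
#' emulating snapshots of multi-color beads across the field.
#'
#' @param n_points Number of control points (>= 3).
#' @param linear 2x2 linear part of the channel-1 to channel-2 transform.
#' @param translation Length-2 translation, nm.
#' @param noise_sd Per-axis Gaussian noise sd added to each channel, nm.
#' @param field_half Half-extent of the bead field, nm.
#' @param seed Integer seed or `NULL`.
#' @return Tibble with columns `x1, y1, x2, y2` (nm).
#' @export
simulate_beads <- function(n_points, linear = diag(2), translation = c(0, 0),
                           noise_sd = 0, field_half = 20000, seed = NULL) {
  stopifnot(n_points >= 3, all(dim(linear) == c(2, 2)), length(translation) == 2,
            noise_sd >= 0)
  .with_seed(seed, {
    p1 <- cbind(stats::runif(n_points, -field_half, field_half),
                stats::runif(n_points, -field_half, field_half))
    p2 <- p1 %*% t(linear) + matrix(translation, n_points, 2, byrow = TRUE)
    if (noise_sd > 0) {
      p1 <- p1 + matrix(stats::rnorm(2 * n_points, 0, noise_sd), ncol = 2)
      p2 <- p2 + matrix(stats::rnorm(2 * n_points, 0, noise_sd), ncol = 2)
    }
    tibble::tibble(x1 = p1[, 1], y1 = p1[, 2], x2 = p2[, 1], y2 = p2[, 2])
  })
}

#' Simulate FRAP intensity traces
#'
#' Emulates the acquisition design used for divisome turnover measurements:
#' frames at `frame_interval` (default 2 s, i.e. 30 frames per minute for
#' 4 min = 120 frames), with the photobleaching step during `bleach_frame`
#' (default frame 2). The bleach-ROI intensity is the prebleach level before
#' the bleach, drops to `1 - bleach_depth` of prebleach at the bleach frame,
#' and recovers as
#' `I(t') = floor + (plateau - floor) * (1 - exp(-k t'))` with
#' `k = log(2) / halftime` and t' measured from the first post-bleach frame.
#' The whole-midcell ROI stays at the prebleach level. Gaussian noise of sd
#' `noise_sd` (fraction of prebleach) is added to both ROIs per frame.
#'
#' @param halftime Recovery half-time, s.
#' @param n_traces Number of traces (cells).
#' @param frame_interval Seconds between frames (default 2).
#' @param n_frames Frames per trace (default 120).
#' @param bleach_frame Frame during which the bleach occurs (default 2).
#' @param bleach_depth Fractional intensity drop at the bleach (default 0.8).
#' @param plateau Recovery plateau as a fraction of prebleach (default 0.8).
#' @param noise_sd Per-frame Gaussian noise, fraction of prebleach.
#' @param seed Integer seed or `NULL`.
#' @return Tibble with columns `trace`, `frame`, `t_s`, `I_bleach`,
#'   `I_midcell` (intensities normalized so prebleach = 1).
#' @export
simulate_frap <- function(halftime, n_traces = 1, frame_interval = 2,
                          n_frames = 120, bleach_frame = 2, bleach_depth = 0.8,
                          plateau = 0.8, noise_sd = 0.05, seed = NULL) {
  stopifnot(halftime > 0, bleach_depth > 0, bleach_depth <= 1,
            n_frames > bleach_frame, n_traces >= 1, noise_sd >= 0)
  k <- log(2) / halftime
  floor_level <- 1 - bleach_depth
  .with_seed(seed, {
    purrr::map_dfr(seq_len(n_traces), function(tr) {
      frame <- seq_len(n_frames)
      t_s <- (frame - 1) * frame_interval
      ib <- numeric(n_frames)
      ib[frame < bleach_frame] <- 1
      ib[frame == bleach_frame] <- floor_level
      post <- frame > bleach_frame
      tprime <- (frame[post] - (bleach_frame + 1)) * frame_interval
      ib[post] <- floor_level + (plateau - floor_level) * (1 - exp(-k * tprime))
      im <- rep(1, n_frames)
      if (noise_sd > 0) {
        ib <- ib + stats::rnorm(n_frames, 0, noise_sd)
        im <- im + stats::rnorm(n_frames, 0, noise_sd)
      }
      tibble::tibble(trace = tr, frame = frame, t_s = t_s,
                     I_bleach = ib, I_midcell = im)
    })
  })
}
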