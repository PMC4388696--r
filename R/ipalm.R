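# Surface-referenced z-position estimation for interferometric PALM:
# locate the dye-coated coverslip surface by a Gaussian fit to its z
# histogram, average molecule z-positions inside a user-defined box at the
# bottom of each cell, and propagate label-size uncertainty when comparing
# species.

#' Fit the coverslip-surface z position
#'
#' Gaussian fit to the 1-nm-binned z histogram of the surface-dye channel,
#' returning the surface center and the full width at half maximum of the
#' fit. Surface fits are expected to be sharp (FWHM around 10 nm); a FWHM
#' above 50 nm triggers a quality warning.
#'
#' @param locs 3-D localization tibble of the surface channel
#'   (>= 100 records).
#' @param bin Histogram bin, nm (default 1).
#' @return Tibble with `z0` (surface center, nm) and `fwhm` (nm).
#' @export
fit_surface_z <- function(locs, bin = 1) {
  validate_locs(locs)
  if (!has_z(locs)) stop("surface fit requires z coordinates", call. = FALSE)
  if (nrow(locs) < 100) {
    stop("insufficient data: need >= 100 surface localizations, have ",
         nrow(locs), call. = FALSE)
  }
  fit <- .fit_gaussian_1d(locs$z_nm, bin)
  fwhm <- sd_to_fwhm(fit$sigma)
  if (fwhm > 50) {
    warning(sprintf("surface fit FWHM %.1f nm exceeds 50 nm; surface may be tilted or doubled",
                    fwhm))
  }
  tibble::tibble(z0 = fit$mu, fwhm = fwhm)
}

#' Mean z-position of molecules in a box above the surface
#'
#' Averages the z-positions of molecules inside a box centered at the bottom
#' of the cell: `z0 <= z <= z0 + z_depth` and `|y| <= width/2` (short-axis
#' coordinate). Returns the mean height above the surface, `mean(z) - z0`.
#' The default box (z-depth 150 nm, width 200 nm) restricts the average to
#' the flat bottom of the cell, away from curved side regions.
#'
#' @param locs 3-D localization tibble in the cell frame.
#' @param z0 Surface z position, nm (from [fit_surface_z()]).
#' @param z_depth Box depth above the surface, nm (default 150).
#' @param width Box width along the short axis, nm (default 200).
#' @param min_molecules Minimum in-box molecules for a valid estimate
#'   (default 10).
#' @return Mean z above the surface, nm; `NA` when the box holds fewer than
#'   `min_molecules` molecules (the cell is then excluded from cross-cell
#'   averages).
#' @export
mean_z_in_box <- function(locs, z0, z_depth = 150, width = 200,
                          min_molecules = 10) {
  validate_locs(locs)
  if (!has_z(locs)) stop("mean_z_in_box requires z coordinates", call. = FALSE)
  stopifnot(z_depth > 0, width > 0)
  inbox <- locs$z_nm >= z0 & locs$z_nm <= z0 + z_depth &
    abs(locs$y_nm) <= width / 2
  if (sum(inbox) < min_molecules) {
    return(NA_real_)
  }
  mean(locs$z_nm[inbox]) - z0
}

#' Per-cell surface-referenced z estimation
#'
#' Runs [fit_surface_z()] on the surface channel and [mean_z_in_box()] on the
#' protein channel of each cell's localization table, then summarizes across
#' cells.
#'
#' @param cells List of 3-D localization tibbles, each with a `channel`
#'   column containing `surface_channel` and `protein_channel` records.
#' @param surface_channel,protein_channel Channel identifiers.
#' @param ... Passed to [mean_z_in_box()].
#' @return Object of class `z_estimate`: `mean_z` (cross-cell mean, nm), `se`
#'   (nm), `n_cells` (cells with a valid box), and the `per_cell` tibble.
#' @export
estimate_mean_z <- function(cells, surface_channel = "surface",
                            protein_channel = "layer1", ...) {
  per_cell <- purrr::imap_dfr(cells, function(locs, id) {
    surf <- dplyr::filter(locs, .data$channel == surface_channel)
    prot <- dplyr::filter(locs, .data$channel == protein_channel)
    z0 <- fit_surface_z(surf)$z0
    tibble::tibble(cell = id, z0 = z0,
                   mean_z = mean_z_in_box(prot, z0, ...))
  })
  valid <- per_cell$mean_z[is.finite(per_cell$mean_z)]
  structure(
    list(
      mean_z = mean(valid),
      se = stats::sd(valid) / sqrt(length(valid)),
      n_cells = length(valid),
      per_cell = per_cell
    ),
    class = "z_estimate"
  )
}

#' @export
print.z_estimate <- function(x, ...) {
  cat(sprintf("<z_estimate> z = %.1f +/- %.1f nm (n = %d cells)\n",
              x$mean_z, x$se, x$n_cells))
  invisible(x)
}

#' Axial displacement between two species with label-size uncertainty
#'
#' Difference of two surface-referenced mean z estimates, with the
#' fluorescent-label sizes (and optionally the two standard errors) combined
#' in quadrature into an uncertainty. Two ~4 nm labels alone give
#' `sqrt(4^2 + 4^2) = 5.7` nm. The displacement is called significant when
#' its magnitude exceeds the combined uncertainty.
#'
#' @param a,b `z_estimate` objects (or lists with `mean_z` and `se`).
#' @param label_sizes Length-2 numeric, label sizes in nm (default `c(4, 4)`,
#'   the physical size of a fluorescent-protein label).
#' @param include_se Also fold the two standard errors into the uncertainty
#'   (default `TRUE`); set `FALSE` for the label-only uncertainty.
#' @return One-row tibble with `displacement`, `uncertainty`, `significant`.
#' @export
species_displacement <- function(a, b, label_sizes = c(4, 4), include_se = TRUE) {
  stopifnot(length(label_sizes) == 2, all(label_sizes >= 0))
  disp <- a$mean_z - b$mean_z
  u2 <- sum(label_sizes^2)
  if (include_se) {
    u2 <- u2 + (a$se %||% 0)^2 + (b$se %||% 0)^2
  }
  unc <- sqrt(u2)
  tibble::tibble(displacement = disp, uncertainty = unc,
                 significant = abs(disp) > unc)
}

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0 || all(is.na(x))) y else x
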