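# Cluster detection in rendered localization images, axis displacements of
# cluster centroids, and the two radial placement models for
# chromosome-anchored clusters: a Gaussian-distributed radius with random
# projection angle, and uniform sampling of a disk cross-section.

#' Detect clusters in a rendered image
#'
#' Threshold-based cluster analysis: binarize the image at a fraction of its
#' maximum, label 8-connected components, and summarize each component by the
#' intensity-weighted centroid and the second-moment ellipse (major axis
#' length = 4 sd along the principal axis, the standard region-properties
#' convention, so a uniform elliptical region reports its true axis length).
#'
#' @param image A `rendered_image` (see [render_image()]).
#' @param threshold_frac Threshold as a fraction of the image maximum
#'   (default 0.2). A threshold above the maximum yields an empty set.
#' @return Tibble with one row per cluster: `centroid_x`, `centroid_y` (nm),
#'   `major_axis` (nm), `eccentricity`, `n_localizations`.
#' @export
detect_clusters <- function(image, threshold_frac = 0.2) {
  stopifnot(inherits(image, "rendered_image"), threshold_frac > 0)
  m <- image$counts
  mask <- m >= threshold_frac * max(m)
  empty <- tibble::tibble(centroid_x = numeric(), centroid_y = numeric(),
                          major_axis = numeric(), eccentricity = numeric(),
                          n_localizations = numeric())
  if (!any(mask)) return(empty)
  labels <- .label_components8(mask)
  p <- image$pixel_size
  cx <- image$origin[["x"]] + (row(m) - 0.5) * p
  cy <- image$origin[["y"]] + (col(m) - 0.5) * p
  purrr::map_dfr(seq_len(max(labels)), function(lab) {
    sel <- labels == lab
    w <- m[sel]
    x <- cx[sel]
    y <- cy[sel]
    W <- sum(w)
    mx <- sum(w * x) / W
    my <- sum(w * y) / W
    # second central moments of the intensity distribution, plus the pixel's
    # own variance p^2/12 so single-pixel clusters have finite extent
    sxx <- sum(w * (x - mx)^2) / W + p^2 / 12
    syy <- sum(w * (y - my)^2) / W + p^2 / 12
    sxy <- sum(w * (x - mx) * (y - my)) / W
    ev <- eigen(matrix(c(sxx, sxy, sxy, syy), 2, 2), symmetric = TRUE)$values
    tibble::tibble(
      centroid_x = mx, centroid_y = my,
      major_axis = 4 * sqrt(ev[1]),
      eccentricity = sqrt(max(0, 1 - ev[2] / ev[1])),
      n_localizations = W
    )
  })
}

# 8-connected component labeling of a logical matrix via an adjacency graph.
.label_components8 <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  labels <- matrix(0L, nrow(mask), ncol(mask))
  if (n == 0) return(labels)
  id <- matrix(0L, nrow(mask), ncol(mask))
  id[mask] <- seq_len(sum(mask))
  # order which() returns (column-major) matches id assignment
  edges <- integer(0)
  offs <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  for (k in seq_len(nrow(offs))) {
    ni <- idx[, 1] + offs[k, 1]
    nj <- idx[, 2] + offs[k, 2]
    ok <- ni >= 1 & ni <= nrow(mask) & nj >= 1 & nj <= ncol(mask)
    ok[ok] <- mask[cbind(ni[ok], nj[ok])]
    if (any(ok)) {
      edges <- c(edges, rbind(id[idx[ok, , drop = FALSE]],
                              id[cbind(ni[ok], nj[ok])]))
    }
  }
  g <- igraph::make_graph(edges, n = sum(mask), directed = FALSE)
  comp <- igraph::components(g)$membership
  labels[mask] <- comp[id[mask]]
  labels
}

#' Axis displacements of cluster centroids
#'
#' Expresses cluster centroids in the cell frame and reports the absolute
#' displacement from the cell center along the long axis (`l`) and the short
#' axis (`r_prime`, the 2-D projection of the true radial displacement).
#'
#' @param clusters Tibble from [detect_clusters()] (centroids in the lab
#'   frame, or already in the cell frame if `frame` is an identity frame).
#' @param frame A [cell_frame()].
#' @return Tibble with `l`, `r_prime` (nm, absolute) and `cell_length` (nm).
#' @export
axis_displacements <- function(clusters, frame) {
  stopifnot(inherits(frame, "cell_frame"))
  locs <- tibble::tibble(x_nm = clusters$centroid_x, y_nm = clusters$centroid_y)
  cf <- to_cell_frame(locs, frame)
  tibble::tibble(l = abs(cf$x_nm), r_prime = abs(cf$y_nm),
                 cell_length = frame$length)
}

#' Fit the Gaussian-radius projection model to projected displacements
#'
#' The model places clusters at radius r ~ Normal(mu, sigma) (negative draws
#' rejected) with a uniformly random angular position; the observed
#' short-axis displacement is the projection |r cos(phi)|. For each (mu,
#' sigma) on a grid, `n_sim` projected displacements are simulated with a
#' common seed, both simulated and observed samples are binned (60 nm bins)
#' and normalized to unit area, and the candidate minimizing the sum of
#' squared histogram differences is returned.
#'
#' @param r_prime Observed projected displacements, nm (>= 100 values).
#' @param bin Histogram bin, nm (default 60).
#' @param mu_grid,sigma_grid Candidate grids, nm.
#' @param n_sim Simulated displacements per candidate (default 1000).
#' @param seed Seed reused for every candidate (common random numbers keep
#'   the objective surface smooth).
#' @return Object of class `radial_fit` with `model = "gaussian"`, `mu_r`,
#'   `sigma_r`, `sse`, and the full `objective` grid tibble. Warns when the
#'   optimum lies on the grid boundary.
#' @export
fit_gaussian_projection <- function(r_prime, bin = 60,
                                    mu_grid = seq(100, 500, by = 10),
                                    sigma_grid = seq(20, 250, by = 10),
                                    n_sim = 1000, seed = 1) {
  stopifnot(length(r_prime) >= 100, all(r_prime >= 0), bin > 0, n_sim >= 1)
  breaks <- seq(0, max(r_prime, mu_grid + 4 * max(sigma_grid)) + bin, by = bin)
  obs_d <- .hist_density(r_prime, breaks)
  grid <- tidyr::expand_grid(mu = mu_grid, sigma = sigma_grid)
  grid$sse <- purrr::map2_dbl(grid$mu, grid$sigma, function(mu, sigma) {
    sim <- simulate_radial_clusters(n_sim, "gaussian", mu_r = mu,
                                    sigma_r = sigma, seed = seed)
    sum((.hist_density(sim$r_proj, breaks) - obs_d)^2)
  })
  best <- grid[which.min(grid$sse), ]
  if ((length(mu_grid) > 2 && best$mu %in% range(mu_grid)) ||
      (length(sigma_grid) > 2 && best$sigma %in% range(sigma_grid))) {
    warning("optimum on the grid boundary; widen mu_grid/sigma_grid")
  }
  structure(
    list(model = "gaussian", mu_r = best$mu, sigma_r = best$sigma,
         sse = best$sse, bins = bin, objective = grid,
         n_obs = length(r_prime)),
    class = "radial_fit"
  )
}

# unit-area histogram density on fixed breaks; values beyond the last break
# are clamped into the final bin so candidates share a common support
.hist_density <- function(x, breaks) {
  x <- pmin(x, max(breaks) - 1e-9)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  h$density
}

#' Fit the uniform-disk projection model to projected displacements
#'
#' Assumes clusters uniformly sample a disk cross-section of radius R; the
#' projected displacement then has the analytic density
#' `f(r') = 4/(pi R^2) * sqrt(R^2 - r'^2)` on `[0, R]`. The density is
#' integrated over the 60 nm bins analytically, compared with the observed
#' unit-area histogram by least squares over a grid of R, and the best R is
#' returned with the derived radial moments mean = 2R/3, sd = R/sqrt(18).
#'
#' @param r_prime Observed projected displacements, nm (>= 100 values).
#' @param bin Histogram bin, nm (default 60).
#' @param r_grid Candidate disk radii, nm.
#' @return Object of class `radial_fit` with `model = "disk"`, `r_max`,
#'   derived `mean_r` and `sd_r`, `sse` and the `objective` grid.
#' @export
fit_uniform_disk <- function(r_prime, bin = 60, r_grid = seq(100, 800, by = 1)) {
  stopifnot(length(r_prime) >= 100, all(r_prime >= 0), bin > 0)
  if (max(r_prime) > max(r_grid)) {
    warning("observed displacements exceed every candidate disk radius")
  }
  breaks <- seq(0, max(r_prime, r_grid) + bin, by = bin)
  obs_d <- .hist_density(r_prime, breaks)
  sse <- vapply(r_grid, function(R) {
    probs <- .disk_bin_probs(breaks, R)
    sum((probs / bin - obs_d)^2)
  }, numeric(1))
  best <- which.min(sse)
  if (length(r_grid) > 2 && best %in% c(1L, length(r_grid))) {
    warning("optimum on the grid boundary; widen r_grid")
  }
  R <- r_grid[best]
  structure(
    list(model = "disk", r_max = R, mean_r = 2 * R / 3, sd_r = R / sqrt(18),
         sse = sse[best], bins = bin,
         objective = tibble::tibble(r_max = r_grid, sse = sse),
         n_obs = length(r_prime)),
    class = "radial_fit"
  )
}

#' Projected density of the uniform-disk model
#'
#' Density of the absolute short-axis projection of a point uniform on a
#' disk of radius `r_max`: `4/(pi r_max^2) sqrt(r_max^2 - r^2)` on
#' `[0, r_max]`, zero beyond.
#'
#' @param r Projected displacement(s), nm.
#' @param r_max Disk radius, nm.
#' @return Density value(s), 1/nm.
#' @export
disk_projection_density <- function(r, r_max) {
  stopifnot(r_max > 0)
  ifelse(r >= 0 & r <= r_max,
         4 / (pi * r_max^2) * sqrt(pmax(r_max^2 - r^2, 0)),
         0)
}

# exact integral of disk_projection_density over each histogram bin;
# antiderivative of sqrt(R^2 - x^2) is (x sqrt(R^2-x^2) + R^2 asin(x/R))/2
.disk_bin_probs <- function(breaks, R) {
  G <- function(x) {
    x <- pmin(x, R)
    (x * sqrt(pmax(R^2 - x^2, 0)) + R^2 * asin(pmin(x / R, 1))) / 2
  }
  4 / (pi * R^2) * diff(G(breaks))
}

#' @export
print.radial_fit <- function(x, ...) {
  if (x$model == "gaussian") {
    cat(sprintf("<radial_fit gaussian> r = %.0f +/- %.0f nm (sse %.3g, n = %d)\n",
                x$mu_r, x$sigma_r, x$sse, x$n_obs))
  } else {
    cat(sprintf("<radial_fit disk> r_max = %.0f nm -> r = %.0f +/- %.0f nm (sse %.3g, n = %d)\n",
                x$r_max, x$mean_r, x$sd_r, x$sse, x$n_obs))
  }
  invisible(x)
}

#' Long-axis displacement binned by cell length
#'
#' Summarizes cluster long-axis displacement as binned means by cell length
#' (no parametric model): clusters migrate toward midcell as cells elongate.
#'
#' @param displacements Tibble from [axis_displacements()] (columns `l`,
#'   `cell_length`).
#' @param length_bin Cell-length bin, nm (default 500).
#' @return Tibble with `length_mid`, `mean_l`, `n`.
#' @export
long_axis_profile <- function(displacements, length_bin = 500) {
  displacements |>
    dplyr::mutate(length_mid = (floor(.data$cell_length / length_bin) + 0.5) * length_bin) |>
    dplyr::group_by(.data$length_mid) |>
    dplyr::summarise(mean_l = mean(.data$l), n = dplyr::n(), .groups = "drop")
}
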