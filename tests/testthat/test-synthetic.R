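test_that("ring generator places molecules on the cylindrical shell", {
  # noiseless: 3D distance from the long axis equals d/2 exactly
  r <- simulate_ring_band(600, 115, n_molecules = 500, loc_precision = 0,
                          z_precision = 0, dims = 3, seed = 1)
  expect_equal(nrow(r), 500)
  expect_equal(sqrt(r$y_nm^2 + r$z_nm^2), rep(300, 500), tolerance = 1e-12)

  # long-axis sd matches the FWHM identity sd = w / (2 sqrt(2 log 2))
  r2 <- simulate_ring_band(689, 115, n_molecules = 10000, loc_precision = 0,
                           seed = 2)
  expect_equal(sd(r2$x_nm), 115 / (2 * sqrt(2 * log(2))), tolerance = 0.02)

  # deterministic given seed
  expect_identical(simulate_ring_band(600, 100, 50, seed = 9),
                   simulate_ring_band(600, 100, 50, seed = 9))
})

test_that("two-color generator applies the short-axis shift and efficiency", {
  # all noise off: channel-2 y differs from truth by exactly shift_y
  tc <- simulate_two_color(613, 161, 400, loc_precision = 0, shift_y = 97,
                           registration_sd = 0, seed = 3)
  truth <- attr(tc, "truth")
  ch1 <- dplyr::filter(tc, channel == "1")
  ch2 <- dplyr::filter(tc, channel == "2")
  expect_equal(ch1$y_nm, truth$y_nm)
  expect_equal(mean(ch2$y_nm - truth$y_nm), 97, tolerance = 1e-12)

  # zero shift, zero noise: channels identical
  tc0 <- simulate_two_color(613, 161, 200, loc_precision = 0, shift_y = 0,
                            registration_sd = 0, seed = 4)
  expect_equal(dplyr::filter(tc0, channel == "1")$y_nm,
               dplyr::filter(tc0, channel == "2")$y_nm)

  # detection efficiency 0.5: channel-2 count inside the binomial 99% interval
  tc5 <- simulate_two_color(613, 161, 1000, detection_efficiency = 0.5,
                            seed = 5)
  n2 <- sum(tc5$channel == "2")
  expect_true(n2 >= qbinom(0.005, 1000, 0.5) && n2 <= qbinom(0.995, 1000, 0.5))
})

test_that("radial cluster generator matches its closed-form moments", {
  # gaussian mode: projection identity E|cos phi| = 2/pi
  g <- simulate_radial_clusters(1e5, "gaussian", mu_r = 280, sigma_r = 120,
                                seed = 6)
  expect_true(min(g$r) >= 0)
  expect_equal(mean(g$r_proj), (2 / pi) * mean(g$r), tolerance = 0.01)

  # disk mode: E[r] = 2R/3 and E[r_proj] relates through the same projection
  d <- simulate_radial_clusters(1e5, "disk", r_max = 419, seed = 7)
  expect_equal(mean(d$r), 2 * 419 / 3, tolerance = 0.01)
  expect_true(all(d$r <= 419))

  # sigma -> 0 with phi = 0 forced: projection equals mu_r
  tiny <- simulate_radial_clusters(200, "gaussian", mu_r = 280,
                                   sigma_r = 1e-9, seed = 8)
  expect_equal(abs(tiny$r * cos(0)), rep(280, 200), tolerance = 1e-6)
})

test_that("radial samples are seed-stable in distribution", {
  # different seeds give statistically indistinguishable r_proj samples
  ref <- simulate_radial_clusters(2000, "gaussian", seed = 100)$r_proj
  pvals <- sapply(101:110, function(s) {
    suppressWarnings(stats::ks.test(
      ref, simulate_radial_clusters(2000, "gaussian", seed = s)$r_proj
    )$p.value)
  })
  expect_gt(min(pvals), 0.01)
})

test_that("iPALM layer generator builds surface plus layers", {
  depths <- tibble::tibble(z = c(67, 117), n = c(1000, 800))
  tbl <- simulate_ipalm_layers(depths, z_precision = 0, surface_n = 500,
                               surface_fwhm = 10, seed = 9)
  expect_equal(nrow(tbl), 1000 + 800 + 500)
  expect_equal(mean(tbl$z_nm[tbl$channel == "layer1"]), 67, tolerance = 1e-12)
  expect_equal(mean(tbl$z_nm[tbl$channel == "layer2"]), 117, tolerance = 1e-12)
  # surface z histogram has the requested FWHM
  surf <- dplyr::filter(tbl, channel == "surface")
  fit <- fit_surface_z(surf)
  expect_equal(fit$fwhm, 10, tolerance = 0.1)
  expect_equal(fit$z0, 0, tolerance = 0.5)
})

test_that("bead generator realizes the requested transform and noise", {
  # identity, no noise: channels identical
  b0 <- simulate_beads(10, seed = 10)
  expect_equal(b0$x1, b0$x2)
  expect_equal(b0$y1, b0$y2)

  # pure translation
  bt <- simulate_beads(20, translation = c(50, -20), seed = 11)
  expect_equal(bt$x2 - bt$x1, rep(50, 20))
  expect_equal(bt$y2 - bt$y1, rep(-20, 20))

  # noise_sd 5 per channel per axis: RMS residual after the true transform
  # is sqrt(4 * 25) = 10 = 5 * sqrt(2) per axis pair summed over x and y
  bn <- simulate_beads(4000, noise_sd = 5, seed = 12)
  rms <- sqrt(mean((bn$x2 - bn$x1)^2 + (bn$y2 - bn$y1)^2))
  expect_equal(rms, 5 * sqrt(2) * sqrt(2), tolerance = 0.1)
})

test_that("FRAP generator follows the acquisition timing and recovery law", {
  tr <- simulate_frap(19.8, noise_sd = 0, seed = 13)
  # default timing: 120 frames spanning 4 minutes at 2 s intervals
  expect_equal(nrow(tr), 120)
  expect_equal(max(tr$t_s), 238)
  expect_equal(diff(tr$t_s)[1], 2)

  # half-time definition: at t' = halftime the trace is halfway between
  # floor and plateau
  floor_level <- 0.2
  plateau <- 0.8
  idx <- which(tr$frame == 3 + round(19.8 / 2))  # t' = 19.8 not on grid;
  # check via the exact law instead at frame offsets on the grid
  tprime <- (tr$frame - 3) * 2
  post <- tr$frame >= 3
  expect_equal(tr$I_bleach[post],
               floor_level + (plateau - floor_level) *
                 (1 - exp(-log(2) / 19.8 * tprime[post])),
               tolerance = 1e-12)
  # midcell ROI constant at prebleach
  expect_equal(tr$I_midcell, rep(1, 120))
})
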