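test_that("band width recovers the generating FWHM", {
  # noiseless synthetic ring at w = 115
  r <- simulate_ring_band(689, 115, n_molecules = 10000, loc_precision = 0,
                          seed = 1)
  expect_equal(measure_band_width(r), 115, tolerance = 3 / 115)

  # degenerate: all localizations at one long-axis coordinate
  deg <- tibble::tibble(x_nm = rep(5, 60), y_nm = seq_len(60))
  expect_warning(w <- measure_band_width(deg), "degenerate")
  expect_equal(w, 0)

  # too few localizations
  expect_error(measure_band_width(fixture_locs(20)), "insufficient")

  # ROI restricts the fit window
  r2 <- dplyr::bind_rows(
    simulate_ring_band(689, 115, 1000, loc_precision = 0, seed = 2),
    tibble::tibble(x_nm = stats::runif(200, 2000, 3000),
                   y_nm = stats::runif(200, -350, 350))
  )
  expect_equal(measure_band_width(r2, roi = c(-600, 600)), 115,
               tolerance = 5 / 115)
})

test_that("band diameter finds the two most distal peaks", {
  # dense noiseless projected shell of radius 300: diameter 600 within a bin
  r <- simulate_ring_band(600, 115, 20000, loc_precision = 0, seed = 3)
  expect_lte(abs(measure_band_diameter(r) - 600), 15)
  expect_lte(abs(measure_band_diameter(r, deconvolve = FALSE) - 600), 15)

  # unimodal Gaussian profile has no diameter
  uni <- tibble::tibble(x_nm = stats::rnorm(500, 0, 50),
                        y_nm = stats::rnorm(500, 0, 80))
  expect_error(measure_band_diameter(uni), class = "divlayers_no_diameter")

  expect_error(measure_band_diameter(fixture_locs(50)), "insufficient")
})

test_that("measured diameter is monotone in the true diameter", {
  means <- sapply(c(400, 600, 800), function(d) {
    mean(sapply(1:8, function(s) {
      locs <- simulate_ring_band(d, 115, 600, loc_precision = 20, seed = s)
      tryCatch(measure_band_diameter(locs), error = function(e) NA_real_)
    }), na.rm = TRUE)
  })
  expect_true(all(diff(means) > 0))
})

test_that("width and diameter recover generating values at default noise", {
  res <- purrr::map_dfr(1:20, function(s) {
    locs <- simulate_ring_band(689, 115, 600, loc_precision = 20, seed = s)
    tibble::tibble(
      w = measure_band_width(locs),
      d = tryCatch(measure_band_diameter(locs), error = function(e) NA_real_)
    )
  })
  expect_equal(mean(res$w), 115, tolerance = 0.03)
  expect_equal(mean(res$d, na.rm = TRUE), 689, tolerance = 0.03)
})

test_that("profile peak finding reports topographic prominence", {
  # two clear peaks with a saddle; interior bump has small prominence
  profile <- c(0, 2, 10, 3, 4, 3, 1, 8, 0)
  pk <- find_profile_peaks(profile)
  expect_equal(pk$index, c(3, 5, 8))
  expect_equal(pk$prominence[pk$index == 3], 10)   # global max: full height
  expect_equal(pk$prominence[pk$index == 5], 1)    # bump above the saddle
  expect_equal(pk$prominence[pk$index == 8], 7)    # 8 minus saddle at 1
  # boundary maxima count as peaks (density is zero outside)
  expect_equal(find_profile_peaks(c(9, 1, 5))$index, c(1, 3))
})

test_that("diameter correlation line fit matches the normal equations", {
  # exact points on y = x - 95
  x <- c(500, 600, 700, 800)
  fit <- fit_diameter_correlation(tibble::tibble(d_ftsz = x, d_zapb = x - 95))
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, -95)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$x_intercept, 95)
  expect_equal(fit$radial_separation, 47.5)

  # two points: exact interpolating line
  f2 <- fit_diameter_correlation(tibble::tibble(x = c(0, 10), y = c(5, 25)))
  expect_equal(f2$slope, 2)
  expect_equal(f2$intercept, 5)

  # equals closed-form OLS on random data
  withr::with_seed(99, {
    xs <- stats::runif(40, 400, 900)
    ys <- xs - 95 + stats::rnorm(40, 0, 30)
  })
  f3 <- fit_diameter_correlation(tibble::tibble(x = xs, y = ys))
  sxy <- sum((xs - mean(xs)) * (ys - mean(ys)))
  sxx <- sum((xs - mean(xs))^2)
  expect_equal(f3$slope, sxy / sxx, tolerance = 1e-9)
  expect_equal(f3$intercept, mean(ys) - f3$slope * mean(xs), tolerance = 1e-9)

  # degenerate x variance
  expect_error(
    fit_diameter_correlation(tibble::tibble(x = c(5, 5, 5), y = 1:3)),
    "degenerate"
  )

  # tidy/glance expose the derived quantities
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "radial_separation"], 47.5)
  expect_equal(glance(fit)$r_squared, 1)
})

test_that("group comparison is a calibrated Welch test", {
  # identical groups
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3))$p_value, 1,
               tolerance = 1e-12)
  # zero-variance convention
  expect_equal(compare_groups(c(2, 2), c(2, 2))$p_value, 1)

  # summary-equivalent groups to widths 115 (se 3, n 54) vs 161 (se 12, n 34)
  a <- fixture_group(54, 115, 3)
  b <- fixture_group(34, 161, 12)
  res <- compare_groups(a, b)
  expect_lt(res$p_value, 1e-3)
  expect_equal(abs(res$statistic), 46 / sqrt(3^2 + 12^2), tolerance = 1e-6)

  # null calibration: p values uniform under the null
  pvals <- withr::with_seed(7, {
    sapply(1:400, function(i) {
      compare_groups(stats::rnorm(20), stats::rnorm(20))$p_value
    })
  })
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("per-cell morphometry aggregates as mean and standard error", {
  cells <- lapply(1:6, function(s) {
    simulate_ring_band(689, 115, 600, loc_precision = 20, seed = s)
  })
  per_cell <- ring_morphometry(cells)
  expect_equal(nrow(per_cell), 6)
  smry <- summarize_rings(per_cell)
  expect_equal(smry$n_cells, 6)
  expect_equal(smry$width_nm, mean(per_cell$width_nm))
  expect_equal(smry$se_width,
               sd(per_cell$width_nm) / sqrt(6))
})
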