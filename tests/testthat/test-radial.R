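test_that("cluster detection finds components with correct shape", {
  # a uniform disk of diameter 100 nm rendered at 5 nm pixels
  disk <- withr::with_seed(1, {
    pts <- tibble::tibble(x_nm = stats::runif(4000, -50, 50),
                          y_nm = stats::runif(4000, -50, 50))
    pts[pts$x_nm^2 + pts$y_nm^2 <= 50^2, ]
  })
  img <- render_image(disk, pixel_size = 5)
  cl <- detect_clusters(img, threshold_frac = 0.01)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$major_axis, 100, tolerance = 0.1)
  expect_lt(cl$eccentricity, 0.35)   # near-circular
  expect_equal(cl$n_localizations, nrow(disk))
  expect_equal(cl$centroid_x, 0, tolerance = 3)

  # two clusters 500 nm apart
  two <- dplyr::bind_rows(disk, dplyr::mutate(disk, x_nm = x_nm + 500))
  cl2 <- detect_clusters(render_image(two, 5), threshold_frac = 0.01)
  expect_equal(nrow(cl2), 2)

  # threshold above the maximum: empty set, not an error
  expect_equal(nrow(detect_clusters(img, threshold_frac = 1.01)), 0)
})

test_that("labeling merges diagonal (8-connected) pixels", {
  locs <- tibble::tibble(x_nm = c(2, 12, 22), y_nm = c(2, 12, 22))
  img <- render_image(locs, pixel_size = 10)
  cl <- detect_clusters(img, threshold_frac = 0.5)
  expect_equal(nrow(cl), 1)  # three diagonal pixels form one component
})

test_that("axis displacements report absolute cell-frame offsets", {
  clusters <- tibble::tibble(centroid_x = c(0, 200, -300),
                             centroid_y = c(0, 100, -150))
  fr <- cell_frame(0, 0, 0, 2600)
  disp <- axis_displacements(clusters, fr)
  expect_equal(disp$l, c(0, 200, 300))
  expect_equal(disp$r_prime, c(0, 100, 150))
  expect_equal(disp$cell_length, rep(2600, 3))
})

test_that("projection identity holds for several radius distributions", {
  # E|r cos phi| = (2/pi) E[r] for any nonnegative radius distribution
  check <- function(r) {
    phi <- withr::with_seed(5, stats::runif(length(r), 0, 2 * pi))
    expect_equal(mean(abs(r * cos(phi))), (2 / pi) * mean(r),
                 tolerance = 0.02)
  }
  check(rep(280, 5e4))
  check(withr::with_seed(6, stats::runif(5e4, 0, 500)))
  check(simulate_radial_clusters(5e4, "gaussian", 280, 120, seed = 7)$r)
})

test_that("disk model density normalizes and has closed-form moments", {
  for (R in c(3, 419)) {
    total <- stats::integrate(disk_projection_density, 0, R, r_max = R,
                              rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8)
  }
  # R = 3: moments (2, 0.7071)
  expect_equal(2 * 3 / 3, 2)
  mc <- simulate_radial_clusters(1e6, "disk", r_max = 419, seed = 8)
  expect_equal(mean(mc$r), 2 * 419 / 3, tolerance = 3 * sd(mc$r) / sqrt(1e6) / (2 * 419 / 3))
  expect_equal(sd(mc$r), 419 / sqrt(18), tolerance = 0.01)
})

test_that("gaussian projection fit recovers generating parameters", {
  obs <- simulate_radial_clusters(613, "gaussian", 280, 120, seed = 9)$r_proj
  fit <- fit_gaussian_projection(obs, mu_grid = seq(180, 380, by = 20),
                                 sigma_grid = seq(40, 200, by = 20),
                                 n_sim = 2000, seed = 4)
  expect_lte(abs(fit$mu_r - 280), 20)
  expect_lte(abs(fit$sigma_r - 120), 20)

  # the objective is deterministic given the seed
  fit2 <- fit_gaussian_projection(obs, mu_grid = seq(180, 380, by = 20),
                                  sigma_grid = seq(40, 200, by = 20),
                                  n_sim = 2000, seed = 4)
  expect_identical(fit$objective, fit2$objective)

  # a second generating condition
  obs2 <- simulate_radial_clusters(800, "gaussian", 150, 100, seed = 10)$r_proj
  fit3 <- fit_gaussian_projection(obs2, mu_grid = seq(70, 270, by = 20),
                                  sigma_grid = seq(40, 180, by = 20),
                                  n_sim = 2000, seed = 4)
  expect_equal(fit3$mu_r, 150, tolerance = 40 / 150)
  expect_equal(fit3$sigma_r, 100, tolerance = 40 / 100)
})

test_that("degenerate sigma data pushes the fitted sigma to the grid floor", {
  r <- rep(280, 600)
  phi <- withr::with_seed(11, stats::runif(600, 0, 2 * pi))
  obs <- abs(r * cos(phi))
  fit <- suppressWarnings(
    fit_gaussian_projection(obs, mu_grid = seq(220, 340, by = 20),
                            sigma_grid = seq(10, 150, by = 20),
                            n_sim = 2000, seed = 4)
  )
  expect_equal(fit$sigma_r, 10)
})

test_that("uniform disk fit recovers the generating radius and moments", {
  obs <- simulate_radial_clusters(613, "disk", r_max = 419, seed = 12)$r_proj
  fit <- fit_uniform_disk(obs)
  expect_equal(fit$r_max, 419, tolerance = 0.06)
  expect_equal(fit$mean_r, 2 * fit$r_max / 3)
  expect_equal(fit$sd_r, fit$r_max / sqrt(18))

  w <- capture_warnings(fit_uniform_disk(obs, r_grid = seq(100, 300, by = 10)))
  expect_true(any(grepl("exceed|boundary", w)))
})

test_that("long-axis profile bins displacements by cell length", {
  disp <- tibble::tibble(l = c(100, 200, 400, 500),
                         r_prime = 0,
                         cell_length = c(2200, 2300, 3300, 3400))
  prof <- long_axis_profile(disp, length_bin = 1000)
  expect_equal(nrow(prof), 2)
  expect_equal(prof$mean_l, c(150, 450))
})
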