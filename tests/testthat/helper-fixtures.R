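# Small in-code fixtures shared across test files.

# a localization tibble with deterministic coordinates
fixture_locs <- function(n = 10, with_z = FALSE, seed = 42) {
  withr::with_seed(seed, {
    out <- tibble::tibble(
      x_nm = stats::runif(n, -500, 500),
      y_nm = stats::runif(n, -400, 400),
      frame = seq_len(n),
      channel = "1",
      precision_nm = stats::runif(n, 10, 30)
    )
    if (with_z) out$z_nm <- stats::runif(n, 0, 200)
    out
  })
}

# vector with exact mean m and exact standard error se at size n
fixture_group <- function(n, m, se) {
  base <- scale(seq_len(n))[, 1]          # mean 0, sd 1
  m + base * se * sqrt(n)
}

# naive O(n1*n2*grid) cross-correlation, the independent oracle
xcorr_bruteforce <- function(ch1, ch2, h, grid) {
  sapply(grid, function(d) {
    acc <- 0
    for (i in seq_len(nrow(ch1))) {
      acc <- acc + sum(exp(-((ch1$x_nm[i] - ch2$x_nm)^2 +
                               (ch1$y_nm[i] - ch2$y_nm - d)^2) / (2 * h^2)))
    }
    acc / (nrow(ch1) * nrow(ch2))
  })
}
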