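# FRAP analysis: bleach-ratio screening, two-ROI normalization,
# single-exponential recovery fitting (half-time) and bootstrap standard
# errors.
#
# Trace layout: tibbles with columns `frame`, `I_bleach`, `I_midcell` (and
# optionally `trace`, `t_s`), one row per acquisition frame. The default
# acquisition is 120 frames at 2 s intervals with the photobleaching step
# during frame 2, so frame 3 is the first post-bleach acquisition.

#' Screen a FRAP trace by bleaching ratio
#'
#' The bleaching ratio is the fractional intensity drop of the bleach ROI
#' between the last prebleach acquisition and the first post-bleach
#' acquisition: `(I_bleach(1) - I_bleach(3)) / I_bleach(1)`. Only traces
#' bleached more deeply than `min_ratio` (default 40%) are analyzed.
#'
#' @param trace Tibble with at least 3 frames of `I_bleach`.
#' @param min_ratio Acceptance threshold (default 0.40).
#' @return One-row tibble with `ratio` and `accepted`.
#' @export
screen_bleach_ratio <- function(trace, min_ratio = 0.40) {
  stopifnot(is.data.frame(trace), "I_bleach" %in% names(trace),
            nrow(trace) >= 3)
  i1 <- trace$I_bleach[1]
  i3 <- trace$I_bleach[3]
  if (!is.finite(i1) || i1 <= 0) {
    return(tibble::tibble(ratio = NA_real_, accepted = FALSE))
  }
  ratio <- (i1 - i3) / i1
  tibble::tibble(ratio = ratio, accepted = ratio > min_ratio)
}

#' Normalize a FRAP trace to [0, ~1]
#'
#' Sets the first post-bleach acquisition, `I_bleach(3)`, to 0 and uses the
#' average of the last 60 frames of the whole-midcell ROI as the maximum
#' (the midcell ROI is far more stable than the tail of the bleach ROI):
#' \deqn{R(N) = \frac{I_{Bleach}(N) - I_{Bleach}(3)}
#'   {\langle I_{Midcell}(61{:}120)\rangle - I_{Bleach}(3)}}
#'
#' @param trace Tibble with `I_bleach` and `I_midcell` (>= 120 frames for the
#'   default plateau window).
#' @param plateau_frames Frames averaged for the maximum (default 61:120).
#' @param bleach_frame Frame during which the bleach occurred (default 2; the
#'   first post-bleach frame is `bleach_frame + 1`).
#' @return Tibble with `frame`, `t_s` (if present in the input) and the
#'   normalized recovery `R`; `R` at the first post-bleach frame is exactly 0.
#' @export
normalize_trace <- function(trace, plateau_frames = 61:120, bleach_frame = 2) {
  stopifnot(is.data.frame(trace),
            all(c("I_bleach", "I_midcell") %in% names(trace)))
  if (nrow(trace) < max(plateau_frames)) {
    stop("trace has ", nrow(trace), " frames; plateau window needs ",
         max(plateau_frames), call. = FALSE)
  }
  i0 <- trace$I_bleach[bleach_frame + 1]
  denom <- mean(trace$I_midcell[plateau_frames]) - i0
  if (!is.finite(denom) || denom <= 0) {
    stop("normalization error: midcell plateau does not exceed the post-bleach level",
         call. = FALSE)
  }
  out <- tibble::tibble(frame = trace$frame %||% seq_len(nrow(trace)),
                        R = (trace$I_bleach - i0) / denom)
  if ("t_s" %in% names(trace)) out$t_s <- trace$t_s
  out
}

#' Fit the recovery half-time to averaged normalized traces
#'
#' Averages normalized traces pointwise, then fits the post-bleach portion to
#' a single exponential `R(t') = A (1 - exp(-k t'))` with t' measured from
#' the first post-bleach frame. The amplitude is free (bounded in (0, 1.2])
#' rather than forced to full recovery, since observed plateaus sit below 1.
#' The half-time is `log(2) / k`.
#'
#' @param traces A list of normalized tibbles (from [normalize_trace()]), or
#'   a single long tibble with a `trace` column.
#' @param frame_interval Seconds between frames (default 2).
#' @param bleach_frame Bleach frame (default 2).
#' @return Object of class `frap_fit` with `k` (1/s), `halftime` (s),
#'   `amplitude`, `n_traces` and the averaged `curve` tibble.
#' @export
fit_halftime <- function(traces, frame_interval = 2, bleach_frame = 2) {
  traces <- .as_trace_list(traces)
  stopifnot(length(traces) >= 1)
  frames <- traces[[1]]$frame
  mat <- vapply(traces, function(tr) {
    stopifnot(identical(tr$frame, frames))
    tr$R
  }, numeric(length(frames)))
  avg <- rowMeans(as.matrix(mat))
  post <- frames > bleach_frame
  tp <- (frames[post] - (bleach_frame + 1)) * frame_interval
  df <- data.frame(t = tp, R = avg[post])
  a0 <- min(max(mean(df$R[df$t >= stats::quantile(df$t, 0.6)]), 0.05), 1.2)
  k0 <- log(2) / max(frame_interval, df$t[which(df$R >= a0 / 2)[1]] %||% 10)
  fit <- tryCatch(
    minpack.lm::nlsLM(R ~ A * (1 - exp(-k * t)), data = df,
                      start = list(A = a0, k = k0),
                      lower = c(A = 1e-6, k = 1e-6),
                      upper = c(A = 1.2, k = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("recovery fit failed to converge: ",
                             conditionMessage(e), call. = FALSE)
  )
  cf <- stats::coef(fit)
  structure(
    list(
      k = unname(cf["k"]),
      halftime = log(2) / unname(cf["k"]),
      amplitude = unname(cf["A"]),
      n_traces = length(traces),
      frame_interval = frame_interval,
      bleach_frame = bleach_frame,
      curve = tibble::tibble(t = df$t, R = df$R,
                             fitted = stats::predict(fit))
    ),
    class = "frap_fit"
  )
}

.as_trace_list <- function(traces) {
  if (is.data.frame(traces)) {
    if ("trace" %in% names(traces)) {
      traces <- split(tibble::as_tibble(traces), traces$trace)
    } else {
      traces <- list(tibble::as_tibble(traces))
    }
  }
  lapply(traces, function(tr) {
    if (!"frame" %in% names(tr)) tr$frame <- seq_len(nrow(tr))
    tr
  })
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> half-time %.2f s (k = %.4f 1/s, A = %.2f, %d traces)\n",
              x$halftime, x$k, x$amplitude, x$n_traces))
  invisible(x)
}

#' Bootstrap standard error of the recovery half-time
#'
#' Resamples the set of normalized traces with replacement `n_boot` times
#' (default 3000); each resample is averaged and refit, and the standard
#' error is the standard deviation of the resulting half-time distribution.
#'
#' @param traces As in [fit_halftime()] (>= 2 traces).
#' @param n_boot Number of bootstrap resamples (default 3000).
#' @param seed Integer seed or `NULL`.
#' @inheritParams fit_halftime
#' @param max_fail_frac Abort if more than this fraction of resample fits
#'   fail (default 0.05); failed resamples are otherwise skipped.
#' @return One-row tibble with `se_halftime` (s), `n_boot`, `n_failed`.
#' @export
bootstrap_se <- function(traces, n_boot = 3000, seed = NULL,
                         frame_interval = 2, bleach_frame = 2,
                         max_fail_frac = 0.05) {
  traces <- .as_trace_list(traces)
  stopifnot(length(traces) >= 2, n_boot >= 2)
  .with_seed(seed, {
    ht <- vapply(seq_len(n_boot), function(b) {
      pick <- sample.int(length(traces), replace = TRUE)
      tryCatch(
        fit_halftime(traces[pick], frame_interval, bleach_frame)$halftime,
        error = function(e) NA_real_
      )
    }, numeric(1))
    n_failed <- sum(is.na(ht))
    if (n_failed > max_fail_frac * n_boot) {
      stop(n_failed, " of ", n_boot, " bootstrap fits failed", call. = FALSE)
    }
    tibble::tibble(se_halftime = stats::sd(ht, na.rm = TRUE),
                   n_boot = n_boot, n_failed = n_failed)
  })
}

#' Full FRAP pipeline: screen, normalize, fit
#'
#' Applies the bleach-ratio screen to every trace, normalizes the accepted
#' ones, fits the averaged recovery, and optionally bootstraps the half-time
#' standard error.
#'
#' @param traces Long tibble from [simulate_frap()] (or equivalent) with a
#'   `trace` column, or a list of per-trace tibbles.
#' @param min_ratio Bleach-ratio threshold (default 0.40).
#' @param n_boot Bootstrap resamples; 0 skips the bootstrap.
#' @param seed Seed for the bootstrap.
#' @inheritParams fit_halftime
#' @return A `frap_fit`, with elements `n_screened_out` and (when
#'   bootstrapped) `se_halftime` added.
#' @export
frap_pipeline <- function(traces, min_ratio = 0.40, n_boot = 0, seed = NULL,
                          frame_interval = 2, bleach_frame = 2) {
  traces <- .as_trace_list(traces)
  keep <- vapply(traces, function(tr) screen_bleach_ratio(tr, min_ratio)$accepted,
                 logical(1))
  if (!any(keep)) stop("no trace passed the bleach-ratio screen", call. = FALSE)
  norm <- lapply(traces[keep], normalize_trace, bleach_frame = bleach_frame)
  fit <- fit_halftime(norm, frame_interval, bleach_frame)
  fit$n_screened_out <- sum(!keep)
  if (n_boot > 0 && length(norm) >= 2) {
    fit$se_halftime <- bootstrap_se(norm, n_boot, seed, frame_interval,
                                    bleach_frame)$se_halftime
  }
  fit
}
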