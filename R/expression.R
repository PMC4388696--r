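# Fluorescence-based expression calibration: convert integrated cellular
# intensities to fusion-protein copy numbers and the fraction of total
# (wild-type + fusion) protein, anchored on a reference fusion whose
# expression fraction is known.

#' Build an expression calibration from a reference fusion
#'
#' Given a reference fusion protein whose integrated cellular fluorescence
#' and expression fraction are known, derives the per-molecule intensity.
#' With the fraction defined against total (wt + fusion) protein,
#' `f = N_fus / (N_endog + N_fus)`, the reference copy number is
#' `N_fus,ref = f/(1-f) * N_endog,ref` and the per-molecule intensity is
#' `k_int = I_ref / N_fus,ref`.
#'
#' @param reference_intensity Integrated cellular intensity of the reference
#'   fusion, arbitrary units.
#' @param reference_fraction Known expression fraction of the reference
#'   fusion, in (0, 1) (fusion / (wt + fusion)).
#' @param endogenous_copies Endogenous (wt) copy number of the reference
#'   protein, molecules per cell.
#' @return Object of class `expr_calib` with `k_int` (units per molecule).
#' @export
expression_calibration <- function(reference_intensity, reference_fraction,
                                   endogenous_copies) {
  stopifnot(reference_intensity > 0, reference_fraction > 0,
            reference_fraction < 1, endogenous_copies > 0)
  ref_copies <- reference_fraction / (1 - reference_fraction) * endogenous_copies
  structure(
    list(
      reference_intensity = reference_intensity,
      reference_fraction = reference_fraction,
      endogenous_copies = endogenous_copies,
      k_int = reference_intensity / ref_copies
    ),
    class = "expr_calib"
  )
}

#' @export
print.expr_calib <- function(x, ...) {
  cat(sprintf("<expr_calib> %.3f units/molecule (reference: %.0f units = %.0f%% of total)\n",
              x$k_int, x$reference_intensity, 100 * x$reference_fraction))
  invisible(x)
}

#' Fusion copy number and expression fraction from intensity
#'
#' Converts an integrated cellular intensity to fusion copies via the
#' calibration (`copies = intensity / k_int`) and reports the expression
#' fraction. The default convention expresses the fraction against total
#' protein, `100 * copies / (endog + copies)`; `mode = "wt"` gives the
#' fraction of the wild-type level instead (`100 * copies / endog`).
#'
#' @param intensity Integrated cellular intensity, same units as the
#'   calibration reference.
#' @param calib An [expression_calibration()].
#' @param endog Endogenous copy number of this protein, molecules per cell.
#' @param mode `"total"` (default; fusion / (wt + fusion)) or `"wt"`.
#' @return One-row tibble with `copies` and `fraction_pct`.
#' @export
fusion_fraction <- function(intensity, calib, endog, mode = c("total", "wt")) {
  mode <- match.arg(mode)
  stopifnot(inherits(calib, "expr_calib"))
  if (any(intensity <= 0) || any(endog <= 0)) {
    stop("intensity and endogenous copy number must be positive", call. = FALSE)
  }
  copies <- intensity / calib$k_int
  frac <- if (mode == "total") 100 * copies / (endog + copies) else 100 * copies / endog
  tibble::tibble(copies = copies, fraction_pct = frac)
}

#' Intensity implied by an expression fraction (inverse of [fusion_fraction()])
#'
#' @param fraction_pct Expression fraction, percent of total.
#' @inheritParams fusion_fraction
#' @return Intensity in calibration units.
#' @export
fraction_to_intensity <- function(fraction_pct, calib, endog) {
  stopifnot(inherits(calib, "expr_calib"),
            all(fraction_pct > 0), all(fraction_pct < 100), all(endog > 0))
  f <- fraction_pct / 100
  copies <- f / (1 - f) * endog
  copies * calib$k_int
}
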