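# Localization-table I/O, image rendering and per-cell coordinate frames.
#
# All coordinates are continuous nanometres in a lab frame. A cell frame maps
# the lab frame onto the cell's own axes: x = signed long-axis coordinate,
# y = signed short-axis coordinate, both relative to the cell center
# (right-handed convention).

# Canonical column names of the localization-table dialect.
.loc_canonical <- c("x_nm", "y_nm", "z_nm", "frame", "channel", "precision_nm")

# Common SMLM column aliases accepted on read (ThunderSTORM-style headers
# among them). Matching is case-insensitive after squeezing whitespace.
.loc_aliases <- c(
  "x" = "x_nm", "x [nm]" = "x_nm", "x(nm)" = "x_nm",
  "y" = "y_nm", "y [nm]" = "y_nm", "y(nm)" = "y_nm",
  "z" = "z_nm", "z [nm]" = "z_nm", "z(nm)" = "z_nm",
  "uncertainty [nm]" = "precision_nm", "uncertainty" = "precision_nm",
  "precision" = "precision_nm", "sigma [nm]" = "precision_nm"
)

#' Read a localization table
#'
#' Reads a comma-separated single-molecule localization table with one header
#' row. The canonical dialect uses columns `x_nm`, `y_nm`, and optionally
#' `z_nm`, `frame`, `channel`, `precision_nm` (all coordinates in nanometres).
#' Common SMLM aliases (`x`, `x [nm]`, `uncertainty [nm]`, ...) are accepted
#' and renamed on read.
#'
#' @param path Path to a CSV file with at least `x` and `y` columns.
#' @param aliases Accept common SMLM column aliases (default `TRUE`).
#' @return A tibble with canonical column names; coordinates in nm. The table
#'   carries z coordinates iff a z column was present.
#' @export
read_locs <- function(path, aliases = TRUE) {
  if (!file.exists(path)) {
    stop("localization file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  nm <- names(raw)
  if (aliases) {
    key <- tolower(gsub("\\s+", " ", trimws(nm)))
    hit <- key %in% names(.loc_aliases) & !(nm %in% .loc_canonical)
    nm[hit] <- unname(.loc_aliases[key[hit]])
    names(raw) <- nm
  }
  for (required in c("x_nm", "y_nm")) {
    if (!required %in% names(raw)) {
      stop("localization table is missing mandatory column '", required, "'",
           call. = FALSE)
    }
  }
  numeric_cols <- intersect(c("x_nm", "y_nm", "z_nm", "frame", "precision_nm"),
                            names(raw))
  for (col in numeric_cols) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]) & raw[[col]] != "NA")
    if (length(bad) > 0) {
      stop("non-numeric value in column '", col, "' at row ", bad[1],
           ": '", raw[[col]][bad[1]], "'", call. = FALSE)
    }
    raw[[col]] <- vals
  }
  out <- tibble::as_tibble(raw[, intersect(.loc_canonical, names(raw)), drop = FALSE])
  validate_locs(out)
  out
}

#' Write a localization table
#'
#' Writes the canonical CSV dialect. Reading the file back with [read_locs()]
#' reproduces all coordinates at the printed precision.
#'
#' @param locs A localization tibble (as returned by [read_locs()] or the
#'   `simulate_*` generators).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_locs <- function(locs, path) {
  validate_locs(locs)
  readr::write_csv(locs, path, progress = FALSE)
  invisible(path)
}

# Internal contract checks for localization tibbles.
validate_locs <- function(locs) {
  stopifnot(is.data.frame(locs))
  for (required in c("x_nm", "y_nm")) {
    if (!required %in% names(locs)) {
      stop("localization table is missing mandatory column '", required, "'",
           call. = FALSE)
    }
  }
  for (col in intersect(c("x_nm", "y_nm", "z_nm"), names(locs))) {
    if (any(!is.finite(locs[[col]]))) {
      stop("non-finite coordinate in column '", col, "'", call. = FALSE)
    }
  }
  if ("precision_nm" %in% names(locs)) {
    p <- locs$precision_nm
    if (any(!is.na(p) & p <= 0)) {
      stop("localization precision must be > 0 where present", call. = FALSE)
    }
  }
  invisible(locs)
}

#' Does a localization table carry z coordinates?
#' @param locs A localization tibble.
#' @return `TRUE` iff every record has a finite `z_nm`.
#' @export
has_z <- function(locs) {
  "z_nm" %in% names(locs) && all(is.finite(locs$z_nm))
}

#' Define a per-cell coordinate frame
#'
#' A cell frame is the cell's own axis system: origin at the cell center,
#' x along the long axis, y along the short axis (right-handed). The long-axis
#' orientation is an angle in `[0, pi)` measured in the lab frame.
#'
#' @param center_x,center_y Cell center, nm (lab frame).
#' @param angle Long-axis orientation, radians; normalized into `[0, pi)`.
#' @param length Cell length, nm (> 0).
#' @return An object of class `cell_frame`.
#' @export
cell_frame <- function(center_x = 0, center_y = 0, angle = 0, length = 3000) {
  stopifnot(is.finite(center_x), is.finite(center_y), is.finite(angle),
            is.finite(length), length > 0)
  angle <- angle %% pi
  structure(
    list(center_x = center_x, center_y = center_y, angle = angle, length = length),
    class = "cell_frame"
  )
}

#' @export
print.cell_frame <- function(x, ...) {
  cat(sprintf("<cell_frame> center (%.1f, %.1f) nm, axis %.3f rad, length %.0f nm\n",
              x$center_x, x$center_y, x$angle, x$length))
  invisible(x)
}

#' Transform localizations into a cell frame
#'
#' Rigid transform (rotation + translation): output `x_nm` is the signed
#' long-axis coordinate and `y_nm` the signed short-axis coordinate relative
#' to the cell center. All pairwise distances are preserved.
#'
#' @param locs A localization tibble (lab frame).
#' @param frame A [cell_frame()].
#' @return The tibble with `x_nm`/`y_nm` replaced by cell-frame coordinates.
#' @export
to_cell_frame <- function(locs, frame) {
  stopifnot(inherits(frame, "cell_frame"))
  validate_locs(locs)
  dx <- locs$x_nm - frame$center_x
  dy <- locs$y_nm - frame$center_y
  ca <- cos(frame$angle)
  sa <- sin(frame$angle)
  out <- locs
  out$x_nm <- ca * dx + sa * dy
  out$y_nm <- -sa * dx + ca * dy
  out
}

#' Inverse of [to_cell_frame()]
#'
#' @inheritParams to_cell_frame
#' @return The tibble mapped back to the lab frame.
#' @export
from_cell_frame <- function(locs, frame) {
  stopifnot(inherits(frame, "cell_frame"))
  validate_locs(locs)
  ca <- cos(frame$angle)
  sa <- sin(frame$angle)
  out <- locs
  out$x_nm <- ca * locs$x_nm - sa * locs$y_nm + frame$center_x
  out$y_nm <- sa * locs$x_nm + ca * locs$y_nm + frame$center_y
  out
}

#' Render a localization table into a 2D count image
#'
#' Bins localizations on a regular grid with half-open pixels
#' `[k*p, (k+1)*p)` whose origin is the minimum corner of the data, then
#' optionally applies Gaussian smoothing. Without smoothing the image holds
#' integer counts and conserves the number of localizations exactly.
#'
#' @param locs A non-empty localization tibble.
#' @param pixel_size Pixel edge, nm (default 15, the display pixel used for
#'   PALM pseudo-color images).
#' @param smoothing_sd Gaussian smoothing sd in nm; 0 disables smoothing.
#' @return A `rendered_image`: list with `counts` (matrix, rows indexing x
#'   bins, columns y bins), `pixel_size` (nm) and `origin` (nm, grid corner).
#' @export
render_image <- function(locs, pixel_size = 15, smoothing_sd = 0) {
  validate_locs(locs)
  stopifnot(pixel_size > 0, smoothing_sd >= 0)
  if (nrow(locs) == 0) {
    stop("cannot render an empty localization table", call. = FALSE)
  }
  origin <- c(
    x = floor(min(locs$x_nm) / pixel_size) * pixel_size,
    y = floor(min(locs$y_nm) / pixel_size) * pixel_size
  )
  ix <- floor((locs$x_nm - origin[["x"]]) / pixel_size) + 1L
  iy <- floor((locs$y_nm - origin[["y"]]) / pixel_size) + 1L
  nx <- max(ix)
  ny <- max(iy)
  counts <- matrix(0, nrow = nx, ncol = ny)
  for (k in seq_along(ix)) {
    counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1
  }
  if (smoothing_sd > 0) {
    counts <- .gauss_blur(counts, smoothing_sd / pixel_size)
  }
  structure(
    list(counts = counts, pixel_size = pixel_size, origin = origin),
    class = "rendered_image"
  )
}

# Separable Gaussian blur; sd in pixels. Kernel normalized so total
# intensity is preserved up to edge truncation.
.gauss_blur <- function(m, sd_px) {
  half <- max(1L, ceiling(3 * sd_px))
  k <- stats::dnorm(seq(-half, half), sd = sd_px)
  k <- k / sum(k)
  blur1 <- function(mat) {
    n <- nrow(mat)
    out <- matrix(0, n, ncol(mat))
    for (j in seq(-half, half)) {
      src <- pmin(pmax(seq_len(n) + j, 1L), n)  # replicate edges
      out <- out + k[j + half + 1L] * mat[src, , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(m))))
}

#' @export
print.rendered_image <- function(x, ...) {
  cat(sprintf("<rendered_image> %d x %d px at %.1f nm/px, total intensity %.1f\n",
              nrow(x$counts), ncol(x$counts), x$pixel_size, sum(x$counts)))
  invisible(x)
}

#' Write a rendered image as 16-bit TIFF
#'
#' @param image A `rendered_image`.
#' @param path Output TIFF path.
#' @param scale Divisor applied before writing; defaults to the image maximum
#'   so the full 16-bit range is used.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path, scale = max(image$counts)) {
  stopifnot(inherits(image, "rendered_image"))
  if (scale <= 0) scale <- 1
  # writeTIFF expects [0,1]; rows of the matrix become image rows (y), so
  # transpose to keep x horizontal.
  tiff::writeTIFF(t(pmin(image$counts / scale, 1)), path, bits.per.sample = 16L)
  invisible(path)
}
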