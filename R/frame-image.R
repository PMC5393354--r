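#' Single detector or dose grid
#'
#' The shared 2D grid container used throughout the pipeline: raw detector
#' frames (ADU), corrected images and fluence (relative units) and dose
#' maps (cGy) all live on such a grid. Positions are in mm relative to the
#' grid centre; for even dimensions the centre is the midpoint between the
#' two central pixels.
#'
#' @param pixels Numeric matrix (rows x cols), all values finite.
#' @param pitch_mm Pixel pitch in mm (default 0.2, the native panel pitch).
#' @param units One of `"ADU"`, `"relative"`, `"cGy"`.
#' @return A `frame_image`: the matrix with attributes `pitch_mm` and
#'   `units`.
#' @examples
#' img <- frame_image(matrix(1, 64, 64), pitch_mm = 0.4)
#' dim(img)
#' @export
frame_image <- function(pixels, pitch_mm = 0.2, units = c("ADU", "relative", "cGy")) {
  units <- match.arg(units)
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 8L || ncol(pixels) < 8L)
    stop("frame_image requires at least 8x8 pixels, got ",
         nrow(pixels), "x", ncol(pixels))
  if (!is.numeric(pitch_mm) || length(pitch_mm) != 1L || pitch_mm <= 0)
    stop("pitch_mm must be a single positive number")
  if (!all(is.finite(pixels)))
    stop("frame_image pixels must all be finite")
  storage.mode(pixels) <- "double"
  structure(pixels, pitch_mm = pitch_mm, units = units,
            class = c("frame_image", "matrix", "array"))
}

#' @export
print.frame_image <- function(x, ...) {
  cat(sprintf(
    "<frame_image> %d x %d px @ %.3g mm [%s], range [%.4g, %.4g]\n",
    nrow(x), ncol(x), attr(x, "pitch_mm"), attr(x, "units"),
    min(x), max(x)
  ))
  invisible(x)
}

is_frame_image <- function(x) inherits(x, "frame_image")

#' Pixel pitch of a grid object
#' @param x A `frame_image`, `kernel` or `dose_map`.
#' @return Pitch in mm.
#' @export
pitch_mm <- function(x) attr(x, "pitch_mm")

#' Units tag of a frame image
#' @param x A `frame_image`.
#' @return One of `"ADU"`, `"relative"`, `"cGy"`.
#' @export
units_tag <- function(x) attr(x, "units")

# Replace pixel values, keeping geometry/metadata.
with_pixels <- function(img, pixels, units = units_tag(img)) {
  frame_image(pixels, pitch_mm = pitch_mm(img), units = units)
}

# Positions (mm) of row/column centres relative to the grid centre.
# Works for odd and even dims: index i maps to (i - (n+1)/2) * pitch.
grid_positions <- function(n, pitch) (seq_len(n) - (n + 1) / 2) * pitch

#' Axis positions of a grid
#' @param img A `frame_image` (or any matrix-backed grid with a pitch).
#' @return List with `row_mm` and `col_mm`, positions of pixel centres in
#'   mm relative to the grid centre.
#' @export
frame_positions <- function(img) {
  p <- pitch_mm(img)
  list(row_mm = grid_positions(nrow(img), p),
       col_mm = grid_positions(ncol(img), p))
}

same_geometry <- function(a, b, tol = 1e-9) {
  nrow(a) == nrow(b) && ncol(a) == ncol(b) &&
    abs(pitch_mm(a) - pitch_mm(b)) <= tol * max(pitch_mm(a), pitch_mm(b))
}

stop_geometry <- function(a, b, what = "images") {
  if (!same_geometry(a, b))
    stop(sprintf(
      "geometry mismatch between %s: %dx%d @ %g mm vs %dx%d @ %g mm",
      what, nrow(a), ncol(a), pitch_mm(a), nrow(b), ncol(b), pitch_mm(b)
    ))
  invisible(TRUE)
}

#' Cine acquisition stack
#'
#' An ordered list of frames sharing one geometry, as produced by
#' continuous ("cine") acquisition over the whole beam-on time.
#'
#' @param frames List of `frame_image` objects with identical geometry.
#' @param frame_rate_fps Acquisition rate, in (0, 50] frames per second.
#' @param mode An [energy_mode()] or mode name (optional, may be `NA`).
#' @return A `cine_stack` object.
#' @export
cine_stack <- function(frames, frame_rate_fps = 25, mode = NULL) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("cine_stack requires a non-empty list of frames")
  frames <- lapply(frames, function(f) {
    if (is_frame_image(f)) f else frame_image(f)
  })
  first <- frames[[1L]]
  for (i in seq_along(frames)) {
    if (!same_geometry(frames[[i]], first))
      stop("frame ", i, " geometry differs from frame 1")
  }
  if (!is.numeric(frame_rate_fps) || frame_rate_fps <= 0 || frame_rate_fps > 50)
    stop("frame_rate_fps must lie in (0, 50]")
  if (!is.null(mode)) mode <- as_energy_mode(mode)
  structure(
    list(frames = frames, frame_rate_fps = frame_rate_fps, mode = mode),
    class = "cine_stack"
  )
}

#' @export
print.cine_stack <- function(x, ...) {
  f <- x$frames[[1L]]
  cat(sprintf(
    "<cine_stack> %d frames, %d x %d px @ %.3g mm, %.3g fps%s\n",
    length(x$frames), nrow(f), ncol(f), pitch_mm(f), x$frame_rate_fps,
    if (is.null(x$mode)) "" else paste0(", ", x$mode$name)
  ))
  invisible(x)
}

#' @export
length.cine_stack <- function(x) length(x$frames)

#' Per-pixel average of a cine stack
#'
#' Arithmetic mean over frames, the operation used to build averaged
#' dark-field and flood-field images from 300-frame calibration stacks.
#'
#' @param stack A [cine_stack()].
#' @return A `frame_image` with the per-pixel mean; units preserved.
#' @export
average_frames <- function(stack) {
  stopifnot(inherits(stack, "cine_stack"))
  n <- length(stack$frames)
  acc <- Reduce(`+`, lapply(stack$frames, unclass))
  with_pixels(stack$frames[[1L]], acc / n)
}

#' Per-pixel sum of a cine stack
#'
#' The integrated image for a delivery: each frame is recorded over part of
#' the beam-on time and the sum carries the whole delivered signal. This is
#' the default input to dose reconstruction.
#'
#' @param stack A [cine_stack()].
#' @return A `frame_image` with the per-pixel sum; units preserved.
#' @export
integrate_frames <- function(stack) {
  stopifnot(inherits(stack, "cine_stack"))
  acc <- Reduce(`+`, lapply(stack$frames, unclass))
  with_pixels(stack$frames[[1L]], acc)
}

#' Extract a 1D profile through a grid
#'
#' Nearest-row/column extraction (no interpolation) along the in-plane
#' (along columns, i.e. a fixed row) or cross-plane (fixed column) axis at
#' a given offset from the grid centre.
#'
#' @param img A `frame_image` or `dose_map`.
#' @param axis `"inplane"` (profile runs along the row direction) or
#'   `"crossplane"` (along the column direction).
#' @param offset_mm Perpendicular offset of the profile line from centre.
#' @return A tibble with columns `position_mm` and `value`.
#' @export
extract_profile <- function(img, axis = c("inplane", "crossplane"),
                            offset_mm = 0) {
  axis <- match.arg(axis)
  pos <- frame_positions(img)
  if (axis == "inplane") {
    # fixed row (selected by offset), positions run along columns
    idx <- which.min(abs(pos$row_mm - offset_mm))
    if (offset_mm < min(pos$row_mm) - pitch_mm(img) / 2 ||
        offset_mm > max(pos$row_mm) + pitch_mm(img) / 2)
      stop("offset_mm = ", offset_mm, " lies outside the grid")
    tibble::tibble(position_mm = pos$col_mm, value = as.numeric(unclass(img)[idx, ]))
  } else {
    idx <- which.min(abs(pos$col_mm - offset_mm))
    if (offset_mm < min(pos$col_mm) - pitch_mm(img) / 2 ||
        offset_mm > max(pos$col_mm) + pitch_mm(img) / 2)
      stop("offset_mm = ", offset_mm, " lies outside the grid")
    tibble::tibble(position_mm = pos$row_mm, value = as.numeric(unclass(img)[, idx]))
  }
}

#' Full width at half maximum of a profile
#'
#' Width between the 50%-of-maximum crossings, found by linear
#' interpolation between neighbouring samples. Used to check field sizes.
#'
#' @param profile Tibble with `position_mm`, `value` (e.g. from
#'   [extract_profile()]).
#' @param level Fraction of the profile maximum (default 0.5).
#' @return Width in mm, or `NA` if the profile never crosses the level.
#' @export
profile_width <- function(profile, level = 0.5) {
  v <- profile$value
  p <- profile$position_mm
  thr <- level * max(v)
  above <- v >= thr
  if (!any(above)) return(NA_real_)
  i1 <- which(above)[1L]
  i2 <- rev(which(above))[1L]
  left <- if (i1 == 1L) p[1L] else {
    p[i1 - 1L] + (thr - v[i1 - 1L]) / (v[i1] - v[i1 - 1L]) * (p[i1] - p[i1 - 1L])
  }
  right <- if (i2 == length(v)) p[length(v)] else {
    p[i2] + (v[i2] - thr) / (v[i2] - v[i2 + 1L]) * (p[i2 + 1L] - p[i2])
  }
  right - left
}
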