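#' Averaged dark-field image
#'
#' Per-pixel average of a beam-off cine stack (typically 300 frames); the
#' offset correction subtracted from every incoming raw image.
#'
#' @param stack Beam-off [cine_stack()].
#' @return `frame_image` in ADU.
#' @export
build_dark_field <- function(stack) {
  out <- average_frames(stack)
  with_pixels(out, unclass(out), units = "ADU")
}

#' Averaged flood-field image
#'
#' Average of offset-corrected open-beam frames: the per-pixel gain
#' reference. The open beam must fully cover the detector.
#'
#' @param stack Open-beam [cine_stack()].
#' @param dark Dark field from [build_dark_field()], same geometry.
#' @return `frame_image` in ADU (dark already subtracted).
#' @export
build_flood_field <- function(stack, dark) {
  avg <- average_frames(stack)
  stop_geometry(avg, dark, "flood stack and dark field")
  with_pixels(avg, unclass(avg) - unclass(dark), units = "ADU")
}

#' Flag dead / stuck pixels
#'
#' A pixel is flagged if its gain is non-positive (flood equals dark) or
#' if its dark or flood value is a robust outlier: more than `k_mad`
#' median absolute deviations from the map median.
#'
#' @param dark,flood Dark and flood `frame_image`s (flood already
#'   dark-subtracted).
#' @param k_mad Outlier threshold multiplier (default 6).
#' @return Logical matrix, `TRUE` = dead.
#' @export
detect_dead_pixels <- function(dark, flood, k_mad = 6) {
  stop_geometry(dark, flood, "dark and flood fields")
  out_of <- function(m) {
    md <- stats::median(m)
    s <- stats::mad(m)
    if (s == 0) s <- .Machine$double.eps
    abs(m - md) > k_mad * s
  }
  unclass(flood) <= 0 | out_of(unclass(dark)) | out_of(unclass(flood))
}

#' Beam-profile correction matrix
#'
#' Flood-field normalisation flattens the true open-beam profile (the WFF
#' "horns", the FFF cone). This matrix, the reference open-beam profile
#' normalised to 1 at the grid centre, multiplies Eq.-1-corrected images
#' to restore that structure.
#'
#' @param reference_profile_2d Positive `frame_image`: relative open-beam
#'   dose/fluence covering the panel (water-scan data in practice, the
#'   synthetic beam profile in tests).
#' @return `frame_image`, centre-normalised, units `"relative"`.
#' @export
build_profile_matrix <- function(reference_profile_2d) {
  m <- unclass(reference_profile_2d)
  if (any(m <= 0))
    stop("reference profile must be positive everywhere")
  ctr <- centre_value(reference_profile_2d)
  with_pixels(reference_profile_2d, m / ctr, units = "relative")
}

# Mean of the (up to) 2x2 central pixels — exact centre for odd dims,
# midpoint average for even dims.
centre_value <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- if (nr %% 2L) (nr + 1L) %/% 2L else c(nr %/% 2L, nr %/% 2L + 1L)
  ci <- if (nc %% 2L) (nc + 1L) %/% 2L else c(nc %/% 2L, nc %/% 2L + 1L)
  mean(unclass(img)[ri, ci])
}

#' Assemble a correction set
#'
#' Everything needed to turn a raw image into a corrected, profile-true
#' relative image and later into absolute dose: dark field, flood field,
#' beam-profile matrix, dead-pixel mask and the per-mode absolute factors.
#'
#' @param dark,flood `frame_image`s from [build_dark_field()] /
#'   [build_flood_field()].
#' @param profile_matrix From [build_profile_matrix()]; defaults to unity.
#' @param dead_mask Logical matrix; defaults to [detect_dead_pixels()].
#' @param f_abs Named numeric vector/list, absolute calibration factor
#'   (cGy per corrected-dose unit) per energy-mode name. May be empty
#'   until [compute_abs_factor()] has been run.
#' @param mode [energy_mode()] the set was acquired in.
#' @param k_mad Threshold used when `dead_mask` is derived here.
#' @return A `correction_set` object.
#' @export
correction_set <- function(dark, flood, profile_matrix = NULL,
                           dead_mask = NULL, f_abs = list(),
                           mode = NULL, k_mad = 6) {
  stop_geometry(dark, flood, "dark and flood fields")
  if (is.null(dead_mask)) dead_mask <- detect_dead_pixels(dark, flood, k_mad)
  if (is.null(profile_matrix))
    profile_matrix <- with_pixels(dark, matrix(1, nrow(dark), ncol(dark)),
                                  units = "relative")
  stop_geometry(dark, profile_matrix, "dark field and profile matrix")
  if (any(unclass(profile_matrix) <= 0))
    stop("beam_profile_matrix must be positive everywhere")
  live <- !dead_mask
  if (any(unclass(flood)[live] <= 0)) {
    bad <- which(unclass(flood) <= 0 & live, arr.ind = TRUE)[1L, ]
    stop("flood - dark is not positive at live pixel (",
         bad[1L], ", ", bad[2L], ")")
  }
  f_abs <- as.list(f_abs)
  if (length(f_abs) && any(unlist(f_abs) <= 0))
    stop("f_abs values must be positive")
  if (!is.null(mode)) mode <- as_energy_mode(mode)
  structure(
    list(dark = dark, flood = flood, profile_matrix = profile_matrix,
         dead_mask = dead_mask, f_abs = f_abs, mode = mode, k_mad = k_mad),
    class = "correction_set"
  )
}

#' @export
print.correction_set <- function(x, ...) {
  cat(sprintf(
    "<correction_set> %d x %d px @ %.3g mm, %d dead px%s%s\n",
    nrow(x$dark), ncol(x$dark), pitch_mm(x$dark), sum(x$dead_mask),
    if (is.null(x$mode)) "" else paste0(", ", x$mode$name),
    if (length(x$f_abs)) paste0(", F_ABS for ",
                                paste(names(x$f_abs), collapse = "/")) else ""
  ))
  invisible(x)
}

#' Apply the dark/flood pixel correction to a raw image
#'
#' The standard gain/offset correction
#' `corrected = (raw - dark) / (flood - dark)` applied per pixel at live
#' pixels; dead pixels are then filled with the median of their live
#' 8-neighbours (filling after the correction keeps the fill in relative
#' units, free of gain bias).
#'
#' On real hardware the dark field is subtracted from every incoming
#' frame during acquisition; for an image integrated over `n_frames`
#' cine frames the accumulated offset is therefore `n_frames` times the
#' per-frame dark field.
#'
#' @param raw Raw integrated or single-frame `frame_image` (ADU).
#' @param cs A [correction_set()].
#' @param n_frames Number of frames summed into `raw` (default 1; use
#'   the stack length for an integrated delivery).
#' @return `frame_image`, units `"relative"`.
#' @export
correct_raw <- function(raw, cs, n_frames = 1L) {
  stop_geometry(raw, cs$dark, "raw image and correction set")
  num <- unclass(raw) - n_frames * unclass(cs$dark)
  den <- unclass(cs$flood)
  out <- matrix(0, nrow(raw), ncol(raw))
  live <- !cs$dead_mask
  out[live] <- num[live] / den[live]
  if (any(cs$dead_mask))
    out <- fill_dead(out, cs$dead_mask)
  with_pixels(raw, out, units = "relative")
}

# Median of live 8-neighbours; isolated dead pixels only need one pass,
# clustered ones fall back to the map median.
fill_dead <- function(m, dead) {
  idx <- which(dead, arr.ind = TRUE)
  nr <- nrow(m); nc <- ncol(m)
  fallback <- stats::median(m[!dead])
  vals <- numeric(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1L]; c <- idx[i, 2L]
    rr <- max(1L, r - 1L):min(nr, r + 1L)
    cc <- max(1L, c - 1L):min(nc, c + 1L)
    nb <- m[rr, cc]
    ok <- !dead[rr, cc]
    ok[rr == r, cc == c] <- FALSE
    vals[i] <- if (any(ok)) stats::median(nb[ok]) else fallback
  }
  m[idx] <- vals
  m
}

#' Restore the open-beam profile
#'
#' Pixel-wise product of an Eq.-1-corrected image with the beam-profile
#' matrix, undoing the flattening induced by flood normalisation.
#'
#' @param img Corrected `frame_image` (relative units).
#' @param cs A [correction_set()].
#' @return `frame_image`, units `"relative"`.
#' @export
apply_beam_profile_correction <- function(img, cs) {
  stop_geometry(img, cs$profile_matrix, "image and profile matrix")
  with_pixels(img, unclass(img) * unclass(cs$profile_matrix),
              units = "relative")
}

#' Absolute calibration factor
#'
#' `F_ABS = delivered dose / D_EPID` for a reference delivery: a 10 x 10
#' cm2 field, 100 MU (100 cGy at d_max) at 100 cm SDD. `D_EPID` is the
#' central-axis value of the reconstructed relative-dose image of that
#' delivery (mean of the central 5 x 5 pixel region).
#'
#' @param d_epid_reference Relative-dose CAX reading of the reference
#'   delivery (positive scalar).
#' @param delivered_dose_cGy Dose actually delivered (default 100).
#' @return `F_ABS` in cGy per relative-dose unit.
#' @export
compute_abs_factor <- function(d_epid_reference, delivered_dose_cGy = 100) {
  if (!is.numeric(d_epid_reference) || d_epid_reference <= 0)
    stop("d_epid_reference must be a positive scalar")
  if (!is.numeric(delivered_dose_cGy) || delivered_dose_cGy <= 0)
    stop("delivered_dose_cGy must be a positive scalar")
  delivered_dose_cGy / d_epid_reference
}

#' Store / load a correction set
#'
#' On-disk layout: `dark`, `flood`, `profile_matrix` as CSV+JSON grids
#' ([write_frame()]), `dead_mask.csv` (0/1) and `meta.json` holding
#' `energy_mode`, `f_abs` and `k_mad`.
#'
#' @param cs A [correction_set()].
#' @param dir Directory (created if needed).
#' @return `dir` (write) / a `correction_set` (read).
#' @export
write_correction_set <- function(cs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_frame(cs$dark, file.path(dir, "dark"))
  write_frame(cs$flood, file.path(dir, "flood"))
  write_frame(cs$profile_matrix, file.path(dir, "profile_matrix"))
  utils::write.table(cs$dead_mask * 1L, file.path(dir, "dead_mask.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(energy_mode = if (is.null(cs$mode)) NA else cs$mode$name,
         f_abs = cs$f_abs, k_mad = cs$k_mad),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_correction_set
#' @export
read_correction_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  dead <- as.matrix(utils::read.table(file.path(dir, "dead_mask.csv"),
                                      sep = ",", header = FALSE)) > 0
  dimnames(dead) <- NULL
  correction_set(
    dark = read_frame(file.path(dir, "dark")),
    flood = read_frame(file.path(dir, "flood")),
    profile_matrix = read_frame(file.path(dir, "profile_matrix")),
    dead_mask = dead,
    f_abs = as.list(meta$f_abs),
    mode = if (is.na(meta$energy_mode)) NULL else meta$energy_mode,
    k_mad = meta$k_mad
  )
}
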