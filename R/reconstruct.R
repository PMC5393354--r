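#' Deconvolution settings
#'
#' The inverse of the glare convolution is realised as a Wiener-style
#' regularised inverse filter; these settings control its numerics.
#'
#' @param regularization_eps Relative spectral floor in (0, 0.5); the
#'   filter is `conj(K) / (|K|^2 + (eps * max|K|)^2)`. Default 1e-3.
#' @param pad_policy `"reflect"` (default) or `"zero"` padding before the
#'   FFT, so the long glare tails never wrap around.
#' @param pad_width_px Padding width; defaults to (and is never less
#'   than) the kernel half width.
#' @param clip_negative Clip noise-induced negative fluence to 0
#'   (default `TRUE`); the clipped-pixel count is recorded on the result.
#' @return A `deconv_settings` object.
#' @export
deconv_settings <- function(regularization_eps = 1e-3,
                            pad_policy = c("reflect", "zero"),
                            pad_width_px = NULL, clip_negative = TRUE) {
  pad_policy <- match.arg(pad_policy)
  if (regularization_eps <= 0 || regularization_eps >= 0.5)
    stop("regularization_eps must lie in (0, 0.5)")
  structure(list(regularization_eps = regularization_eps,
                 pad_policy = pad_policy, pad_width_px = pad_width_px,
                 clip_negative = clip_negative),
            class = "deconv_settings")
}

#' Reconstruct incident photon fluence from a corrected image
#'
#' Inverts the detector glare convolution: the corrected (and
#' profile-restored) image is deconvolved with the glare kernel in the
#' frequency domain on a padded grid, then cropped back. A sum-normalised
#' kernel has unit DC gain, so flat signals pass through unchanged (up to
#' the regularisation floor).
#'
#' @param img Corrected `frame_image` (relative units).
#' @param k_de Glare [kernel()], sum-normalised, same pitch as `img`.
#' @param settings A [deconv_settings()].
#' @return A `frame_image` tagged `"relative"`: the relative primary
#'   photon fluence. Attribute `n_clipped` counts clipped negatives.
#' @export
deconvolve_fluence <- function(img, k_de, settings = deconv_settings()) {
  check_pitch(img, k_de)
  v <- fft_deconvolve(unclass(img), unclass(k_de),
                      eps = settings$regularization_eps,
                      pad = settings$pad_policy,
                      pad_width = settings$pad_width_px)
  n_clipped <- 0L
  if (settings$clip_negative) {
    n_clipped <- sum(v < 0)
    v[v < 0] <- 0
  }
  out <- with_pixels(img, v, units = "relative")
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Convolve fluence with the pencil-beam kernel to relative water dose
#'
#' Linear (padded frequency-domain) convolution of the fluence map with
#' the water pencil-beam dose kernel: the relative dose distribution in
#' water at the mode's d_max.
#'
#' @param fluence `frame_image` of relative fluence.
#' @param k_pb Pencil-beam [kernel()], sum-normalised, same pitch.
#' @return `frame_image` of relative dose.
#' @export
convolve_dose <- function(fluence, k_pb) {
  check_pitch(fluence, k_pb)
  v <- fft_convolve(unclass(fluence), unclass(k_pb), pad = "zero")
  with_pixels(fluence, v, units = "relative")
}

check_pitch <- function(img, k) {
  if (abs(pitch_mm(img) - pitch_mm(k)) >
        1e-9 * max(pitch_mm(img), pitch_mm(k)))
    stop("pixel pitch mismatch: image ", pitch_mm(img), " mm vs kernel ",
         pitch_mm(k), " mm; use resample_kernel() explicitly")
  invisible(TRUE)
}

#' Absolute dose map
#'
#' Scales a relative dose image by the stored absolute calibration factor
#' for the energy mode, yielding dose in cGy at the mode's d_max.
#'
#' @param rel_dose Relative-dose `frame_image`.
#' @param cs [correction_set()] holding `f_abs` for `mode`.
#' @param mode [energy_mode()] or name.
#' @return A `dose_map`: `frame_image` in cGy with attributes `depth_cm`
#'   and `mode`.
#' @export
to_absolute <- function(rel_dose, cs, mode) {
  mode <- as_energy_mode(mode)
  f <- cs$f_abs[[mode$name]]
  if (is.null(f))
    stop("no absolute factor stored for mode ", mode$name,
         "; run the reference calibration first")
  dose_map(unclass(rel_dose) * f, pitch_mm = pitch_mm(rel_dose),
           mode = mode)
}

#' Construct a dose map
#' @param values Non-negative dose matrix (cGy).
#' @param pitch_mm Grid spacing.
#' @param mode [energy_mode()] or name; sets `depth_cm` to the mode's
#'   d_max.
#' @return A `dose_map` (also a `frame_image`).
#' @export
dose_map <- function(values, pitch_mm, mode) {
  mode <- as_energy_mode(mode)
  img <- frame_image(pmax(as.matrix(values), 0), pitch_mm = pitch_mm,
                     units = "cGy")
  attr(img, "depth_cm") <- mode$d_max_cm
  attr(img, "mode") <- mode
  class(img) <- c("dose_map", class(img))
  img
}

#' @export
print.dose_map <- function(x, ...) {
  cat(sprintf(
    "<dose_map> %d x %d px @ %.3g mm, %s at d_max %.1f cm, max %.4g cGy\n",
    nrow(x), ncol(x), pitch_mm(x), attr(x, "mode")$name,
    attr(x, "depth_cm"), max(x)
  ))
  invisible(x)
}

#' Central-axis value
#'
#' Mean over the central `(2 * roi_px + 1)^2` pixel region; the reading
#' used for absolute calibration and output factors. For even grid
#' dimensions the region is grown by one pixel so it stays centred.
#'
#' @param d `dose_map` or `frame_image`.
#' @param roi_px ROI half width in pixels (default 2, i.e. 5 x 5).
#' @return Scalar mean.
#' @export
cax_value <- function(d, roi_px = 2L) {
  nr <- nrow(d); nc <- ncol(d)
  ri <- centre_indices(nr, roi_px)
  ci <- centre_indices(nc, roi_px)
  if (min(ri) < 1L || max(ri) > nr || min(ci) < 1L || max(ci) > nc)
    stop("CAX ROI (half width ", roi_px, ") does not fit the grid")
  mean(unclass(d)[ri, ci])
}

centre_indices <- function(n, roi) {
  if (n %% 2L) {
    c0 <- (n + 1L) %/% 2L
    (c0 - roi):(c0 + roi)
  } else {
    (n %/% 2L - roi):(n %/% 2L + roi + 1L)
  }
}

#' Output factor
#'
#' CAX dose of a field relative to the 10 x 10 cm2 reference field of the
#' same mode and geometry.
#'
#' @param field_dose,ref_dose `dose_map`s on the same grid.
#' @param roi_px CAX ROI half width (default 2).
#' @return Scalar output factor.
#' @export
output_factor <- function(field_dose, ref_dose, roi_px = 2L) {
  stop_geometry(field_dose, ref_dose, "field and reference dose maps")
  ref <- cax_value(ref_dose, roi_px)
  if (ref <= 0) stop("reference CAX dose is zero")
  cax_value(field_dose, roi_px) / ref
}

#' Run the full image-to-dose chain
#'
#' The canonical order: pixel correction (dark/flood), beam-profile
#' restoration, glare deconvolution to fluence, pencil-beam convolution
#' to relative dose, then (if `f_abs` is stored) absolute calibration.
#'
#' @param stack Raw [cine_stack()] of a delivery.
#' @param cs [correction_set()].
#' @param k_de,k_pb Glare and pencil-beam [kernel()]s.
#' @param mode [energy_mode()] or name.
#' @param settings [deconv_settings()].
#' @param integrate Sum frames (default, the integrated delivery) rather
#'   than average them.
#' @param absolute Apply `f_abs` (default `TRUE` when stored).
#' @return A list with `raw` (integrated image), `corrected`, `fluence`,
#'   `rel_dose` and `dose` (a `dose_map`, or `NULL` when not calibrated).
#' @export
reconstruct_dose <- function(stack, cs, k_de, k_pb, mode,
                             settings = deconv_settings(),
                             integrate = TRUE,
                             absolute = TRUE) {
  mode <- as_energy_mode(mode)
  raw <- if (integrate) integrate_frames(stack) else average_frames(stack)
  corrected <- correct_raw(raw, cs,
                           n_frames = if (integrate) length(stack) else 1L)
  corrected <- apply_beam_profile_correction(corrected, cs)
  fluence <- deconvolve_fluence(corrected, k_de, settings)
  rel <- convolve_dose(fluence, k_pb)
  dose <- NULL
  if (absolute && !is.null(cs$f_abs[[mode$name]]))
    dose <- to_absolute(rel, cs, mode)
  list(raw = raw, corrected = corrected, fluence = fluence,
       rel_dose = rel, dose = dose)
}

#' Calibrate the absolute factor from a reference delivery
#'
#' Processes a reference 10 x 10 cm2 delivery of known dose through the
#' relative chain and stores `F_ABS = delivered / D_EPID` (D_EPID the CAX
#' 5 x 5 reading of the reconstructed relative dose) in the correction
#' set for the given mode.
#'
#' @param stack Reference delivery [cine_stack()].
#' @param cs [correction_set()].
#' @param k_de,k_pb Kernels.
#' @param mode [energy_mode()] or name.
#' @param delivered_dose_cGy Dose of the reference delivery (default 100,
#'   i.e. 100 MU).
#' @param settings [deconv_settings()].
#' @return The updated `correction_set`.
#' @export
calibrate_abs_factor <- function(stack, cs, k_de, k_pb, mode,
                                 delivered_dose_cGy = 100,
                                 settings = deconv_settings()) {
  mode <- as_energy_mode(mode)
  rec <- reconstruct_dose(stack, cs, k_de, k_pb, mode,
                          settings = settings, absolute = FALSE)
  d_epid <- cax_value(rec$rel_dose, roi_px = 2L)
  cs$f_abs[[mode$name]] <- compute_abs_factor(d_epid, delivered_dose_cGy)
  cs
}
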