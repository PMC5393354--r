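#' Representative photon energy spectrum for a beam mode
#'
#' Packaged bremsstrahlung-shaped spectra standing in for spectra derived
#' from treatment-planning-system commissioning data. The shape is
#' `w(E) ~ E * exp(-E / E0)` truncated at the nominal accelerating
#' potential, with `E0` solved so the mean energy is about one third of
#' the nominal energy for flattened (WFF) beams. Filter-free (FFF) beams
#' keep the low-energy photons the flattening filter would absorb, so
#' their target mean is 15% lower (softer) at the same nominal energy.
#'
#' @param mode [energy_mode()] or mode name.
#' @param n_bins Number of energy bins (default 40).
#' @return A `photon_spectrum`: list with `energy_MeV` (ascending bin
#'   centres), `weights` (sum to 1) and `mode`.
#' @export
default_spectrum <- function(mode, n_bins = 40) {
  mode <- as_energy_mode(mode)
  e_max <- mode$nominal_MV
  target_mean <- e_max / 3 * if (mode$has_flattening_filter) 1 else 0.85
  e <- seq(0.05, e_max, length.out = n_bins)
  mean_for <- function(e0) {
    w <- e * exp(-e / e0)
    sum(w * e) / sum(w)
  }
  e0 <- stats::uniroot(function(e0) mean_for(e0) - target_mean,
                       c(0.01, 50))$root
  w <- e * exp(-e / e0)
  photon_spectrum(e, w / sum(w), mode)
}

#' Construct a photon spectrum
#' @param energy_MeV Ascending bin-centre energies, within (0.01, 20) MeV.
#' @param weights Non-negative relative fluence per bin (normalised to 1).
#' @param mode [energy_mode()] or name (optional).
#' @return A `photon_spectrum` object.
#' @export
photon_spectrum <- function(energy_MeV, weights, mode = NULL) {
  if (length(energy_MeV) == 0L) stop("empty spectrum")
  if (is.unsorted(energy_MeV, strictly = TRUE))
    stop("energy bins must be strictly ascending")
  if (any(energy_MeV <= 0.01) || any(energy_MeV >= 20))
    stop("energies must lie within (0.01, 20) MeV")
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative and not all zero")
  if (!is.null(mode)) mode <- as_energy_mode(mode)
  structure(
    list(energy_MeV = as.numeric(energy_MeV),
         weights = as.numeric(weights) / sum(weights),
         mode = mode),
    class = "photon_spectrum"
  )
}

#' Mean energy of a spectrum
#' @param spectrum A `photon_spectrum`.
#' @return Mean energy in MeV.
#' @export
mean_energy <- function(spectrum) {
  sum(spectrum$energy_MeV * spectrum$weights)
}

#' @export
print.photon_spectrum <- function(x, ...) {
  cat(sprintf(
    "<photon_spectrum> %d bins, %.3g-%.3g MeV, mean %.3g MeV%s\n",
    length(x$energy_MeV), min(x$energy_MeV), max(x$energy_MeV),
    mean_energy(x),
    if (is.null(x$mode)) "" else paste0(" [", x$mode$name, "]")
  ))
  invisible(x)
}
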