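# Forward simulator: ground-truth fluence, ground-truth dose and
# realistic raw cine stacks (gain/dark structure, Poisson and read
# noise), so the inverse pipeline is testable end to end with no
# measured data. The detector forward model is deliberately the same
# linear-shift-invariant glare convolution the inverse chain assumes, so
# round-trip tests isolate pipeline correctness; `mismatch_kernel` in
# [simulate_epid_stack()] probes robustness against model error.

#' Field specification
#'
#' @param shape `"square"`, `"rectangle"`, `"circle"` or `"mlc_polygon"`.
#' @param size_cm Side (square), `c(width, height)` (rectangle), diameter
#'   (circle); ignored for polygons.
#' @param vertices_cm For `"mlc_polygon"`: n x 2 matrix of (x, y) cm.
#' @param penumbra_sigma_mm Gaussian edge blur (default 3 mm).
#' @param amplitude Relative fluence scale; encodes monitor units and
#'   output factor (default 1).
#' @param mode [energy_mode()] or name (default `"6MV_WFF"`): selects the
#'   open-beam profile shape.
#' @return A `field_spec` object.
#' @export
field_spec <- function(shape = c("square", "rectangle", "circle",
                                 "mlc_polygon"),
                       size_cm = 10, vertices_cm = NULL,
                       penumbra_sigma_mm = 3, amplitude = 1,
                       mode = "6MV_WFF") {
  shape <- match.arg(shape)
  if (shape != "mlc_polygon" && any(size_cm <= 0))
    stop("field dimensions must be positive")
  if (shape == "square" && (size_cm < 2 || size_cm > 20))
    stop("square field sides must lie in [2, 20] cm for the default panel")
  if (penumbra_sigma_mm <= 0) stop("penumbra_sigma_mm must be positive")
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (shape == "mlc_polygon") {
    vertices_cm <- as.matrix(vertices_cm)
    if (is.null(vertices_cm) || nrow(vertices_cm) < 3L)
      stop("an MLC polygon needs at least 3 vertices")
    if (polygon_self_intersects(vertices_cm))
      stop("MLC polygon is self-intersecting")
  }
  structure(list(shape = shape, size_cm = size_cm,
                 vertices_cm = vertices_cm,
                 penumbra_sigma_mm = penumbra_sigma_mm,
                 amplitude = amplitude, mode = as_energy_mode(mode)),
            class = "field_spec")
}

#' Build an MLC-shaped irregular field
#' @param vertices_cm n x 2 matrix of polygon vertices (x, y) in cm,
#'   simple (non-self-intersecting); rasterised by the even-odd rule.
#' @param ... Passed to [field_spec()] (`penumbra_sigma_mm`, `amplitude`,
#'   `mode`).
#' @return A `field_spec` of shape `"mlc_polygon"`.
#' @export
make_mlc_polygon <- function(vertices_cm, ...) {
  field_spec(shape = "mlc_polygon", vertices_cm = vertices_cm, ...)
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
    (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

polygon_self_intersects <- function(v) {
  n <- nrow(v)
  edges <- cbind(seq_len(n), c(seq_len(n)[-1L], 1L))
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next # shares the closing vertex
      if (segments_intersect(v[edges[i, 1L], ], v[edges[i, 2L], ],
                             v[edges[j, 1L], ], v[edges[j, 2L], ]))
        return(TRUE)
    }
  }
  FALSE
}

# even-odd rule point-in-polygon, vectorised over points
points_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1L]; yi <- v[i, 2L]
    xj <- v[j, 1L]; yj <- v[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Open-beam profile of a mode
#'
#' The radial open-beam shape that flood normalisation removes and the
#' beam-profile matrix restores. Flattened (WFF) beams: a mild radial
#' rise ("horns"), about +4% at 8 cm off axis. Filter-free (FFF) beams:
#' a Gaussian-like radial falloff, about -15% at 8 cm.
#'
#' @param mode [energy_mode()] or name, or `"flat"` for a unit profile.
#' @param pitch_mm,dims Grid geometry (`dims` = `c(rows, cols)` or a
#'   scalar).
#' @param horn_frac WFF horn amplitude at 8 cm (default 0.04).
#' @param fff_drop FFF falloff at 8 cm (default 0.15).
#' @return `frame_image` (relative), value 1 at the centre.
#' @export
beam_profile_2d <- function(mode, pitch_mm, dims, horn_frac = 0.04,
                            fff_drop = 0.15) {
  dims <- rep(as.integer(dims), length.out = 2L)
  r <- radius_grid(pitch_mm, dims)
  if (identical(mode, "flat")) {
    v <- matrix(1, dims[1L], dims[2L])
  } else {
    mode <- as_energy_mode(mode)
    v <- if (mode$has_flattening_filter) {
      1 + horn_frac * (r / 80)^2
    } else {
      exp(log(1 - fff_drop) * (r / 80)^2)
    }
  }
  frame_image(v, pitch_mm = pitch_mm, units = "relative")
}

radius_grid <- function(pitch_mm, dims) {
  x <- grid_positions(dims[1L], pitch_mm)
  y <- grid_positions(dims[2L], pitch_mm)
  sqrt(outer(x^2, y^2, `+`))
}

#' Ground-truth incident fluence of a field
#'
#' Binary aperture at the stated size (rasterised by the even-odd rule
#' for polygons), blurred with the Gaussian penumbra, multiplied by the
#' mode's open-beam profile and scaled by the amplitude.
#'
#' @param spec A [field_spec()].
#' @param pitch_mm,dims Grid geometry.
#' @param profile `"mode"` (default: the spec's mode profile) or
#'   `"flat"`.
#' @return `frame_image` of relative fluence.
#' @export
make_field_fluence <- function(spec, pitch_mm, dims, profile = "mode") {
  dims <- rep(as.integer(dims), length.out = 2L)
  x <- grid_positions(dims[1L], pitch_mm) / 10 # cm
  y <- grid_positions(dims[2L], pitch_mm) / 10
  extent_cm <- c(dims[1L], dims[2L]) * pitch_mm / 10
  ap <- switch(spec$shape,
    square = {
      half <- spec$size_cm / 2
      if (spec$size_cm > min(extent_cm))
        stop("field (", spec$size_cm, " cm) exceeds the grid (",
             paste(round(extent_cm, 1), collapse = " x "), " cm)")
      outer(abs(x) <= half, abs(y) <= half, `&`)
    },
    rectangle = {
      sz <- rep(spec$size_cm, length.out = 2L)
      if (sz[1L] > extent_cm[1L] || sz[2L] > extent_cm[2L])
        stop("field exceeds the grid")
      outer(abs(x) <= sz[1L] / 2, abs(y) <= sz[2L] / 2, `&`)
    },
    circle = {
      if (spec$size_cm > min(extent_cm)) stop("field exceeds the grid")
      radius_grid(pitch_mm, dims) / 10 <= spec$size_cm / 2
    },
    mlc_polygon = {
      v <- spec$vertices_cm
      if (max(abs(v)) > max(extent_cm) / 2) stop("field exceeds the grid")
      pts <- expand.grid(px = x, py = y)
      matrix(points_in_polygon(pts$px, pts$py, v), dims[1L], dims[2L])
    }
  )
  sig_px <- spec$penumbra_sigma_mm / pitch_mm
  half_k <- max(4L, ceiling(4 * sig_px))
  blurred <- fft_convolve(ap * 1.0, gaussian_kernel_px(sig_px, half_k),
                          pad = "zero")
  prof <- if (identical(profile, "flat")) {
    matrix(1, dims[1L], dims[2L])
  } else {
    unclass(beam_profile_2d(spec$mode, pitch_mm, dims))
  }
  frame_image(pmax(blurred, 0) * prof * spec$amplitude,
              pitch_mm = pitch_mm, units = "relative")
}

#' Panel model for the synthetic detector
#'
#' Per-pixel multiplicative gain (mean 1), dark fixed-pattern offset,
#' read noise, an ADU conversion factor and the cine frame count. The
#' defaults emulate a few-percent gain dispersion and a dark level of
#' about 50 ADU, stated as package choices (real panel magnitudes are
#' not published).
#'
#' @param dims Grid `c(rows, cols)` or scalar.
#' @param pitch_mm Pixel pitch.
#' @param gain_sigma Gain map standard deviation (default 0.03).
#' @param dark_level_adu Mean dark level (default 50 ADU).
#' @param dark_sigma_adu Dark fixed-pattern spread (default 5 ADU).
#' @param read_noise_adu Per-frame Gaussian read noise (default 2 ADU).
#' @param conversion ADU per unit incident signal, integrated over a
#'   delivery (default 1e4, i.e. a per-pixel signal-to-noise ratio of
#'   about 100 at unit fluence amplitude).
#' @param n_frames Cine frames per delivery (default 50).
#' @param poisson Apply Poisson counting noise (default `TRUE`).
#' @param seed Seed fixing the gain/dark structure.
#' @return A `panel_model` object.
#' @export
panel_model <- function(dims = 128L, pitch_mm = 1.6, gain_sigma = 0.03,
                        dark_level_adu = 50, dark_sigma_adu = 5,
                        read_noise_adu = 2, conversion = 1e4,
                        n_frames = 50L, poisson = TRUE, seed = 1L) {
  dims <- rep(as.integer(dims), length.out = 2L)
  if (conversion <= 0) stop("conversion must be positive")
  if (n_frames < 1L) stop("n_frames must be at least 1")
  set.seed(seed)
  gain <- matrix(stats::rnorm(prod(dims), 1, gain_sigma), dims[1L])
  gain <- pmax(gain, 0.2)
  dark <- matrix(stats::rnorm(prod(dims), dark_level_adu, dark_sigma_adu),
                 dims[1L])
  dark <- pmax(dark, 0)
  structure(list(dims = dims, pitch_mm = pitch_mm, gain_map = gain,
                 dark_map = dark, read_noise_adu = read_noise_adu,
                 conversion = conversion, n_frames = as.integer(n_frames),
                 poisson = poisson, seed = seed),
            class = "panel_model")
}

#' Simulate a raw cine acquisition of a fluence map
#'
#' Ideal signal `S = fluence (x) K_de`; each frame is
#' `Poisson(S * conversion / n_frames) * gain + dark + read noise`,
#' reproducible under the given seed. With `poisson = FALSE` and zero
#' read noise the frames are exact, which the algebraic round-trip tests
#' rely on.
#'
#' @param fluence `frame_image` of incident fluence.
#' @param k_de Glare [kernel()] (the detector response).
#' @param panel A [panel_model()] with matching geometry.
#' @param seed Per-acquisition RNG seed (default 1).
#' @param mode Optional [energy_mode()] tag for the stack.
#' @param mismatch_kernel Optional second kernel blended in (10%) to
#'   probe model mismatch.
#' @return A [cine_stack()] in ADU.
#' @export
simulate_epid_stack <- function(fluence, k_de, panel, seed = 1L,
                                mode = NULL, mismatch_kernel = NULL) {
  if (!all(dim(fluence) == panel$dims))
    stop("fluence geometry does not match the panel")
  check_pitch(fluence, k_de)
  if (abs(pitch_mm(fluence) - panel$pitch_mm) > 1e-9)
    stop("fluence pitch does not match the panel")
  s <- fft_convolve(unclass(fluence), unclass(k_de), pad = "zero")
  if (!is.null(mismatch_kernel)) {
    s2 <- fft_convolve(unclass(fluence), unclass(mismatch_kernel),
                       pad = "zero")
    s <- 0.9 * s + 0.1 * s2
  }
  s <- pmax(s, 0)
  lambda <- s * panel$conversion / panel$n_frames
  set.seed(seed)
  frames <- lapply(seq_len(panel$n_frames), function(i) {
    counts <- if (panel$poisson) {
      matrix(stats::rpois(length(lambda), lambda), nrow(lambda))
    } else lambda
    px <- counts * panel$gain_map + panel$dark_map
    if (panel$read_noise_adu > 0)
      px <- px + matrix(stats::rnorm(length(px), 0, panel$read_noise_adu),
                        nrow(px))
    frame_image(pmax(px, 0), pitch_mm = panel$pitch_mm, units = "ADU")
  })
  cine_stack(frames, frame_rate_fps = 25, mode = mode)
}

#' Simulate dark and flood calibration acquisitions
#'
#' Dark: beam-off frames (dark fixed pattern plus read noise). Flood: an
#' open beam fully covering the panel, shaped by the mode's open-beam
#' profile, through the same forward model as any delivery.
#'
#' @param panel A [panel_model()].
#' @param k_de Glare [kernel()].
#' @param mode [energy_mode()] or name, or `"flat"` for a flat flood.
#' @param n_frames Calibration frame count (default 300).
#' @param flood_amplitude Fluence amplitude of the flood exposure
#'   (default 25: calibration floods deliver far more signal than a
#'   single reference delivery, so flood noise does not imprint a fixed
#'   pattern on every corrected image).
#' @param seed RNG seed.
#' @return List with `dark` and `flood` [cine_stack()]s.
#' @export
simulate_calibration_stacks <- function(panel, k_de, mode = "6MV_WFF",
                                        n_frames = 300L,
                                        flood_amplitude = 25, seed = 2L) {
  set.seed(seed)
  dark_frames <- lapply(seq_len(n_frames), function(i) {
    px <- panel$dark_map
    if (panel$read_noise_adu > 0)
      px <- px + matrix(stats::rnorm(length(px), 0, panel$read_noise_adu),
                        nrow(px))
    frame_image(pmax(px, 0), pitch_mm = panel$pitch_mm, units = "ADU")
  })
  prof <- if (identical(mode, "flat")) {
    frame_image(matrix(flood_amplitude, panel$dims[1L], panel$dims[2L]),
                pitch_mm = panel$pitch_mm, units = "relative")
  } else {
    p <- beam_profile_2d(mode, panel$pitch_mm, panel$dims)
    with_pixels(p, unclass(p) * flood_amplitude)
  }
  flood_panel <- panel
  flood_panel$n_frames <- as.integer(n_frames)
  flood <- simulate_epid_stack(prof, k_de, flood_panel, seed = seed + 1L,
                               mode = if (identical(mode, "flat")) NULL
                                      else mode)
  list(dark = cine_stack(dark_frames, frame_rate_fps = 25),
       flood = flood)
}

#' Ground-truth dose of a fluence map
#'
#' Truth surface for round-trip and gamma tests: the fluence convolved
#' with the pencil-beam kernel, scaled to absolute dose.
#'
#' @param fluence `frame_image` of incident fluence.
#' @param k_pb Pencil-beam [kernel()].
#' @param dose_per_amplitude cGy per unit convolved-fluence value
#'   (default 1).
#' @param mode [energy_mode()] or name (default the 6 MV WFF plane).
#' @return A `dose_map`.
#' @export
ground_truth_dose <- function(fluence, k_pb, dose_per_amplitude = 1,
                              mode = "6MV_WFF") {
  check_pitch(fluence, k_pb)
  v <- fft_convolve(unclass(fluence), unclass(k_pb), pad = "zero")
  dose_map(v * dose_per_amplitude, pitch_mm = pitch_mm(fluence),
           mode = mode)
}

#' Random multi-segment synthetic plan
#'
#' Emulates the time-integrated composite fluence of a modulated
#' delivery: random rectangular MLC-like segments with random offsets
#' and amplitudes, summed into one composite.
#'
#' @param n_segments Number of segments (>= 1).
#' @param pitch_mm,dims Grid geometry.
#' @param mode [energy_mode()] or name.
#' @param seed RNG seed.
#' @param penumbra_sigma_mm Edge blur per segment (default 3).
#' @return List with `segments` (list of per-segment fluence maps),
#'   `specs` (the generating [field_spec()]s) and `fluence` (the
#'   composite `frame_image`).
#' @export
make_synthetic_plan <- function(n_segments, pitch_mm, dims,
                                mode = "6MV_WFF", seed = 1L,
                                penumbra_sigma_mm = 3) {
  if (n_segments < 1L) stop("n_segments must be at least 1")
  dims <- rep(as.integer(dims), length.out = 2L)
  set.seed(seed)
  extent_cm <- min(dims) * pitch_mm / 10
  segs <- vector("list", n_segments)
  specs <- vector("list", n_segments)
  for (i in seq_len(n_segments)) {
    w <- stats::runif(1, 0.25, 0.6) * extent_cm
    hgt <- stats::runif(1, 0.25, 0.6) * extent_cm
    cx <- stats::runif(1, -0.12, 0.12) * extent_cm
    cy <- stats::runif(1, -0.12, 0.12) * extent_cm
    amp <- stats::runif(1, 0.3, 1)
    v <- rbind(c(cx - w / 2, cy - hgt / 2), c(cx + w / 2, cy - hgt / 2),
               c(cx + w / 2, cy + hgt / 2), c(cx - w / 2, cy + hgt / 2))
    specs[[i]] <- make_mlc_polygon(v, penumbra_sigma_mm = penumbra_sigma_mm,
                                   amplitude = amp, mode = mode)
    segs[[i]] <- make_field_fluence(specs[[i]], pitch_mm, dims)
  }
  comp <- Reduce(`+`, lapply(segs, unclass))
  list(segments = segs, specs = specs,
       fluence = frame_image(comp, pitch_mm = pitch_mm,
                             units = "relative"))
}

#' Solve field amplitudes for target output factors
#'
#' The CAX dose of a field depends on field size through the pencil-beam
#' scatter tails, so a plain amplitude ratio is not an output factor.
#' This solves, per field, the amplitude that makes the ground-truth CAX
#' output factor (relative to the reference field) equal the target.
#'
#' @param sizes_cm Square field sides.
#' @param targets Target output factors, one per size.
#' @param ref_size_cm Reference field side (default 10).
#' @param k_pb Pencil-beam [kernel()].
#' @param pitch_mm,dims Grid geometry.
#' @param penumbra_sigma_mm Edge blur (default 3).
#' @param mode [energy_mode()] or name.
#' @return Tibble with `size_cm`, `target_of`, `amplitude`.
#' @export
solve_field_amplitudes <- function(sizes_cm, targets, ref_size_cm = 10,
                                   k_pb, pitch_mm, dims,
                                   penumbra_sigma_mm = 3,
                                   mode = "6MV_WFF") {
  stopifnot(length(sizes_cm) == length(targets))
  unit_cax <- function(sz) {
    f <- make_field_fluence(
      field_spec("square", sz, penumbra_sigma_mm = penumbra_sigma_mm,
                 amplitude = 1, mode = mode),
      pitch_mm, dims
    )
    cax_value(ground_truth_dose(f, k_pb, mode = mode))
  }
  ref <- unit_cax(ref_size_cm)
  amps <- vapply(seq_along(sizes_cm), function(i) {
    targets[i] * ref / unit_cax(sizes_cm[i])
  }, 0)
  tibble::tibble(size_cm = sizes_cm, target_of = targets,
                 amplitude = amps)
}
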