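# Shared builders for the test suite. Grids are desk-scale stand-ins for
# the 1024 x 1024 / 0.2 mm panel: 128 px at 1.6 mm or 256 px at 0.8 mm
# cover the same 20.48 x 20.48 cm2 active area.

const_stack <- function(values, dims = 16L, pitch = 0.2, rate = 25) {
  frames <- lapply(values, function(v)
    frame_image(matrix(v, dims, dims), pitch_mm = pitch))
  cine_stack(frames, frame_rate_fps = rate)
}

# near-delta glare kernel for cheap tests
tiny_glare <- function(pitch = 1.6, half = 16L, mode = "6MV_WFF") {
  build_glare_kernel(default_glare_params(mode), pitch, half)
}

delta_kernel <- function(pitch = 1.6, half = 8L) {
  v <- matrix(0, 2 * half + 1, 2 * half + 1)
  v[half + 1, half + 1] <- 1
  kernel(v, pitch_mm = pitch, kind = "glare")
}

noiseless_panel <- function(dims = 128L, pitch = 1.6, seed = 5L, ...) {
  panel_model(dims = dims, pitch_mm = pitch, seed = seed,
              poisson = FALSE, read_noise_adu = 0, ...)
}

# cache one Monte Carlo pencil-beam kernel per session
mc_kernel_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_pencil_beam_kernel(
        default_spectrum("6MV_WFF"), cross_section_table(),
        depth_cm = 1.5, pitch_mm = 1.6, half_size_px = 24,
        n_histories = 1e5, seed = 11
      )
    }
    cache
  }
})

# calibrated correction set + kernels on the standard 128 px test panel
standard_rig <- local({
  cache <- NULL
  function(noisy = TRUE) {
    key <- if (noisy) "noisy" else "clean"
    if (is.null(cache)) cache <<- list()
    if (is.null(cache[[key]])) {
      mode <- "6MV_WFF"
      panel <- if (noisy) panel_model(dims = 128, pitch_mm = 1.6, seed = 5)
               else noiseless_panel()
      k_de <- tiny_glare()
      k_pb <- mc_kernel_cached()
      cal <- simulate_calibration_stacks(panel, k_de, mode,
                                         n_frames = 300, seed = 2)
      dark <- build_dark_field(cal$dark)
      flood <- build_flood_field(cal$flood, dark)
      cs <- correction_set(dark, flood,
                           build_profile_matrix(
                             beam_profile_2d(mode, 1.6, 128)),
                           mode = mode)
      f10 <- make_field_fluence(field_spec("square", 10, mode = mode),
                                1.6, 128)
      dpa <- 100 / cax_value(ground_truth_dose(f10, k_pb, mode = mode))
      ref <- simulate_epid_stack(f10, k_de, panel, seed = 31, mode = mode)
      cs <- calibrate_abs_factor(ref, cs, k_de, k_pb, mode, 100)
      cache[[key]] <<- list(mode = mode, panel = panel, k_de = k_de,
                            k_pb = k_pb, cs = cs, f10 = f10,
                            dose_per_amp = dpa)
    }
    cache[[key]]
  }
})

# exhaustive brute-force gamma: every refined-lattice reference point, no
# radius bound, no early termination; its own bilinear interpolation.
brute_force_gamma <- function(eval_dose, ref_dose, crit) {
  ep <- pitch_mm(eval_dose); rp <- pitch_mm(ref_dose)
  k <- max(1L, as.integer(ceiling(ep * crit$interp_factor / rp)))
  h <- ep / k
  radius <- crit$search_radius_factor * crit$dta_mm
  n_ext <- ceiling(radius / h)
  pos_r1 <- (1 - (nrow(eval_dose) + 1) / 2) * ep
  pos_c1 <- (1 - (ncol(eval_dose) + 1) / 2) * ep
  lat_r <- seq(pos_r1 - n_ext * h, by = h,
               length.out = (nrow(eval_dose) - 1L) * k + 2L * n_ext + 1L)
  lat_c <- seq(pos_c1 - n_ext * h, by = h,
               length.out = (ncol(eval_dose) - 1L) * k + 2L * n_ext + 1L)
  rm <- unclass(ref_dose)
  bilin <- function(xm, ym) { # own bilinear, loop-free over lattice
    ri <- xm / rp + (nrow(rm) + 1) / 2
    ci <- ym / rp + (ncol(rm) + 1) / 2
    ok <- ri >= 1 & ri <= nrow(rm) & ci >= 1 & ci <= ncol(rm)
    r0 <- pmin(pmax(floor(ri), 1), nrow(rm) - 1)
    c0 <- pmin(pmax(floor(ci), 1), ncol(rm) - 1)
    fr <- ri - r0; fc <- ci - c0
    v <- rm[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
      rm[cbind(r0 + 1, c0)] * fr * (1 - fc) +
      rm[cbind(r0, c0 + 1)] * (1 - fr) * fc +
      rm[cbind(r0 + 1, c0 + 1)] * fr * fc
    v[!ok] <- NA_real_
    v
  }
  pts <- expand.grid(x = lat_r, y = lat_c)
  ref_vals <- bilin(pts$x, pts$y)
  ref_max <- max(rm)
  dd <- crit$dose_diff_pct / 100 * ref_max
  de <- unclass(eval_dose)
  pe <- (seq_len(nrow(de)) - (nrow(de) + 1) / 2) * ep
  ce <- (seq_len(ncol(de)) - (ncol(de) + 1) / 2) * ep
  gm <- matrix(NA_real_, nrow(de), ncol(de))
  sel <- de > crit$threshold_frac * ref_max
  keep <- !is.na(ref_vals)
  rx <- pts$x[keep]; ry <- pts$y[keep]; rv <- ref_vals[keep]
  for (i in which(sel)) {
    rr <- arrayInd(i, dim(de))
    d2 <- (rx - pe[rr[1]])^2 + (ry - ce[rr[2]])^2
    g2 <- d2 / crit$dta_mm^2 + (de[i] - rv)^2 / dd^2
    gm[i] <- sqrt(min(g2))
  }
  gm
}

# smooth non-negative random dose map (low-pass filtered white noise)
smooth_random_dose <- function(n = 32L, pitch = 2, seed = 1L,
                               mode = "6MV_WFF") {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * n), n)
  g <- outer(stats::dnorm(-4:4, sd = 2), stats::dnorm(-4:4, sd = 2))
  sm <- matrix(0, n, n)
  pad <- 4L
  mp <- matrix(0, n + 2 * pad, n + 2 * pad)
  mp[pad + 1:n, pad + 1:n] <- m
  for (i in 1:n) for (j in 1:n)
    sm[i, j] <- sum(mp[i:(i + 8), j:(j + 8)] * g)
  sm <- sm - min(sm) + 0.2 * (max(sm) - min(sm))
  dose_map(sm / max(sm) * 100, pitch_mm = pitch, mode = mode)
}

gaussian_ref <- function(sigma, half, pitch) {
  x <- (-half:half) * pitch
  g <- exp(-x^2 / (2 * sigma^2))
  m <- outer(g, g)
  m / sum(m)
}

kernel_mid <- function(k) (nrow(k) - 1L) %/% 2L + 1L

# pixels at least margin_mm inside the 50%-of-max field edge
interior_mask <- function(f, margin_mm = 5) {
  m <- unclass(f) > 0.5 * max(f)
  r <- ceiling(margin_mm / pitch_mm(f))
  out <- m
  for (dr in -r:r) for (dc in -r:r) {
    if (dr * dr + dc * dc > r * r) next
    sh <- shift_mat(m, dr, dc)
    out <- out & sh
  }
  out
}

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Poisson counting noise at a stated per-pixel SNR at the maximum
with_noise <- function(img, snr = 100) {
  v <- pmax(unclass(img), 0)
  scale <- snr^2 / max(v)
  noisy <- matrix(stats::rpois(length(v), v * scale) / scale, nrow(v))
  with_pixels(img, noisy)
}
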