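test_that("deconvolution inverts convolution where it should", {
  img <- frame_image(matrix(runif(64 * 64, 1, 3), 64), pitch_mm = 1.6,
                     units = "relative")
  # a discrete delta passes the image through (tiny spectral floor)
  d <- delta_kernel(pitch = 1.6, half = 8)
  out <- deconvolve_fluence(img, d, deconv_settings(1e-9))
  expect_lt(max(abs(unclass(out) - unclass(img))), 1e-9)
  # a flat image is an eigenfunction of a sum-normalised kernel
  flat <- frame_image(matrix(2.5, 64, 64), pitch_mm = 1.6,
                      units = "relative")
  k <- tiny_glare()
  out2 <- deconvolve_fluence(flat, k, deconv_settings(1e-3))
  expect_lt(max(abs(unclass(out2) - 2.5)) / 2.5, 1e-5)
  # noiseless forward-then-inverse round trip on a 10 x 10 cm2 field
  f <- make_field_fluence(field_spec("square", 10), 1.6, 128,
                          profile = "flat")
  blurred <- convolve_dose(f, k)
  rec <- deconvolve_fluence(blurred, k, deconv_settings(1e-3))
  interior <- interior_mask(f, margin_mm = 5)
  err <- abs(unclass(rec) - unclass(f)) / max(f)
  expect_lt(max(err[interior]), 0.01)
  # with Poisson noise at SNR ~ 100 the interior error stays below 3%
  set.seed(8)
  noisy <- with_noise(blurred, snr = 100)
  rec_n <- deconvolve_fluence(noisy, k, deconv_settings(1e-3))
  err_n <- abs(unclass(rec_n) - unclass(f)) / max(f)
  # 1% Poisson noise: 3% is the ~3-sigma band, so it bounds all but the
  # expected statistical outliers
  expect_lt(stats::quantile(err_n[interior], 0.995), 0.03)
  expect_lt(max(err_n[interior]), 0.05)
})

test_that("re-convolving the deconvolved image restores the input", {
  k <- tiny_glare()
  f <- make_field_fluence(field_spec("square", 8), 1.6, 128,
                          profile = "flat")
  img <- convolve_dose(f, k)
  rec <- deconvolve_fluence(img, k,
                            deconv_settings(1e-3, clip_negative = FALSE))
  back <- convolve_dose(rec, k)
  lvl <- unclass(img) > 0.1 * max(img)
  err <- abs(unclass(back) - unclass(img)) / max(img)
  expect_lt(max(err[lvl]), 1e-3)
})

test_that("pencil-beam convolution behaves like a convolution", {
  k <- mc_kernel_cached()
  # a delta fluence reproduces the kernel at the delta position
  m <- matrix(0, 64, 64); m[33, 33] <- 1
  delta_f <- frame_image(m, pitch_mm = 1.6, units = "relative")
  out <- unclass(convolve_dose(delta_f, k))
  h <- (nrow(k) - 1L) %/% 2L
  sub <- out[33 + (-h:h), 33 + (-h:h)]
  expect_lt(max(abs(sub - unclass(k))), 1e-12)
  # constant fluence is preserved (unit DC gain)
  flat <- frame_image(matrix(4, 64, 64), pitch_mm = 1.6,
                      units = "relative")
  # interior far from edges: reflect-free region
  ct <- unclass(convolve_dose(flat, k))[28:37, 28:37]
  expect_lt(max(abs(ct - 4)) / 4, 1e-6)
  # linearity: two disjoint fields convolve to the sum of the parts
  m1 <- matrix(0, 96, 96); m1[20:30, 20:30] <- 1
  m2 <- matrix(0, 96, 96); m2[60:75, 60:75] <- 2
  fi <- function(mm) frame_image(mm, pitch_mm = 1.6, units = "relative")
  both <- unclass(convolve_dose(fi(m1 + m2), k))
  sep <- unclass(convolve_dose(fi(m1), k)) +
    unclass(convolve_dose(fi(m2), k))
  expect_lt(max(abs(both - sep)), 1e-10)
  # total signal is conserved for a field away from the borders
  fin <- matrix(0, 96, 96); fin[37:60, 37:60] <- 1.5
  out2 <- convolve_dose(fi(fin), k)
  expect_lt(abs(sum(out2) - sum(fin)) / sum(fin), 1e-6)
})

test_that("CAX readings and output factors follow their definitions", {
  flat <- dose_map(matrix(7, 33, 33), pitch_mm = 2, mode = "6MV_WFF")
  expect_equal(cax_value(flat), 7)
  m <- matrix(0, 33, 33); m[17, 17] <- 10
  expect_equal(cax_value(dose_map(m, 2, "6MV_WFF"), roi_px = 0L), 10)
  # odd-symmetric gradients cancel in the centred ROI
  g <- outer(1:33, rep(1, 33)) + outer(rep(1, 33), 1:33) # linear ramp
  expect_equal(cax_value(dose_map(g, 2, "6MV_WFF")), g[17, 17])
  expect_equal(output_factor(flat, flat), 1)
  expect_error(cax_value(flat, roi_px = 40), "fit")
})

test_that("absolute scaling applies the stored factor", {
  rel <- frame_image(matrix(80, 16, 16), pitch_mm = 1.6,
                     units = "relative")
  dark <- frame_image(matrix(0, 16, 16), pitch_mm = 1.6)
  flood <- frame_image(matrix(1, 16, 16), pitch_mm = 1.6)
  cs <- correction_set(dark, flood, f_abs = list("10MV_FFF" = 1.25))
  d <- to_absolute(rel, cs, "10MV_FFF")
  expect_equal(cax_value(d), 100)
  expect_equal(attr(d, "depth_cm"), 2.5)
  cs1 <- correction_set(dark, flood, f_abs = list("6MV_WFF" = 1))
  expect_equal(unclass(to_absolute(rel, cs1, "6MV_WFF")),
               unclass(rel), ignore_attr = TRUE)
  expect_error(to_absolute(rel, cs1, "15MV_WFF"), "factor")
})

test_that("the reconstructed dose is linear in delivered signal", {
  rig <- standard_rig(noisy = FALSE)
  st <- simulate_epid_stack(rig$f10, rig$k_de, rig$panel, seed = 41,
                            mode = rig$mode)
  rec1 <- reconstruct_dose(st, rig$cs, rig$k_de, rig$k_pb, rig$mode)
  # scale every frame by alpha: dose scales by alpha (MU linearity)
  alpha <- 0.37
  dark <- rig$cs$dark
  scaled <- cine_stack(lapply(st$frames, function(f)
    with_pixels(f, alpha * (unclass(f) - unclass(dark)) + unclass(dark))),
    frame_rate_fps = st$frame_rate_fps, mode = st$mode)
  rec2 <- reconstruct_dose(scaled, rig$cs, rig$k_de, rig$k_pb, rig$mode)
  expect_lt(max(abs(unclass(rec2$dose) - alpha * unclass(rec1$dose))) /
              max(rec1$dose), 1e-6)
})

test_that("output factors encoded in the generator are recovered", {
  rig <- standard_rig()
  sol <- solve_field_amplitudes(c(4, 10), c(0.95, 1), k_pb = rig$k_pb,
                                pitch_mm = 1.6, dims = 128,
                                mode = rig$mode)
  doses <- lapply(seq_len(nrow(sol)), function(i) {
    f <- make_field_fluence(
      field_spec("square", sol$size_cm[i], amplitude = sol$amplitude[i],
                 mode = rig$mode), 1.6, 128)
    st <- simulate_epid_stack(f, rig$k_de, rig$panel, seed = 50 + i,
                              mode = rig$mode)
    reconstruct_dose(st, rig$cs, rig$k_de, rig$k_pb, rig$mode)$dose
  })
  of <- output_factor(doses[[1]], doses[[2]])
  expect_lt(abs(of - 0.95), 0.01)
})
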