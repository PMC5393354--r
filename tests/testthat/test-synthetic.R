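test_that("generated fields have the stated geometry", {
  # 10 x 10 cm2 square: 50% width within a pixel of 100 mm on both axes
  f <- make_field_fluence(field_spec("square", 10), 1.6, 128,
                          profile = "flat")
  expect_lt(abs(profile_width(extract_profile(f, "inplane", 0)) - 100),
            1.6)
  expect_lt(abs(profile_width(extract_profile(f, "crossplane", 0)) - 100),
            1.6)
  # 2 cm circle: area above 50% close to pi r^2 = pi cm2
  circ <- make_field_fluence(
    field_spec("circle", 2, penumbra_sigma_mm = 2), 1, 128,
    profile = "flat")
  area_cm2 <- sum(unclass(circ) > 0.5 * max(circ)) * (0.1)^2
  expect_lt(abs(area_cm2 - pi) / pi, 0.05)
  # zero amplitude produces a zero map
  z <- make_field_fluence(field_spec("square", 10, amplitude = 0), 1.6,
                          128)
  expect_true(all(unclass(z) == 0))
  expect_error(make_field_fluence(field_spec("square", 18), 1.6, 64),
               "exceeds")
})

test_that("MLC polygons rasterise by the even-odd rule", {
  # a square polygon equals the square field shape
  sq <- make_mlc_polygon(rbind(c(-4, -4), c(4, -4), c(4, 4), c(-4, 4)),
                         penumbra_sigma_mm = 3)
  a <- make_field_fluence(sq, 1.6, 128, profile = "flat")
  b <- make_field_fluence(field_spec("square", 8, penumbra_sigma_mm = 3),
                          1.6, 128, profile = "flat")
  expect_lt(max(abs(unclass(a) - unclass(b))), 1e-9)
  # L-shape: 6x6 minus 3x3 = 27 cm2 (sharp edges, count the aperture)
  lshape <- make_mlc_polygon(
    rbind(c(-3, -3), c(3, -3), c(3, 0), c(0, 0), c(0, 3), c(-3, 3)),
    penumbra_sigma_mm = 0.5)
  fl <- make_field_fluence(lshape, 0.5, 256, profile = "flat")
  area <- sum(unclass(fl) > 0.5 * max(fl)) * 0.05^2
  expect_lt(abs(area - 27) / 27, 0.02)
  expect_error(make_mlc_polygon(rbind(c(0, 0), c(1, 1))), "3 vertices")
  bowtie <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))
  expect_error(make_mlc_polygon(bowtie), "self-intersecting")
})

test_that("the detector forward model is linear and reproducible", {
  k <- tiny_glare()
  panel0 <- noiseless_panel(dims = 64)
  panel0$gain_map <- matrix(1, 64, 64)
  panel0$dark_map <- matrix(0, 64, 64)
  panel0$n_frames <- 1L
  f <- make_field_fluence(field_spec("square", 4), 1.6, 64,
                          profile = "flat")
  st <- simulate_epid_stack(f, k, panel0, seed = 1)
  s <- unclass(convolve_dose(f, k)) # the ideal glare-convolved signal
  expect_lt(max(abs(unclass(st$frames[[1]]) -
                      s * panel0$conversion)), 1e-6)
  # zero fluence, zero noise: frames are exactly the dark pattern
  panel_d <- noiseless_panel(dims = 64)
  z <- frame_image(matrix(0, 64, 64), pitch_mm = 1.6, units = "relative")
  std <- simulate_epid_stack(z, k, panel_d, seed = 1)
  expect_true(all(unclass(std$frames[[3]]) == panel_d$dark_map))
  # linearity in amplitude with noise off
  f2 <- with_pixels(f, unclass(f) * 2.5)
  st2 <- simulate_epid_stack(f2, k, panel0, seed = 1)
  expect_lt(max(abs(unclass(st2$frames[[1]]) -
                      2.5 * unclass(st$frames[[1]]))), 1e-6)
  # identical seeds give bit-identical noisy stacks
  panel_n <- panel_model(dims = 64, pitch_mm = 1.6, seed = 9)
  sa <- simulate_epid_stack(f, k, panel_n, seed = 77)
  sb <- simulate_epid_stack(f, k, panel_n, seed = 77)
  for (i in seq_along(sa$frames))
    expect_identical(unclass(sa$frames[[i]]), unclass(sb$frames[[i]]))
})

test_that("calibration stacks recover the panel structure", {
  k <- tiny_glare()
  panel <- noiseless_panel(dims = 64)
  cal <- simulate_calibration_stacks(panel, k, mode = "flat",
                                     n_frames = 4, seed = 3)
  dark <- build_dark_field(cal$dark)
  expect_true(all(unclass(dark) == panel$dark_map))
  flood <- build_flood_field(cal$flood, dark)
  # noiseless flat flood: flood = gain * amplitude * conversion / n, so
  # the gain map is recovered exactly away from the panel border (the
  # glare convolution loses tail mass over the edge)
  g <- unclass(flood) * 4L / (25 * panel$conversion)
  inner <- 21:44
  expect_lt(max(abs(g - panel$gain_map)[inner, inner]), 1e-9)
  # a fresh flood exposure corrects to 1 within noise at the stated level
  panel_n <- panel_model(dims = 64, pitch_mm = 1.6, seed = 13)
  cal_n <- simulate_calibration_stacks(panel_n, k, mode = "flat",
                                       n_frames = 300, seed = 4)
  dark_n <- build_dark_field(cal_n$dark)
  cs <- correction_set(dark_n, build_flood_field(cal_n$flood, dark_n))
  fresh <- simulate_calibration_stacks(panel_n, k, mode = "flat",
                                       n_frames = 300, seed = 99)$flood
  corr <- correct_raw(integrate_frames(fresh), cs,
                      n_frames = length(fresh))
  dev <- abs(unclass(corr) / stats::median(unclass(corr)) - 1)
  # ~0.3% combined flood noise: 1% is the ~3.5-sigma envelope
  expect_lt(stats::quantile(dev, 0.99), 0.01)
  expect_lt(max(dev), 0.02)
})

test_that("ground-truth dose scales and composes linearly", {
  k <- mc_kernel_cached()
  m <- matrix(0, 64, 64); m[33, 33] <- 1
  d <- ground_truth_dose(frame_image(m, pitch_mm = 1.6,
                                     units = "relative"), k, 7)
  h <- (nrow(k) - 1L) %/% 2L
  expect_equal(unclass(d)[33, 33], 7 * k[h + 1, h + 1],
               tolerance = 1e-12)
  f <- make_field_fluence(field_spec("square", 6), 1.6, 64,
                          profile = "flat")
  d1 <- ground_truth_dose(f, k, 1)
  d3 <- ground_truth_dose(f, k, 3)
  expect_lt(max(abs(unclass(d3) - 3 * unclass(d1))), 1e-9)
})

test_that("synthetic plans compose their segments exactly", {
  plan1 <- make_synthetic_plan(1, 1.6, 128, seed = 5)
  expect_identical(unclass(plan1$fluence), unclass(plan1$segments[[1]]))
  plan <- make_synthetic_plan(7, 1.6, 128, seed = 6)
  expect_length(plan$segments, 7L)
  total <- Reduce(`+`, lapply(plan$segments, unclass))
  expect_identical(unclass(plan$fluence), total)
  # deterministic under the seed
  plan_b <- make_synthetic_plan(7, 1.6, 128, seed = 6)
  expect_identical(unclass(plan$fluence), unclass(plan_b$fluence))
})
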