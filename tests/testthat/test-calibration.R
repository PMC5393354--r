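test_that("dark and flood builders do the stated arithmetic", {
  dark <- build_dark_field(const_stack(rep(50, 5)))
  expect_true(all(unclass(dark) == 50))
  flood <- build_flood_field(const_stack(rep(150, 5)), dark)
  expect_true(all(unclass(flood) == 100))
  # gain-map structure survives exactly in the noiseless case
  set.seed(3)
  g <- matrix(runif(16 * 16, 0.9, 1.1), 16)
  st <- cine_stack(lapply(1:4, function(i) frame_image(g * 100 + 50)))
  fl <- build_flood_field(st, build_dark_field(const_stack(rep(50, 4))))
  expect_equal(unclass(fl), 100 * g, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("Gaussian dark noise averages to the true offset map", {
  set.seed(9)
  truth <- 50
  st <- cine_stack(lapply(1:300, function(i)
    frame_image(matrix(rnorm(64 * 64, truth, 5), 64))))
  dark <- unclass(build_dark_field(st))
  tol <- 5 * 5 / sqrt(300)
  expect_gte(mean(abs(dark - truth) <= tol), 0.99)
})

test_that("pixel correction satisfies the flood/dark identities", {
  dark <- build_dark_field(const_stack(rep(50, 3)))
  flood <- build_flood_field(const_stack(rep(150, 3)), dark)
  cs <- correction_set(dark, flood)
  # a flood exposure corrects to exactly 1, a dark exposure to exactly 0
  flood_exp <- frame_image(matrix(150, 16, 16))
  expect_lt(max(abs(unclass(correct_raw(flood_exp, cs)) - 1)), 1e-9)
  dark_exp <- frame_image(matrix(50, 16, 16))
  expect_lt(max(abs(unclass(correct_raw(dark_exp, cs)))), 1e-9)
  # plain arithmetic: (200 - 50) / 100 = 1.5
  raw <- frame_image(matrix(200, 16, 16))
  expect_equal(unclass(correct_raw(raw, cs))[1, 1], 1.5)
})

test_that("pixel correction is offset- and scale-invariant", {
  set.seed(11)
  raw <- matrix(runif(256, 100, 300), 16)
  dk <- matrix(runif(256, 40, 60), 16)
  gain <- matrix(runif(256, 80, 120), 16)
  cs1 <- correction_set(frame_image(dk), frame_image(gain))
  base <- unclass(correct_raw(frame_image(raw), cs1))
  # add a constant to both raw and dark
  cs2 <- correction_set(frame_image(dk + 17), frame_image(gain))
  shifted <- unclass(correct_raw(frame_image(raw + 17), cs2))
  expect_equal(shifted, base, tolerance = 1e-12)
  # scale numerator and denominator jointly
  cs3 <- correction_set(frame_image(3 * dk), frame_image(3 * gain))
  scaled <- unclass(correct_raw(frame_image(3 * raw), cs3))
  expect_equal(scaled, base, tolerance = 1e-12)
})

test_that("dead pixels are detected and filled from live neighbours", {
  clean_dark <- frame_image(matrix(50, 32, 32))
  clean_flood <- frame_image(matrix(100, 32, 32))
  expect_false(any(detect_dead_pixels(clean_dark, clean_flood)))
  # a zero-gain pixel is always flagged
  fl <- matrix(100, 32, 32); fl[5, 7] <- 0
  mask <- detect_dead_pixels(clean_dark, frame_image(fl))
  expect_true(mask[5, 7])
  expect_equal(sum(mask), 1L)
  # injected outliers in a noisy 256^2 map are recovered exactly
  set.seed(21)
  dk <- matrix(rnorm(256^2, 50, 2), 256)
  fg <- matrix(rnorm(256^2, 100, 2), 256)
  hot <- cbind(sample(256, 10), sample(256, 10))
  fg[hot] <- 500
  mask <- detect_dead_pixels(frame_image(dk), frame_image(fg), k_mad = 6)
  expect_equal(sum(mask), 10L)
  expect_true(all(mask[hot]))
  # the filled value is the local median of live neighbours
  cs <- correction_set(frame_image(matrix(50, 32, 32)),
                       frame_image(fl_live <- {
                         f <- matrix(100, 32, 32); f[5, 7] <- 0; f
                       }))
  raw <- frame_image(matrix(250, 32, 32))
  out <- correct_raw(raw, cs)
  expect_equal(unclass(out)[5, 7], 2) # neighbours are all (250-50)/100
})

centre_val <- function(img) mean(unclass(img)[64:65, 64:65])

test_that("profile matrix restores what flood normalisation removes", {
  # centre-normalisation definition
  flat <- build_profile_matrix(frame_image(matrix(2.5, 16, 16)))
  expect_true(all(abs(unclass(flat) - 1) < 1e-12))
  horn <- beam_profile_2d("6MV_WFF", 1.6, 128, horn_frac = 0.05)
  pm <- build_profile_matrix(horn)
  r80 <- which.min(abs(frame_positions(horn)$row_mm - 80))
  ctr <- which.min(abs(frame_positions(horn)$row_mm))
  expect_equal(unclass(pm)[r80, ctr], 1.05, tolerance = 1e-2)
  # FFF cone: strictly decreasing radially along the axis
  fff <- build_profile_matrix(beam_profile_2d("6MV_FFF", 1.6, 128))
  prof <- extract_profile(fff, "crossplane", 0)
  right <- prof$value[prof$position_mm >= 0]
  expect_true(all(diff(right) < 0))
  # forward round trip: flood acquired under profile P, matrix from P
  mode <- "6MV_WFF"
  k_de <- tiny_glare()
  panel <- noiseless_panel()
  cal <- simulate_calibration_stacks(panel, k_de, mode, n_frames = 5,
                                     seed = 4)
  dark <- build_dark_field(cal$dark)
  cs <- correction_set(dark, build_flood_field(cal$flood, dark),
                       build_profile_matrix(
                         beam_profile_2d(mode, 1.6, 128)))
  # a fresh open-beam exposure corrects to the profile itself
  open_fluence <- beam_profile_2d(mode, 1.6, 128)
  st <- simulate_epid_stack(open_fluence, k_de, panel, seed = 8)
  corr <- apply_beam_profile_correction(
    correct_raw(integrate_frames(st), cs, n_frames = length(st)), cs)
  got <- unclass(corr) / centre_val(corr)
  want <- unclass(open_fluence) / centre_val(open_fluence)
  inner <- 9:120 # clear of the panel border
  expect_lt(max(abs(got[inner, inner] - want[inner, inner]) /
                  want[inner, inner]), 1e-3)
})

test_that("absolute factor is the delivered-to-measured ratio", {
  expect_equal(compute_abs_factor(100, 100), 1)
  expect_equal(compute_abs_factor(80, 100), 1.25)
  expect_error(compute_abs_factor(0, 100), "positive")
})

test_that("correction sets survive a disk round trip", {
  rig <- standard_rig()
  dir <- file.path(tempdir(), "calset")
  write_correction_set(rig$cs, dir)
  back <- read_correction_set(dir)
  expect_equal(unclass(back$dark), unclass(rig$cs$dark),
               tolerance = 1e-15, ignore_attr = TRUE)
  expect_equal(unclass(back$flood), unclass(rig$cs$flood),
               tolerance = 1e-15, ignore_attr = TRUE)
  expect_equal(back$f_abs, rig$cs$f_abs, tolerance = 1e-12)
  expect_identical(back$dead_mask, rig$cs$dead_mask)
  expect_equal(back$mode$name, rig$cs$mode$name)
})
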