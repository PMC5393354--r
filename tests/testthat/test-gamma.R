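test_that("identical distributions give gamma zero everywhere", {
  d <- smooth_random_dose(seed = 4)
  res <- gamma_index(d, d, gamma_criteria(3, 3))
  expect_true(all(res$gamma_map[res$evaluated_mask] < 1e-12))
  expect_equal(res$pass_rate_pct, 100)
  expect_gt(res$n_evaluated, 100)
})

test_that("a uniform +3% offset sits exactly on the 3%/3mm boundary", {
  ref <- smooth_random_dose(seed = 7)
  ev <- dose_map(unclass(ref) * 1.03, pitch_mm = pitch_mm(ref),
                 mode = "6MV_WFF")
  res <- gamma_index(ev, ref, gamma_criteria(3, 3))
  imax <- which.max(unclass(ref))
  expect_equal(res$gamma_map[imax], 1, tolerance = 0.01)
  # a tighter criterion fails part of the high-dose region
  res2 <- gamma_index(ev, ref, gamma_criteria(2, 2))
  expect_lt(res2$pass_rate_pct, 100)
  expect_gte(res$pass_rate_pct, res2$pass_rate_pct)
})

test_that("a pure 3 mm shift passes 3%/3mm in the interior", {
  f <- make_field_fluence(field_spec("square", 8, penumbra_sigma_mm = 4),
                          1, 96, profile = "flat")
  ref <- dose_map(unclass(f) * 100, pitch_mm = 1, mode = "6MV_WFF")
  sh <- unclass(f) * 100
  sh <- rbind(sh[-(1:3), ], matrix(0, 3, ncol(sh))) # exact 3 mm shift
  ev <- dose_map(sh, pitch_mm = 1, mode = "6MV_WFF")
  res <- gamma_index(ev, ref, gamma_criteria(3, 3))
  inner <- interior_mask(ref, margin_mm = 6) & res$evaluated_mask
  expect_true(all(res$gamma_map[inner] <= 1 + 1e-6))
  # at 1%/1mm the shifted penumbra fails
  res2 <- gamma_index(ev, ref, gamma_criteria(1, 1))
  expect_lt(res2$pass_rate_pct, res$pass_rate_pct)
})

test_that("accelerated search equals the exhaustive brute force", {
  for (seed in 1:6) {
    ref <- smooth_random_dose(n = 32, pitch = 2, seed = seed)
    set.seed(100 + seed)
    pert <- unclass(ref) * (1 + rnorm(1024, 0, 0.02)) +
      rnorm(1024, 0, 0.5)
    ev <- dose_map(pmax(pert, 0), pitch_mm = 2, mode = "6MV_WFF")
    crit <- gamma_criteria(3, 3, interp_factor = 2)
    fast <- gamma_index(ev, ref, crit)$gamma_map
    slow <- brute_force_gamma(ev, ref, crit)
    expect_lt(max(abs(fast - slow), na.rm = TRUE), 1e-6)
    expect_identical(is.na(fast), is.na(slow))
  }
})

test_that("gamma is invariant to joint rescaling and nested in criteria", {
  ref <- smooth_random_dose(seed = 12)
  set.seed(55)
  ev <- dose_map(pmax(unclass(ref) + rnorm(1024, 0, 1.5), 0),
                 pitch_mm = pitch_mm(ref), mode = "6MV_WFF")
  g1 <- gamma_index(ev, ref, gamma_criteria(3, 3))
  # joint rescaling: global normalisation makes gamma scale-free
  ev5 <- dose_map(unclass(ev) * 5, pitch_mm = pitch_mm(ref),
                  mode = "6MV_WFF")
  ref5 <- dose_map(unclass(ref) * 5, pitch_mm = pitch_mm(ref),
                   mode = "6MV_WFF")
  g5 <- gamma_index(ev5, ref5, gamma_criteria(3, 3))
  expect_equal(g5$gamma_map, g1$gamma_map, tolerance = 1e-12)
  # nesting across the criteria ladder
  rates <- vapply(list(c(3, 3), c(2, 2), c(1, 1)), function(cr)
    gamma_index(ev, ref, gamma_criteria(cr[1], cr[2]))$pass_rate_pct, 0)
  expect_true(all(diff(rates) <= 0))
})

test_that("coarse reference grids are resampled onto the eval grid", {
  # EPID-like fine eval grid vs a 10 mm array-like reference
  f <- make_field_fluence(field_spec("square", 8, penumbra_sigma_mm = 5),
                          2, 64, profile = "flat")
  fine <- dose_map(unclass(f) * 50, pitch_mm = 2, mode = "6MV_WFF")
  # downsample every 5th pixel to a 10 mm grid
  idx <- seq(3, 64, by = 5)
  coarse <- dose_map(unclass(fine)[idx, idx], pitch_mm = 10,
                     mode = "6MV_WFF")
  res <- gamma_index(fine, coarse, gamma_criteria(3, 3))
  # the flat field interior matches the interpolated reference exactly;
  # residual failures live in the shoulder, where linear interpolation
  # of a 10 mm grid is genuinely lossy
  inner <- interior_mask(fine, margin_mm = 16) & res$evaluated_mask
  expect_true(all(res$gamma_map[inner] <= 1))
  expect_gt(res$pass_rate_pct, 70)
  expect_gt(res$n_evaluated, 1000)
})

test_that("the pass-rate report mirrors the QA table layout", {
  d <- smooth_random_dose(seed = 3)
  rep <- gamma_report(d, d, label = "10 x 10")
  expect_equal(nrow(rep), 3L)
  expect_equal(rep$pass_rate_pct, c(100, 100, 100))
  expect_equal(rep$criterion, c("3%/3mm", "2%/2mm", "1%/1mm"))
  expect_equal(rep$label, rep("10 x 10", 3))
})

test_that("gamma results tidy and summarise cleanly", {
  d <- smooth_random_dose(seed = 9)
  set.seed(2)
  ev <- dose_map(pmax(unclass(d) + rnorm(1024, 0, 1), 0),
                 pitch_mm = pitch_mm(d), mode = "6MV_WFF")
  res <- gamma_index(ev, d, gamma_criteria(2, 2))
  td <- tidy(res)
  expect_equal(nrow(td), 1024L)
  expect_equal(sum(td$evaluated), res$n_evaluated)
  gl <- glance(res)
  expect_equal(gl$pass_rate_pct, res$pass_rate_pct)
  expect_equal(gl$criterion, "2%/2mm")
  expect_gte(gl$max_gamma, gl$mean_gamma)
})
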