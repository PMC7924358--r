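test_that("centerline normalization zeroes the mean and sets C", {
  # constant trace collapses onto the centerline
  p <- normalize_profile(c(1, 1, 1) * 1e-3)
  expect_equal(p$heights, c(0, 0, 0))
  expect_equal(p$c_max, 0)

  # mean 6 um is subtracted; C becomes 14 um
  p2 <- normalize_profile(c(0, 20, 10, -6) * 1e-3)
  expect_equal(p2$heights, (c(0, 20, 10, -6) - 6) * 1e-3)
  expect_equal(p2$c_max, 14e-3)
  expect_lt(abs(mean(p2$heights)), 1e-9)

  # idempotence and shape preservation up to the additive constant
  p3 <- normalize_profile(p2)
  expect_equal(p3$heights, p2$heights)
  expect_equal(diff(p2$heights), diff(c(0, 20, 10, -6) * 1e-3))
})

test_that("surface_profile rejects malformed input", {
  expect_error(surface_profile(0.001, 0), "at least 2")
  expect_error(surface_profile(c(0, 1e-3, 3e-3), c(0, 0, 0)), "uniformly")
  expect_error(surface_profile(c(0, -1e-3), c(0, 0)), "increasing")
})

test_that("period averaging anchors peaks first, averages, normalizes", {
  dx <- 1e-3; period <- 4e-3
  # three peak-first periods: point-wise mean [4,0,0,0], centerline [3,-1,-1,-1]
  trace <- c(2, 0, 0, 0, 4, 0, 0, 0, 6, 0, 0, 0) * 1e-3
  avg <- average_periods(trace, period = period, n_periods = 3, dx = dx)
  expect_equal(avg$heights, c(3, -1, -1, -1) * 1e-3)
  expect_equal(avg$c_max, 3e-3)

  # identical periods reproduce the single (normalized) period
  one <- c(5, 1, 0, 1) * 1e-3
  avg2 <- average_periods(rep(one, 3), period = period, dx = dx)
  expect_equal(avg2$heights, one * 1 - mean(one))

  # a rotated period gives the same output as its peak-first rotation
  rot <- c(0, 1, 5, 1) * 1e-3
  avg3 <- average_periods(rep(rot, 3), period = period, dx = dx)
  expect_equal(avg3$heights, avg2$heights)

  expect_error(average_periods(one, period = period, dx = dx), "periods")
})

test_that("tiling repeats the period across the crevice length", {
  prof <- generate_fixture_profile("triangle", period = 0.27,
                                   amplitude = 0.015)
  tiled <- tile_profile(prof, 13)
  # 13 mm / 0.27 mm = 48 full periods plus a partial one
  expect_equal(length(tiled$positions), 13001L)
  expect_equal(max(tiled$positions), 13)
  # periodicity: sample at x and x + period agree
  m <- round(0.27 / prof$dx)
  expect_equal(tiled$heights[seq_len(13001L - m)],
               tiled$heights[seq_len(13001L - m) + m])
  # tiling to exactly one period is the identity on the heights
  one <- tile_profile(prof, 0.27)
  expect_equal(one$heights[seq_len(m)], prof$heights)
})

test_that("gap construction follows the mismatch-plus-roughness rule", {
  geo <- ref_geometry()
  gp <- build_gap_profile(geo, flat_profile())

  # nominal mouth aperture tan(0.02 deg) * 13 mm = 4.54 um
  expect_equal(gp$gap[1] * 1000, tan(0.02 * pi / 180) * 13 * 1000,
               tolerance = 1e-12)
  expect_equal(gp$gap[1] * 1000, 4.538, tolerance = 1e-3)

  # apex contact: at x = L the flat-profile gap clamps to the floor
  expect_equal(gp$gap[length(gp$gap)], geo$gap_floor)
  expect_true(all(gp$gap >= geo$gap_floor))

  # affine decrease with slope -tan(alpha) until clamped
  un <- !gp$clamped
  expect_true(all(diff(gp$gap[un]) < 0))
  expect_equal(diff(gp$gap[un]),
               rep(-tan(0.02 * pi / 180) * geo$dx, sum(un) - 1L))

  # direct substitution: at a roughness peak (y_p = C) the gap is the
  # bare cone term tan(alpha) * (L - x)
  tri <- generate_fixture_profile("triangle", amplitude = 0.015)
  gp2 <- build_gap_profile(geo, tri)
  x0 <- 6.48  # a peak: 24 full periods from the mouth
  i0 <- which(abs(gp2$x - x0) < 1e-9)
  expect_equal(gp2$gap[i0], tan(0.02 * pi / 180) * (13 - x0),
               tolerance = 1e-9)
})

test_that("gap is invariant to pre-normalization offsets and scales with heights", {
  geo <- ref_geometry()
  raw <- generate_fixture_profile("jitter", seed = 42)$heights
  g1 <- build_gap_profile(geo, normalize_profile(raw, period = 0.27))
  g2 <- build_gap_profile(geo, normalize_profile(raw + 5e-3, period = 0.27))
  expect_equal(g1$gap, g2$gap)

  # scaling heights by s scales (y_g - cone term) by s
  s <- 0.2
  prof <- normalize_profile(raw, period = 0.27)
  gs <- build_gap_profile(geo, scale_profile(prof, s))
  cone <- tan(geo$alpha * pi / 180) * (13 - g1$x)
  un <- !g1$clamped & !gs$clamped
  expect_equal(gs$gap[un] - cone[un], s * (g1$gap[un] - cone[un]),
               tolerance = 1e-9)
})

test_that("profile files round-trip through the two-column reader", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# units: um", "# position height",
               "0 10", "1 -5", "2 3", "3 -8"), path)
  p <- read_profile_file(path, period = 4e-3)
  expect_equal(p$positions, c(0, 1, 2, 3) * 1e-3)
  expect_equal(p$heights, c(10, -5, 3, -8) * 1e-3)

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# units: mm", "0,0.010", "0.001,-0.005"), path2)
  p2 <- read_profile_file(path2)
  expect_equal(p2$heights, c(0.010, -0.005))
  expect_error(read_profile_file(withr::local_tempfile()), "not found")
})
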