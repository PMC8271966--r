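test_that("perturbative PA amplitude is linear and respects geometry", {
  nfr <- array(1, dim = c(20, 20, 20))
  nfr[, , 1:5] <- 0 # a zero-fluence layer
  fl <- fake_fluence(nfr, voxel = 0.5)
  ab <- absorber_spec("inclusion", diameter = 2, position = c(0, 0, 1),
                      mu_a_absorber = 10)
  expect_equal(pa_amplitude_at(fl, ab), 0) # sits in the zero-fluence layer
  ab2 <- absorber_spec("inclusion", diameter = 2, position = c(0, 0, 7),
                       mu_a_absorber = 10)
  a1 <- pa_amplitude_at(fl, ab2)
  ab3 <- ab2; ab3$mu_a_absorber <- 20
  expect_equal(pa_amplitude_at(fl, ab3), 2 * a1) # linear in mu_a
  expect_equal(pa_amplitude_at(fl, ab2, gamma = 3), 3 * a1) # linear in gamma
  out <- absorber_spec("inclusion", diameter = 1, position = c(50, 50, 50))
  expect_error(pa_amplitude_at(fl, out), "outside")
})

test_that("voxelized tube cross-section matches the analytic area", {
  g <- voxel_grid(c(10, 10, 10), 0.1,
                  regions = list(m = optical_properties(0.1, 10)))
  tube <- absorber_spec("tube", diameter = 1, position = c(0, 0, 5),
                        orientation = c(0, 1, 0), length = 4)
  mask <- absorber_voxels(g, tube)
  # per-slice cross-section area vs pi r^2, within one voxel layer around
  # the circumference
  ny <- dim(mask)[2]
  areas <- vapply(seq_len(ny), function(j) sum(mask[, j, ]) * 0.1^2, numeric(1))
  areas <- areas[areas > 0]
  expect_true(all(abs(areas - pi * 0.5^2) < 2 * pi * 0.5 * 0.1))
  # total length matches the requested 4 mm
  expect_equal(length(areas) * 0.1, 4, tolerance = 0.1)
})

test_that("field map normalizes to 0 dB and keeps lateral symmetry", {
  # synthetic fluence with a separable, laterally symmetric pattern
  nx <- 41
  x <- seq(-10, 10, length.out = nx)
  lat <- exp(-x^2 / 18)
  zprof <- exp(-(1:30) / 8)
  nfr <- array(outer(outer(lat, lat), zprof), dim = c(nx, nx, 30))
  fl <- fake_fluence(nfr, voxel = 0.5)
  probe <- absorber_spec("line", diameter = 0.8, length = 2)
  map <- field_map(fl$grid, annular_layout(4), probe,
                   lateral_positions = seq(-6, 6, by = 2),
                   depths = c(2, 5, 8), fluence = fl)
  expect_equal(max(map$amplitude_db), 0)
  expect_true(all(map$amplitude_db <= 0))
  # symmetric lateral offsets give equal amplitude
  j <- seq_along(map$lateral_positions)
  expect_equal(map$amplitude_db[, j], map$amplitude_db[, rev(j)],
               tolerance = 1e-9)
  one <- field_map(fl$grid, annular_layout(4), probe,
                   lateral_positions = 0, depths = 5, fluence = fl)
  expect_equal(as.vector(one$amplitude_db), 0) # self-normalization
})

test_that("penetration depth recovers the closed form for an exponential map", {
  depths <- seq(0.2, 14, by = 0.2)
  amp <- exp(-depths) # A(z) = e^-z -> -20 dB at z = ln(10)
  map <- structure(list(lateral_positions = 0, depths = depths,
                        amplitude_db = matrix(20 * log10(amp / max(amp)),
                                              ncol = 1),
                        amplitude = matrix(amp, ncol = 1), gamma = 1),
                   class = "pa_field_map")
  # the map is normalized to its maximum (the first sampled depth), so the
  # -20 dB point sits ln(10) beyond it
  d20 <- penetration_depth(map, -20)
  expect_equal(as.numeric(d20), depths[1] + log(10), tolerance = 1e-3)
  expect_true(attr(d20, "crossed"))
  # 0 dB threshold is the on-axis maximum location
  expect_error(penetration_depth(map, 0), "threshold_db")
  d0 <- penetration_depth(map, -1e-9)
  expect_equal(as.numeric(d0), depths[1], tolerance = 0.2)
  # threshold never crossed -> max depth with a flag
  dflag <- penetration_depth(map, -200)
  expect_equal(as.numeric(dflag), max(depths))
  expect_false(attr(dflag, "crossed"))
})

test_that("field width is exact on a dB-linear ramp fixture", {
  lat <- seq(-10, 10, by = 1)
  prof_db <- -abs(lat) * 5 # linear ramp: -35 dB at |x| = 7
  map <- structure(list(lateral_positions = lat, depths = 3,
                        amplitude_db = matrix(prof_db, nrow = 1),
                        amplitude = matrix(10^(prof_db / 20), nrow = 1),
                        gamma = 1),
                   class = "pa_field_map")
  w <- field_width(map, -35, depth = 3)
  expect_equal(as.numeric(w), 14, tolerance = 1e-9)
  expect_true(attr(w, "crossed"))
  expect_error(field_width(map, -35, depth = 4), "sampled")
})

test_that("field map CSV export is long-format and complete", {
  path <- withr::local_tempfile(fileext = ".csv")
  map <- structure(list(lateral_positions = c(-1, 0, 1), depths = c(1, 2),
                        amplitude_db = matrix(c(-3, -1, 0, -2, -4, -6), 2, 3),
                        amplitude = matrix(1, 2, 3), gamma = 1),
                   class = "pa_field_map")
  write_field_csv(map, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 6L)
  expect_named(df, c("lateral_mm", "depth_mm", "amplitude_db"))
})
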