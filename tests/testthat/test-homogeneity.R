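test_that("NFR_rel matches a brute-force reference on a hand-built volume", {
  set.seed(21)
  nfr <- array(runif(5 * 5 * 3), dim = c(5, 5, 3))
  fl <- fake_fluence(nfr)
  prof <- nfr_rel_profile(fl, roi_side = 3) # 3x3 ROI centered in 5x5
  # independent elementwise computation
  for (k in 1:3) {
    sl <- nfr[, , k]
    expect_equal(prof$nfr_rel_pct[k], 100 * mean(sl[2:4, 2:4]) / max(sl))
  }
  expect_equal(prof$depth_mm, c(0.5, 1.5, 2.5))
})

test_that("uniform slices score 100% and a hot voxel outside the ROI scores ~0%", {
  u <- array(1, dim = c(9, 9, 2))
  expect_equal(nfr_rel_profile(fake_fluence(u), roi_side = 3)$nfr_rel_pct,
               c(100, 100))
  h <- array(0, dim = c(9, 9, 1))
  h[1, 1, 1] <- 5
  expect_equal(nfr_rel_profile(fake_fluence(h), roi_side = 3)$nfr_rel_pct, 0)
})

test_that("NFR_rel is invariant to rescaling the fluence volume", {
  set.seed(4)
  nfr <- array(runif(6 * 6 * 4), dim = c(6, 6, 4))
  p1 <- nfr_rel_profile(fake_fluence(nfr), roi_side = 2)
  p2 <- nfr_rel_profile(fake_fluence(nfr * 17.3), roi_side = 2)
  expect_equal(p1$nfr_rel_pct, p2$nfr_rel_pct, tolerance = 1e-12)
})

test_that("all-zero and zero-max slices are handled as specified", {
  z <- array(0, dim = c(4, 4, 2))
  expect_error(nfr_rel_profile(fake_fluence(z)), "zero")
  mix <- array(0, dim = c(4, 4, 3))
  mix[, , 1] <- 1
  expect_warning(p <- nfr_rel_profile(fake_fluence(mix), roi_side = 2),
                 "dropped")
  expect_equal(nrow(p), 1L)
})

test_that("ROI snaps to voxel alignment and records the effective side", {
  u <- array(1, dim = c(8, 8, 1))
  p <- nfr_rel_profile(fake_fluence(u, voxel = 0.5), roi_side = 1.96)
  expect_equal(attr(p, "roi_side_effective"), 2) # 4 voxels of 0.5 mm
})

test_that("optimal depth takes the binned argmax with shallow tie-breaking", {
  # strictly decreasing profile -> first retained bin
  fl <- fake_fluence(array(rep(c(9:1), each = 25), dim = c(5, 5, 9)) *
                       array(runif(225, 0.99, 1), dim = c(5, 5, 9)))
  prof <- nfr_rel_profile(fl, roi_side = 3)
  prof$nfr_rel_pct <- seq(90, 10, length.out = 9) # decreasing by construction
  expect_equal(optimal_depth(prof, z_min = 0, bin_width = 1),
               min(bin_profile(prof, bin_width = 1, z_min = 0)$depth_mm))
  # tie broken toward the shallower depth
  prof$nfr_rel_pct <- c(50, 80, 80, 50, 50, 50, 50, 50, 50)
  expect_equal(optimal_depth(prof, z_min = 0, bin_width = 1),
               optimal_depth(prof[c(2, 1, 3:9), ], z_min = 0, bin_width = 1))
})

test_that("profile binning averages within bins and honours z_min", {
  d <- data.frame(depth_mm = seq(0.05, 1.15, by = 0.1),
                  nfr_rel_pct = 1:12)
  class(d) <- c("depth_profile", "data.frame")
  b <- bin_profile(d, bin_width = 0.25, z_min = 0.1)
  expect_true(all(b$depth_mm %in% seq(0, 1.25, by = 0.25)))
  # slices below z_min are excluded
  expect_false(any(abs(b$depth_mm) < 1e-9 & b$nfr_rel_pct == 1))
})

test_that("a single off-axis fiber still yields a usable profile", {
  g <- voxel_grid(c(4, 4, 3), 0.1,
                  regions = list(liver = liver_optical_properties("native", 650)))
  fl <- simulate_fluence(g, annular_layout(1), 2000, seed = 2)
  p <- nfr_rel_profile(fl)
  expect_true(all(p$nfr_rel_pct >= 0 & p$nfr_rel_pct <= 100))
  expect_true(is.numeric(optimal_depth(p)))
})

test_that("profile sweep returns tidy labelled profiles", {
  g <- voxel_grid(c(4, 4, 3), 0.1,
                  regions = list(liver = liver_optical_properties("native", 650)))
  tidy <- profile_sweep(g, c(4, 16), photons_per_fiber = 800, seed = 5)
  expect_setequal(unique(tidy$config_label), c("4 fibers", "16 fibers"))
  expect_true(all(c("depth_mm", "nfr_rel_pct", "config_label", "seed") %in%
                    names(tidy)))
  profs <- attr(tidy, "profiles")
  expect_length(profs, 2L)
  expect_s3_class(profs[["4"]], "depth_profile")
})
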