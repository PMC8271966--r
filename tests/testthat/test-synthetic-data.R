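test_that("liquid phantom builds a homogeneous grid with the requested optics", {
  g <- liquid_phantom(0.1, 10)
  expect_s3_class(g, "voxel_grid")
  expect_equal(g$regions$phantom$mu_a, 0.1)
  expect_equal(g$regions$phantom$mu_s_prime, 10)
  expect_equal(g$regions$phantom$g, 0.7)
  expect_true(all(g$region_map == 1L))
  g2 <- liquid_phantom(0.5, 10)
  expect_equal(g2$regions$phantom$mu_a, 0.5)
  free <- liquid_phantom(0, 0, extent = c(2, 2, 2), voxel_size = 0.5)
  expect_equal(free$regions$phantom$mu_s_prime, 0)
})

test_that("layered scenes stack layers and carve inclusions", {
  chicken <- optical_properties(0.1, 10, g = 0.9, label = "chicken")
  liver <- liver_optical_properties("native", 650)
  blood <- optical_properties(4, 10, g = 0.95, label = "blood")
  spec <- scene_spec("test",
    layers = list(list(label = "chicken", thickness = 4, props = chicken),
                  list(label = "liver", thickness = 6, props = liver)),
    inclusions = list(list(
      absorber = absorber_spec("tube", diameter = 1, position = c(0, 0, 7),
                               orientation = c(0, 1, 0), length = 8,
                               label = "tube"),
      props = blood)),
    extent_lateral = c(10, 10), voxel_size = 0.2)
  out <- layered_scene(spec)
  g <- out$grid
  expect_equal(g$dim, c(50L, 50L, 50L))
  expect_named(g$regions, c("chicken", "liver", "tube"))
  # layer assignment: z < 4 mm chicken (1), z > 4 mm liver (2) except tube (3)
  expect_true(all(g$region_map[, , 1:19] == 1L))
  expect_true(all(g$region_map[, , 22:28] %in% c(2L, 3L)))
  expect_true(any(g$region_map == 3L))
  expect_named(out$absorbers, "tube")
})

test_that("zero-inclusion scenes are homogeneous per layer and bad inclusions error", {
  chicken <- optical_properties(0.1, 10, g = 0.9)
  spec <- scene_spec("plain",
    layers = list(list(label = "chicken", thickness = 5, props = chicken)),
    extent_lateral = c(10, 10), voxel_size = 0.5)
  out <- layered_scene(spec)
  expect_equal(sort(unique(as.vector(out$grid$region_map))), 1L)
  bad <- scene_spec("bad",
    layers = list(list(label = "chicken", thickness = 5, props = chicken)),
    inclusions = list(list(
      absorber = absorber_spec("inclusion", diameter = 1,
                               position = c(50, 50, 50), label = "far"),
      props = chicken)),
    extent_lateral = c(10, 10), voxel_size = 0.5)
  expect_error(layered_scene(bad), "outside")
})

test_that("slab-depth scenes differ only in absorber depth", {
  s15 <- scene_library("slab_depth", slab_depth_mm = 15)
  s32 <- scene_library("slab_depth", slab_depth_mm = 32)
  expect_identical(s15$grid$region_map, s32$grid$region_map)
  expect_equal(s15$absorbers$slab$position[3], 15)
  expect_equal(s32$absorbers$slab$position[3], 32)
  expect_error(scene_library("slab_depth", slab_depth_mm = 20), "15 or 32")
})

test_that("the scene library covers every experimental configuration", {
  for (nm in c("liquid_line", "slab_depth", "tines", "blood_tube", "tumor",
               "ablation")) {
    out <- scene_library(nm)
    expect_s3_class(out$grid, "voxel_grid")
    expect_true(all(vapply(out$grid$regions, inherits, logical(1),
                           "optical_properties")))
  }
  # scene-specific structure
  expect_named(scene_library("blood_tube")$absorbers, "blood_tube")
  expect_true("lesion" %in% names(scene_library("ablation")$grid$regions))
  expect_length(scene_library("tines")$absorbers, 3L)
})

test_that("synthetic PA images honour their construction contrast", {
  # zero noise: exact recovery
  fix0 <- synthetic_pa_image(
    list(list(shape = "disc", center = c(32, 32), radius = 8,
              contrast_db = 20, label = "t")),
    dims = c(64, 64), noise_sigma = 0, seed = 1)
  res0 <- snr_db(image_roi(fix0$image, fix0$masks$t, fix0$background_mask),
                 seed = 1)
  expect_equal(res0$mean_db, 20, tolerance = 1e-9)
  # mild noise at the blood-like contrast: within 1 dB
  fix1 <- synthetic_pa_image(
    list(list(shape = "rect", rows = 20:44, cols = 20:44,
              contrast_db = 12.2, label = "blood")),
    dims = c(64, 64), noise_sigma = 0.1, seed = 2)
  res1 <- snr_db(image_roi(fix1$image, fix1$masks$blood, fix1$background_mask),
                 seed = 1)
  expect_lt(abs(res1$mean_db - 12.2), 1)
  # two structures at different contrasts are ordered accordingly
  fix2 <- synthetic_pa_image(
    list(list(shape = "rect", rows = 5:15, cols = 5:15, contrast_db = 18,
              label = "hi"),
         list(shape = "rect", rows = 40:50, cols = 40:50, contrast_db = 8,
              label = "lo")),
    dims = c(64, 64), noise_sigma = 0.05, seed = 3)
  hi <- snr_db(image_roi(fix2$image, fix2$masks$hi, fix2$background_mask),
               seed = 1)$mean_db
  lo <- snr_db(image_roi(fix2$image, fix2$masks$lo, fix2$background_mask),
               seed = 1)$mean_db
  expect_gt(hi, lo)
})

test_that("synthetic images are reproducible from (spec, seed)", {
  s <- list(list(shape = "disc", center = c(20, 20), radius = 5,
                 contrast_db = 15, label = "t"))
  a <- synthetic_pa_image(s, dims = c(48, 48), seed = 9)
  b <- synthetic_pa_image(s, dims = c(48, 48), seed = 9)
  expect_identical(a$image, b$image)
  c <- synthetic_pa_image(s, dims = c(48, 48), seed = 10)
  expect_false(identical(a$image, c$image))
})
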