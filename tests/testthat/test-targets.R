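test_that("density maps carry unit mass per interior point", {
  # empty annotation set: all-zero map
  d0 <- generate_density_map(point_annotations("e", NULL, c(64, 64)))
  expect_equal(dim(d0), c(64, 64))
  expect_identical(density_mass(d0), 0)

  # single centred point: discretely normalised kernel has mass exactly 1
  d1 <- generate_density_map(
    point_annotations("c", data.frame(x = 32, y = 32), c(64, 64)))
  expect_equal(density_mass(d1), 1, tolerance = 1e-6)

  # seven interior points vs brute-force kernel summation oracle
  set.seed(31)
  pts <- data.frame(x = runif(7, 16, 111), y = runif(7, 16, 111))
  d7 <- generate_density_map(point_annotations("s", pts, c(128, 128)))
  expect_equal(density_mass(d7), 7, tolerance = 1e-5)
  expect_equal(unclass(d7), oracle_density(pts, 128, 128),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("border kernels are clipped without renormalisation", {
  d <- generate_density_map(
    point_annotations("b", data.frame(x = 0, y = 0), c(64, 64)))
  # roughly three quadrants of the kernel fall outside the frame
  expect_lt(density_mass(d), 0.35)
  expect_gt(density_mass(d), 0.20)
})

test_that("point outside bounds and bad configs are rejected", {
  expect_error(point_annotations("x", data.frame(x = 64, y = 2), c(64, 64)),
               "annotation-error")
  expect_error(gen_config(sigma = 0), "config-error")
  expect_error(gen_config(truncation_radius = 2), "config-error")
  expect_error(downsample_density(matrix(0, 8, 8), 0), "config-error")
})

test_that("adaptive bandwidth mode shrinks kernels in crowded regions", {
  pts <- data.frame(x = c(60, 62, 64, 100), y = c(60, 62, 64, 100))
  d <- generate_density_map(point_annotations("a", pts, c(128, 128)),
                            gen_config(adaptive = TRUE))
  # the isolated point gets a wide kernel that clips at the border, so a
  # little mass is legitimately lost
  expect_lte(density_mass(d), 4 + 1e-9)
  expect_gt(density_mass(d), 3.5)
  # the isolated point's kernel is wider: lower peak than the crowded ones
  expect_lt(max(unclass(d)[95:105, 95:105]), max(unclass(d)[55:70, 55:70]))
})

test_that("sum-pooling downsampling preserves mass and matches block sums", {
  z <- downsample_density(matrix(0, 32, 32), 8)
  expect_equal(dim(z), c(4, 4))
  expect_identical(density_mass(z), 0)

  one <- downsample_density(matrix(1, 8, 8), 8)
  expect_equal(unclass(one), matrix(64, 1, 1), ignore_attr = TRUE)

  set.seed(7)
  m <- random_density_matrix(64, 64)
  dn <- downsample_density(density_map(m), 8)
  expect_equal(unclass(dn), oracle_blocksum(m, 8), ignore_attr = TRUE)
  expect_equal(density_mass(dn), sum(m), tolerance = 1e-9)
  expect_identical(attr(dn, "resolution_divisor"), 8L)

  # non-divisible shapes are zero-padded bottom/right: mass still exact
  m2 <- random_density_matrix(50, 61)
  dn2 <- downsample_density(density_map(m2), 8)
  expect_equal(dim(dn2), c(7, 8))
  expect_equal(density_mass(dn2), sum(m2), tolerance = 1e-9)
})

test_that("segmentation target thresholds strictly and monotonically", {
  expect_equal(unclass(make_segmentation_target(matrix(0, 4, 4))),
               matrix(0, 4, 4), ignore_attr = TRUE)
  # a value exactly at the threshold is background (strict inequality)
  m <- matrix(c(1e-3, 2e-3, 0, 5), 2, 2)
  s <- make_segmentation_target(m, 1e-3)
  expect_equal(as.numeric(unclass(s)), c(0, 1, 0, 1))

  set.seed(12)
  r <- random_density_matrix(16, 16, scale = 3e-3)
  s1 <- unclass(make_segmentation_target(r, 1e-3))
  expect_equal(s1, (r > 1e-3) * 1, ignore_attr = TRUE)
  # idempotent under re-thresholding, monotone in epsilon
  expect_equal(unclass(make_segmentation_target(s1, 1e-3)), (s1 > 1e-3) * 1,
               ignore_attr = TRUE)
  s2 <- unclass(make_segmentation_target(r, 2e-3))
  expect_true(all(s2 <= s1))
})

test_that("tiling partitions the scene and conserves density mass", {
  set.seed(9)
  scene <- generate_scene(scene_config(image_size = c(896L, 896L),
                                       n_objects = 40L, seed = 9L), "sc")
  tiles <- tile_scene(scene$image, scene$ann, tile_size = 448L)
  expect_length(tiles, 4L)

  full <- generate_density_map(scene$ann)
  tile_mass <- sum(vapply(tiles, function(t) density_mass(t$density), 0))
  expect_equal(tile_mass, density_mass(full), tolerance = 1e-6)
  # each point lands in exactly one tile
  expect_identical(sum(vapply(tiles, function(t) n_points(t$ann), 0L)), 40L)

  # zero-point scene: all tiles empty
  empty <- generate_scene(scene_config(image_size = c(896L, 896L),
                                       n_objects = 0L, seed = 2L), "e")
  tiles0 <- tile_scene(empty$image, empty$ann, tile_size = 448L)
  expect_true(all(vapply(tiles0, function(t) n_points(t$ann) == 0L, TRUE)))
  expect_true(all(vapply(tiles0, function(t) density_mass(t$density) == 0, TRUE)))
})

test_that("tile-local annotations reproduce the scene density per tile", {
  set.seed(21)
  scene <- generate_scene(scene_config(image_size = c(160L, 224L),
                                       n_objects = 25L, seed = 21L), "sc")
  expect_warning(tiles <- tile_scene(scene$image, scene$ann, tile_size = 448L),
                 "padded")
  expect_length(tiles, 1L)
  full <- generate_density_map(scene$ann)
  expect_equal(density_mass(tiles[[1]]$density), density_mass(full),
               tolerance = 1e-6)
})

test_that("annotation CSV round-trips through write and read", {
  set.seed(4)
  anns <- list(
    point_annotations("im1", data.frame(x = runif(5, 0, 63),
                                        y = runif(5, 0, 63)), c(64, 64)),
    point_annotations("im2", NULL, c(64, 64)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(anns, path)
  manifest <- data.frame(image_id = c("im1", "im2"), height = 64, width = 64)
  back <- read_annotations(path, manifest)
  expect_equal(back$im1$points, anns[[1]]$points, tolerance = 1e-12)
  expect_identical(n_points(back$im2), 0L)
})
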