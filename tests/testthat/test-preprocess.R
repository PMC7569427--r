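test_that("grayscale conversion uses unit-sum luminance weights", {
  z <- array(0, c(2, 2, 3))
  expect_equal(rgb_to_gray(z), matrix(0, 2, 2))
  o <- array(1, c(2, 2, 3))
  expect_equal(rgb_to_gray(o), matrix(1, 2, 2))
  g <- array(0, c(1, 1, 3)); g[1, 1, 2] <- 1
  expect_equal(rgb_to_gray(g)[1, 1], 0.587)
  expect_error(rgb_to_gray(array(0, c(2, 2, 4))), "H x W x 3")
  # 0-255 inputs are rescaled
  big <- array(255, c(2, 2, 3))
  expect_equal(rgb_to_gray(big), matrix(1, 2, 2))
})

test_that("standardization z-scores then min-max rescales", {
  expect_equal(standardize(matrix(c(0, 1), 1)), matrix(c(0, 1), 1))
  expect_equal(standardize(matrix(1:4, 1)), matrix(c(0, 1/3, 2/3, 1), 1))
  expect_warning(out <- standardize(matrix(0.3, 4, 4)), "constant")
  expect_equal(out, matrix(0.5, 4, 4))
})

test_that("clahe is deterministic, range-preserving and expands contrast", {
  set.seed(1)
  img <- matrix(runif(64 * 64), 64, 64)
  a <- clahe(img)
  b <- clahe(img)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))
  # constant image stays (essentially) constant
  cst <- clahe(matrix(0.5, 64, 64))
  expect_lt(diff(range(cst)), 1e-6)
  # low-contrast checkerboard gains contrast
  chk <- matrix(rep(c(0.4, 0.6), length.out = 64 * 64), 64, 64)
  out <- clahe(chk)
  expect_gte(diff(range(out)), diff(range(chk)))
  expect_error(clahe(img, tiles = c(100, 100)), "tile grid")
})

test_that("gamma correction is the stated power law", {
  img <- matrix(c(0, 0.5, 1), 1)
  expect_equal(gamma_correct(img, 1), img)
  expect_equal(gamma_correct(img, 1.2)[1, 2], 0.5^1.2, tolerance = 1e-12)
  expect_equal(gamma_correct(img, 1.2)[1, c(1, 3)], c(0, 1))
  expect_error(gamma_correct(img, -1), "gamma")
})

test_that("pipeline composes stages, preserving shape, range and determinism", {
  set.seed(2)
  rgb <- array(runif(40 * 50 * 3), c(40, 50, 3))
  out <- preprocess_pipeline(rgb, preprocess_config(clahe_tiles = c(4, 4)))
  expect_equal(dim(out), c(40, 50))
  expect_true(all(out >= 0 & out <= 1))
  expect_identical(out, preprocess_pipeline(rgb, preprocess_config(clahe_tiles = c(4, 4))))
})

test_that("pipeline raises vessel/background contrast on a phantom", {
  ds <- generate_fundus_dataset(1, synth_config(seed = 42))[[1]]
  contrast <- function(im) {
    inside <- ds$fov > 0
    mean(im[inside & ds$mask == 0]) - mean(im[inside & ds$mask == 1])
  }
  pp <- preprocess_pipeline(ds$image)
  expect_gte(contrast(pp), contrast(ds$image))
})

test_that("grid patch counts follow floor((dim - S)/s) + 1 plus the edge window", {
  img <- matrix(0, 48, 48)
  pg <- extract_patches(img, size = 48, stride = 5)
  expect_equal(nrow(pg$coords), 1L)
  expect_equal(pg$coords[1, ], c(0L, 0L))

  img2 <- matrix(0, 53, 48)
  pg2 <- extract_patches(img2, size = 48, stride = 5)
  expect_equal(nrow(pg2$coords), 2L)  # floor((53-48)/5)+1

  # a DRIVE-sized image: interior positions before the edge windows
  starts_r <- wanet:::.grid_starts(565L, 48L, 5L)
  starts_c <- wanet:::.grid_starts(584L, 48L, 5L)
  expect_equal(sum(starts_r %% 5 == 0 | starts_r == 565 - 48), length(starts_r))
  expect_equal(length(seq(0, 565 - 48, by = 5)), 104L)
  expect_equal(length(seq(0, 584 - 48, by = 5)), 108L)
  expect_error(extract_patches(matrix(0, 20, 20), size = 48), "exceeds")
})

test_that("random patch extraction is seed-reproducible and seed-sensitive", {
  set.seed(9)
  img <- matrix(runif(80 * 80), 80, 80)
  a <- extract_patches(img, size = 16, mode = "random", n = 30, seed = 7)
  b <- extract_patches(img, size = 16, mode = "random", n = 30, seed = 7)
  c3 <- extract_patches(img, size = 16, mode = "random", n = 30, seed = 8)
  expect_identical(a$coords, b$coords)
  expect_false(identical(a$coords, c3$coords))
  expect_error(extract_patches(img, size = 16, mode = "random"), "requires")
})

test_that("fov restricts random patch centres", {
  img <- matrix(0, 60, 60)
  fov <- matrix(0L, 60, 60)
  fov[20:40, 20:40] <- 1L
  pg <- extract_patches(img, size = 8, mode = "random", n = 50, seed = 3,
                        fov = fov)
  centres <- pg$coords + 4L + 1L  # 0-based corner -> 1-based centre
  expect_true(all(fov[centres] > 0))
})

test_that("patch extraction and reconstruction round-trip exactly", {
  set.seed(4)
  for (dims in list(c(48, 48), c(53, 61), c(96, 100))) {
    img <- matrix(runif(prod(dims)), dims[1], dims[2])
    pg <- extract_patches(img, size = 48, stride = 5)
    expect_lt(max(abs(reconstruct_map(pg) - img)), 1e-6)
  }
  # mask patches share coords and round-trip too
  img <- matrix(runif(64 * 64), 64, 64)
  msk <- matrix(rbinom(64 * 64, 1, 0.2), 64, 64)
  pg <- extract_patches(img, mask = msk, size = 16, stride = 7)
  expect_equal(reconstruct_map(pg, pg$mask_patches), msk + 0)
})

test_that("reconstruction reports uncovered pixels", {
  pg <- extract_patches(matrix(0, 20, 20), size = 8, stride = 4)
  pg$coords <- pg$coords[1, , drop = FALSE]
  pg$patches <- pg$patches[, , 1, drop = FALSE]
  expect_error(reconstruct_map(pg), "not covered")
})

test_that("averaging overlapping patch predictions is the mean", {
  pg <- extract_patches(matrix(0, 8, 8), size = 8, stride = 8)
  pg$coords <- rbind(pg$coords, pg$coords)
  vals <- array(0, c(8, 8, 2))
  vals[, , 2] <- 1
  expect_equal(reconstruct_map(pg, vals), matrix(0.5, 8, 8))
})
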