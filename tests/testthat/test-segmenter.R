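test_that("HU normalization follows the clipped divide-by-1500 rule", {
  expect_equal(normalize_hu(1500), 1)
  expect_equal(normalize_hu(-100), 0)
  expect_equal(normalize_hu(750), 0.5)
  expect_equal(normalize_hu(3000), 1)
  expect_equal(normalize_hu(c(-1000, 0, 150, 1500)),
               c(0, 0, 0.1, 1))
  # offset shifts the window; divisor must be positive
  expect_equal(normalize_hu(650, offset = 100), 0.5)
  expect_error(normalize_hu(1, divisor = 0), "positive")
  s <- ct_slice(matrix(c(-1000, 0, 750, 1500), 2, 2))
  ns <- normalize_hu(s)
  expect_true(ns$normalized)
  expect_equal(ns$data, matrix(c(0, 0, 0.5, 1), 2, 2))
})

test_that("residual images are clipped nonnegative differences", {
  a <- matrix(runif(16), 4, 4)
  expect_equal(residual_image(a, a), matrix(0, 4, 4))
  b <- a - 0.2
  blob <- a; blob[1:2, 1:2] <- a[1:2, 1:2] - 0.2
  r <- residual_image(a, blob)
  expect_equal(r[1:2, 1:2], matrix(0.2, 2, 2))
  expect_equal(r[3:4, 3:4], matrix(0, 2, 2))
  # synthetic higher than original is clipped to zero
  expect_equal(residual_image(a, a + 0.2), matrix(0, 4, 4))
  expect_error(residual_image(a, matrix(0, 2, 2)), "shape")
})

test_that("Otsu separates a two-level image exactly and matches the exhaustive oracle", {
  x <- c(rep(0, 50), rep(0.8, 50))
  m <- otsu_threshold(array(x, c(10, 10)))
  expect_identical(which(m == 1L), which(array(x, c(10, 10)) == 0.8))
  # constant image: empty mask
  mc <- otsu_threshold(matrix(0.3, 5, 5))
  expect_true(all(mc == 0L))
  expect_true(is.na(attr(mc, "threshold")))
  # histogram implementation == exhaustive 256-threshold search
  set.seed(31)
  for (i in 1:50) {
    img <- matrix(runif(64)^sample(1:3, 1), 8, 8)
    if (runif(1) < 0.3) img[1:3, 1:3] <- img[1:3, 1:3] + 1
    expect_equal(otsu_level(img), oracle_otsu(img))
  }
})

test_that("Otsu masks are invariant under positive rescaling of the residual", {
  set.seed(32)
  img <- matrix(runif(256), 16, 16)
  img[4:8, 4:8] <- img[4:8, 4:8] + 2
  m1 <- otsu_threshold(img)
  for (cc in c(0.1, 3, 42)) {
    m2 <- otsu_threshold(img * cc)
    expect_identical(bare(m2), bare(m1))
  }
})

test_that("binary median filtering matches the direct neighborhood oracle", {
  # isolated voxel removed; empty stays empty
  m <- matrix(0L, 9, 9); m[5, 5] <- 1L
  expect_true(all(median_denoise(m, "2d") == 0L))
  expect_true(all(median_denoise(matrix(0L, 5, 5), "2d") == 0L))
  # solid square: interior preserved, corners may round
  sq <- matrix(0L, 12, 12); sq[3:8, 3:8] <- 1L
  got <- median_denoise(sq, "2d")
  expect_equal(bare(got), bare(oracle_median2d(sq)))
  expect_true(all(got[4:7, 4:7] == 1L))
  # random masks against the oracle
  set.seed(33)
  for (i in 1:10) {
    rm_ <- random_mask(12)
    expect_equal(bare(median_denoise(rm_, "2d")), bare(oracle_median2d(rm_)))
  }
  # 3D: a single voxel in a volume disappears, a solid cube survives
  v <- array(0L, c(7, 7, 7)); v[4, 4, 4] <- 1L
  expect_true(all(median_denoise(v, "3d") == 0L))
  cube <- array(0L, c(9, 9, 9)); cube[3:7, 3:7, 3:7] <- 1L
  expect_true(all(median_denoise(cube, "3d")[4:6, 4:6, 4:6] == 1L))
})

test_that("morphological opening matches the erosion-dilation oracle", {
  m <- matrix(0L, 9, 9); m[5, 5] <- 1L
  expect_true(all(morph_refine(m) == 0L))
  expect_true(all(morph_refine(matrix(0L, 6, 6)) == 0L))
  # solid disk of diameter 11: opening preserves it
  d <- matrix(0L, 15, 15)
  cx <- matrix(rep(1:15, each = 15), 15); cy <- t(cx)
  d[(cx - 8)^2 + (cy - 8)^2 <= 5.5^2] <- 1L
  expect_equal(bare(morph_refine(d)), bare(oracle_open2d(d)))
  expect_gt(sum(morph_refine(d)), 0.9 * sum(d))
  set.seed(34)
  for (i in 1:10) {
    rm_ <- random_mask(12)
    got <- morph_refine(rm_)
    expect_equal(bare(got), bare(oracle_open2d(rm_)))
    # opening never adds pixels
    expect_true(all(got <= rm_))
  }
})

test_that("segment_volume records its options and threshold as metadata", {
  set.seed(35)
  G <- build_generator(generator_spec(16, 2, 2))
  vol <- ct_volume(array(runif(16 * 16 * 3, max = 1500), c(16, 16, 3)),
                   spacing = c(1, 1, 2))
  m <- segment_volume(vol, G, median = "2d", per_slice_otsu = FALSE)
  opts <- attr(m, "options")
  expect_equal(opts$median, "2d")
  expect_false(opts$per_slice_otsu)
  expect_equal(attr(m, "spacing"), c(1, 1, 2))
  expect_true(is.numeric(attr(m, "threshold")))
  expect_true(all(m %in% c(0L, 1L)))
  expect_equal(dim(m), dim(vol$data))
  # every stage preserves shape; opening is a subset of the median output
  m2 <- segment_volume(vol, G, per_slice_otsu = TRUE, median = "3d")
  expect_equal(length(attr(m2, "threshold")), 3L)
})
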