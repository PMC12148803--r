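test_that("healthy phantom slices are exactly mirror-symmetric without jitter and noise", {
  spec <- tiny_phantom_spec(noise_sigma = 0, asymmetry_jitter = 0)
  set.seed(11)
  s <- make_phantom_slice(spec, with_tumor = FALSE)
  img <- s$slice$data
  expect_identical(img, img[, rev(seq_len(ncol(img)))])
  expect_true(all(s$mask == 0L))
})

test_that("tumor mask area matches the rasterized-disk oracle and stays in one lung", {
  spec <- tiny_phantom_spec(noise_sigma = 0, asymmetry_jitter = 0)
  W <- spec$image_size
  geo <- symcycle:::phantom_geometry(spec)
  cx <- matrix(rep(seq_len(W) - (W + 1) / 2, each = W), W, W)
  cy <- matrix(rep(seq_len(W) - (W + 1) / 2, times = W), W, W)
  lungL <- ((cx + geo$lung_offset) / geo$lung_ax)^2 + (cy / geo$lung_ay)^2 <= 1
  lungR <- ((cx - geo$lung_offset) / geo$lung_ax)^2 + (cy / geo$lung_ay)^2 <= 1
  set.seed(23)
  for (rep in 1:10) {
    s <- make_phantom_slice(spec, with_tumor = TRUE)
    tum <- attr(s$mask, "tumor")
    # oracle: rasterize a disk at the drawn center/radius and count pixels
    oracle <- sum((cx - tum$cx)^2 + (cy - tum$cy)^2 <= tum$r_px^2)
    expect_equal(sum(s$mask), oracle)
    # loose analytic band around pi r^2 (discretization)
    expect_gt(sum(s$mask), pi * tum$r_px^2 - 4 * tum$r_px - 4)
    expect_lt(sum(s$mask), pi * tum$r_px^2 + 4 * tum$r_px + 4)
    # containment: inside the lung fields, and one lung only
    expect_true(all(lungL[s$mask == 1L] | lungR[s$mask == 1L]))
    expect_true(all(lungL[s$mask == 1L]) || all(lungR[s$mask == 1L]))
    # hyperdense tumor relative to parenchyma
    expect_true(all(s$slice$data[s$mask == 1L] == spec$hu_tumor))
  }
})

test_that("an oversized tumor radius is rejected naming the bound", {
  expect_error(tiny_phantom_spec(tumor_radius_range = c(2, 50)),
               "lung-field minor radius")
  spec <- tiny_phantom_spec()
  spec$tumor_radius_range <- c(49, 50)   # bypass constructor check
  set.seed(1)
  expect_error(make_phantom_slice(spec, with_tumor = TRUE),
               "lung minor radius")
})

test_that("cohorts are a pure function of the spec", {
  spec <- tiny_phantom_spec()
  a <- make_phantom_cohort(spec)
  b <- make_phantom_cohort(spec)
  expect_identical(a, b)
  spec2 <- tiny_phantom_spec()
  spec2$seed <- 8L
  c2 <- make_phantom_cohort(spec2)
  expect_false(identical(a$healthy[[1]]$data, c2$healthy[[1]]$data))
})

test_that("cohort pools have the requested sizes and nonempty masks", {
  co <- make_phantom_cohort(tiny_phantom_spec())
  expect_length(co$healthy, 6L)
  expect_length(co$unhealthy, 6L)
  expect_true(all(vapply(co$masks, function(m) sum(m) > 0, TRUE)))
})

test_that("volume tumors follow the sphere-plane intersection profile", {
  spec <- tiny_phantom_spec()
  co <- make_phantom_cohort(spec)
  v <- co$volumes[[1]]
  per_slice <- apply(v$mask, 3, sum)
  # oracle: a sphere of radius R intersects at most 2R/thickness + 1 planes
  R <- v$tumor$R_mm
  max_slices <- floor(2 * R / spec$slice_thickness) + 1
  expect_gt(sum(per_slice > 0), 0)
  expect_lte(sum(per_slice > 0), max_slices)
  # the swept sphere occupies contiguous slices around its center
  nz <- which(per_slice > 0)
  expect_identical(nz, seq(min(nz), max(nz)))
  expect_true(v$tumor$z0 %in% nz)
})

test_that("written cohorts round-trip arrays, spacing and manifest counts", {
  spec <- tiny_phantom_spec()
  co <- make_phantom_cohort(spec)
  dir <- withr::local_tempdir()
  man <- write_cohort(co, dir, png = TRUE)
  expect_equal(nrow(man), spec$n_healthy + spec$n_unhealthy)
  expect_equal(nrow(utils::read.delim(file.path(dir, "manifest.tsv"))),
               spec$n_healthy + spec$n_unhealthy)
  s <- read_volume(file.path(dir, "healthy", "h_0001.nii.gz"))
  expect_equal(s$data, co$healthy[[1]]$data, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(s$spacing, co$healthy[[1]]$spacing)
  v <- read_volume(file.path(dir, "volumes", "vol_01.nii.gz"))
  expect_equal(v$data, co$volumes[[1]]$image$data, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(v$spacing, c(1.954, 1.954, 1))
  m <- read_volume(file.path(dir, "masks", "u_0001_mask.nii.gz"))
  expect_identical(m$data == 1, co$masks[[1]] == 1L, ignore_attr = TRUE)
  expect_true(file.exists(file.path(dir, "png", "h_0001.png")))
})

test_that("default-spec NIfTI headers carry the 0.977 mm pixel size", {
  spec <- phantom_spec(n_healthy = 1, n_unhealthy = 1, n_volumes = 1,
                       volume_depth = 12, seed = 3)
  co <- make_phantom_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  v <- RNifti::readNifti(file.path(dir, "volumes", "vol_01.nii.gz"))
  expect_equal(RNifti::pixdim(v), c(0.977, 0.977, 1.0))
})
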