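# Seeded generator of mirror-symmetric lung CT phantoms.
#
# Each slice is a body ellipse on an air background containing two lung
# ellipses mirrored about the vertical midline, with smooth symmetric
# parenchymal texture, optional one-sided asymmetric jitter, optional
# Gaussian HU noise, and (for unhealthy slices) a single hyperdense tumor
# disk confined to one lung. Intensities are in Hounsfield units.

#' Phantom cohort specification
#'
#' All randomization parameters of the synthetic cohort generator. An
#' identical spec (including `seed`) yields bit-identical output.
#'
#' @param image_size Pixels per side (default 64; 512 supported).
#' @param pixel_spacing In-plane spacing in mm/pixel (default 0.977).
#' @param slice_thickness Slice spacing in mm (default 1).
#' @param n_healthy,n_unhealthy Slice counts of the two unpaired pools.
#' @param n_volumes Number of 3D stacks (each carrying a spherical tumor).
#' @param volume_depth Slices per 3D stack.
#' @param hu_air,hu_lung,hu_body,hu_tumor Tissue intensities in HU
#'   (defaults -1000, -800, 40, 20). The tumor must be hyperdense relative
#'   to lung parenchyma.
#' @param tumor_radius_range Tumor radius interval in mm (default 2-5).
#' @param noise_sigma Additive Gaussian noise, HU (default 20).
#' @param texture_amp Amplitude of the smooth symmetric lung texture, HU.
#' @param asymmetry_jitter Fraction of the texture amplitude allowed to
#'   differ between the lungs (applied to one randomly chosen lung).
#' @param seed Integer seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 64L, pixel_spacing = 0.977,
                         slice_thickness = 1.0, n_healthy = 200L,
                         n_unhealthy = 200L, n_volumes = 2L,
                         volume_depth = 16L, hu_air = -1000, hu_lung = -800,
                         hu_body = 40, hu_tumor = 20,
                         tumor_radius_range = c(2, 5), noise_sigma = 20,
                         texture_amp = 30, asymmetry_jitter = 0.3,
                         seed = 1L) {
  spec <- structure(list(image_size = as.integer(image_size),
                         pixel_spacing = pixel_spacing,
                         slice_thickness = slice_thickness,
                         n_healthy = as.integer(n_healthy),
                         n_unhealthy = as.integer(n_unhealthy),
                         n_volumes = as.integer(n_volumes),
                         volume_depth = as.integer(volume_depth),
                         hu_air = hu_air, hu_lung = hu_lung,
                         hu_body = hu_body, hu_tumor = hu_tumor,
                         tumor_radius_range = as.numeric(tumor_radius_range),
                         noise_sigma = noise_sigma,
                         texture_amp = texture_amp,
                         asymmetry_jitter = asymmetry_jitter,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  if (spec$image_size < 16L) stop("image_size must be >= 16")
  if (spec$pixel_spacing <= 0 || spec$slice_thickness <= 0)
    stop("spacings must be positive")
  if (length(spec$tumor_radius_range) != 2L ||
      spec$tumor_radius_range[1] <= 0 ||
      diff(spec$tumor_radius_range) < 0)
    stop("tumor_radius_range must be an increasing positive interval")
  if (spec$hu_lung >= spec$hu_tumor)
    stop("hu_tumor must exceed hu_lung (tumor is hyperdense)")
  geo <- phantom_geometry(spec)
  lung_minor_mm <- min(geo$lung_ax, geo$lung_ay) * spec$pixel_spacing
  if (spec$tumor_radius_range[2] >= lung_minor_mm)
    stop(sprintf(paste0("tumor_radius_range max (%.2f mm) must be smaller ",
                        "than the lung-field minor radius (%.2f mm)"),
                 spec$tumor_radius_range[2], lung_minor_mm))
  spec
}

# Fractional geometry of the phantom anatomy, in pixels.
phantom_geometry <- function(spec) {
  W <- spec$image_size
  list(body_ax = 0.42 * W, body_ay = 0.46 * W,
       lung_offset = 0.21 * W, lung_ax = 0.17 * W, lung_ay = 0.30 * W)
}

#' CT slice / volume containers
#'
#' Lightweight containers pairing an intensity array with its pixel spacing
#' (mm) and a flag recording whether values are HU or normalized \[0, 1\].
#'
#' @param data Matrix (slice) or 3-d array (volume).
#' @param spacing Numeric spacing per axis, mm.
#' @param normalized Logical; TRUE when values are in \[0, 1\].
#' @param id Optional identifier.
#' @return An object of class `ct_slice` or `ct_volume`.
#' @export
ct_slice <- function(data, spacing = c(0.977, 0.977), normalized = FALSE,
                     id = NULL) {
  stopifnot(is.matrix(data), all(spacing > 0), length(spacing) == 2L)
  structure(list(data = data, spacing = spacing,
                 normalized = isTRUE(normalized), id = id),
            class = "ct_slice")
}

#' @rdname ct_slice
#' @export
ct_volume <- function(data, spacing = c(0.977, 0.977, 1), normalized = FALSE,
                      id = NULL) {
  stopifnot(length(dim(data)) == 3L, all(spacing > 0), length(spacing) == 3L)
  structure(list(data = data, spacing = spacing,
                 normalized = isTRUE(normalized), id = id),
            class = "ct_volume")
}

# Internal slice builder; draws texture/jitter/noise from the current RNG.
# `tumor_px` forces tumor geometry: list(cx, cy, r_px) in pixel units
# (used when sweeping a sphere through a volume); NULL draws it.
phantom_slice_raw <- function(spec, with_tumor, tumor_px = NULL) {
  W <- spec$image_size
  geo <- phantom_geometry(spec)
  cx <- matrix(rep(seq_len(W) - (W + 1) / 2, each = W), W, W)  # column coord
  cy <- matrix(rep(seq_len(W) - (W + 1) / 2, times = W), W, W) # row coord
  body <- (cx / geo$body_ax)^2 + (cy / geo$body_ay)^2 <= 1
  lungL <- ((cx + geo$lung_offset) / geo$lung_ax)^2 +
    (cy / geo$lung_ay)^2 <= 1
  lungR <- ((cx - geo$lung_offset) / geo$lung_ax)^2 +
    (cy / geo$lung_ay)^2 <= 1
  lung <- lungL | lungR
  img <- matrix(spec$hu_air, W, W)
  img[body] <- spec$hu_body
  img[lung] <- spec$hu_lung

  # symmetric low-frequency texture (even in the mirrored coordinate |cx|)
  tex <- matrix(0, W, W)
  for (m in 1:3) {
    amp <- spec$texture_amp * stats::runif(1, 0.3, 1) / m
    fy <- sample(1:3, 1); fx <- sample(1:3, 1)
    phy <- stats::runif(1, 0, 2 * pi); phx <- stats::runif(1, 0, 2 * pi)
    tex <- tex + amp * cos(2 * pi * fy * cy / W + phy) *
      cos(2 * pi * fx * abs(cx) / W + phx)
  }
  img[lung] <- img[lung] + tex[lung]

  if (spec$asymmetry_jitter > 0) {
    jit <- matrix(0, W, W)
    for (m in 1:2) {
      amp <- spec$texture_amp * stats::runif(1, 0.3, 1)
      fy <- sample(1:4, 1); fx <- sample(1:4, 1)
      phy <- stats::runif(1, 0, 2 * pi); phx <- stats::runif(1, 0, 2 * pi)
      jit <- jit + amp * cos(2 * pi * fy * cy / W + phy) *
        cos(2 * pi * fx * cx / W + phx)
    }
    side <- if (stats::runif(1) < 0.5) lungL else lungR
    img[side] <- img[side] + spec$asymmetry_jitter * jit[side]
  }

  mask <- matrix(0L, W, W)
  tumor_info <- NULL
  if (with_tumor) {
    if (is.null(tumor_px)) {
      r_mm <- stats::runif(1, spec$tumor_radius_range[1],
                           spec$tumor_radius_range[2])
      r_px <- r_mm / spec$pixel_spacing
      if (r_px >= min(geo$lung_ax, geo$lung_ay))
        stop(sprintf(paste0("tumor radius %.2f mm (%.1f px) exceeds the ",
                            "lung minor radius (%.1f px)"),
                     r_mm, r_px, min(geo$lung_ax, geo$lung_ay)))
      side_sign <- if (stats::runif(1) < 0.5) -1 else 1   # -1 = left lung
      for (try in 1:200) {
        u <- stats::runif(1, -1, 1); v <- stats::runif(1, -1, 1)
        if (u^2 + v^2 > 1) next
        tcx <- side_sign * geo$lung_offset + u * max(geo$lung_ax - r_px, 0)
        tcy <- v * max(geo$lung_ay - r_px, 0)
        cand <- (cx - tcx)^2 + (cy - tcy)^2 <= r_px^2
        if (any(cand) && all(lung[cand])) { mask[cand] <- 1L; break }
      }
      if (!any(mask == 1L))
        stop("could not place a tumor disk inside the lung field")
      tumor_info <- list(r_mm = r_mm, r_px = r_px, cx = tcx, cy = tcy,
                         side = if (side_sign < 0) "left" else "right")
    } else {
      cand <- (cx - tumor_px$cx)^2 + (cy - tumor_px$cy)^2 <= tumor_px$r_px^2
      cand <- cand & lung
      mask[cand] <- 1L
      tumor_info <- tumor_px
    }
    img[mask == 1L] <- spec$hu_tumor
  }
  if (spec$noise_sigma > 0)
    img <- img + matrix(stats::rnorm(W * W, sd = spec$noise_sigma), W, W)
  attr(mask, "tumor") <- tumor_info
  list(image = img, mask = mask)
}

#' Generate one phantom slice
#'
#' Draws a slice (and its ground-truth mask) from the current RNG stream;
#' wrap in [set.seed()] (or use [make_phantom_cohort()]) for reproducibility.
#' Healthy slices are exactly mirror-symmetric when `asymmetry_jitter` and
#' `noise_sigma` are both zero.
#'
#' @param spec A [phantom_spec()].
#' @param with_tumor Logical; place a single hyperdense tumor disk in one
#'   randomly chosen lung.
#' @return List with `slice` (a [ct_slice()] in HU) and `mask` (0/1 integer
#'   matrix; all-zero for healthy slices). The drawn tumor geometry is
#'   attached to the mask as attribute `"tumor"`.
#' @export
make_phantom_slice <- function(spec, with_tumor = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  raw <- phantom_slice_raw(spec, with_tumor)
  list(slice = ct_slice(raw$image,
                        spacing = rep(spec$pixel_spacing, 2L)),
       mask = raw$mask)
}

#' Generate a full phantom cohort
#'
#' Deterministically (from `spec$seed`) generates the two unpaired slice
#' pools, per-slice tumor masks, and 3D stacks in which a spherical tumor is
#' swept through contiguous slices (per-slice radius following the
#' sphere-plane intersection), so the per-slice masks assemble into a
#' consistent mask volume.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_cohort`: list with `healthy`
#'   (list of [ct_slice()]), `unhealthy`, `masks` (one 0/1 matrix per
#'   unhealthy slice), `volumes` (list of `list(image = ct_volume, mask)`),
#'   and `spec`.
#' @export
make_phantom_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$n_healthy < 1L || spec$n_unhealthy < 1L)
    stop("pool sizes must be positive")
  set.seed(spec$seed)
  healthy <- vector("list", spec$n_healthy)
  for (i in seq_len(spec$n_healthy)) {
    raw <- phantom_slice_raw(spec, FALSE)
    healthy[[i]] <- ct_slice(raw$image, rep(spec$pixel_spacing, 2L),
                             id = sprintf("h_%04d", i))
  }
  unhealthy <- vector("list", spec$n_unhealthy)
  masks <- vector("list", spec$n_unhealthy)
  for (i in seq_len(spec$n_unhealthy)) {
    raw <- phantom_slice_raw(spec, TRUE)
    unhealthy[[i]] <- ct_slice(raw$image, rep(spec$pixel_spacing, 2L),
                               id = sprintf("u_%04d", i))
    masks[[i]] <- raw$mask
  }
  geo <- phantom_geometry(spec)
  volumes <- vector("list", spec$n_volumes)
  if (spec$n_volumes > 0L) for (v in seq_len(spec$n_volumes)) {
    R_mm <- stats::runif(1, spec$tumor_radius_range[1],
                         spec$tumor_radius_range[2])
    R_px <- R_mm / spec$pixel_spacing
    half_slices <- floor(R_mm / spec$slice_thickness)
    if (spec$volume_depth < 2L * half_slices + 1L)
      stop("volume_depth too small to contain the tumor sphere")
    z0 <- sample((half_slices + 1L):(spec$volume_depth - half_slices), 1L)
    side_sign <- if (stats::runif(1) < 0.5) -1 else 1
    repeat {
      uu <- stats::runif(1, -1, 1); vv <- stats::runif(1, -1, 1)
      if (uu^2 + vv^2 <= 1) break
    }
    tcx <- side_sign * geo$lung_offset + uu * max(geo$lung_ax - R_px, 0)
    tcy <- vv * max(geo$lung_ay - R_px, 0)
    W <- spec$image_size
    vol <- array(0, c(W, W, spec$volume_depth))
    mvol <- array(0L, c(W, W, spec$volume_depth))
    for (z in seq_len(spec$volume_depth)) {
      dz <- (z - z0) * spec$slice_thickness
      if (abs(dz) < R_mm) {
        r_z <- sqrt(R_mm^2 - dz^2) / spec$pixel_spacing
        raw <- phantom_slice_raw(spec, TRUE,
                                 tumor_px = list(cx = tcx, cy = tcy,
                                                 r_px = r_z))
      } else {
        raw <- phantom_slice_raw(spec, FALSE)
      }
      vol[, , z] <- raw$image
      mvol[, , z] <- raw$mask
    }
    sp3 <- c(rep(spec$pixel_spacing, 2L), spec$slice_thickness)
    attr(mvol, "spacing") <- sp3
    volumes[[v]] <- list(image = ct_volume(vol, sp3,
                                           id = sprintf("vol_%02d", v)),
                         mask = mvol,
                         tumor = list(R_mm = R_mm, cx = tcx, cy = tcy,
                                      z0 = z0))
  }
  structure(list(healthy = healthy, unhealthy = unhealthy, masks = masks,
                 volumes = volumes, spec = spec),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat("Phantom cohort:", length(x$healthy), "healthy /",
      length(x$unhealthy), "unhealthy slices (",
      x$spec$image_size, "x", x$spec$image_size, "px ),",
      length(x$volumes), "volumes\n")
  invisible(x)
}

#' Write a phantom cohort to disk
#'
#' Slices, masks and volumes are written as NIfTI with the spacing recorded
#' in the header (`pixdim`); a TSV manifest lists pool membership of every
#' 2D slice (columns path, pool, volume_id, slice_index). Optional 8-bit PNG
#' quick-looks use the window \[-1000, 400\] HU.
#'
#' @param cohort A [make_phantom_cohort()] result.
#' @param dir Output directory (created if missing).
#' @param png Also write PNG quick-looks of the 2D pools.
#' @return The manifest as a data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir, png = FALSE) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  for (sub in c("healthy", "unhealthy", "masks", "volumes"))
    dir.create(file.path(dir, sub), showWarnings = FALSE)
  if (png) dir.create(file.path(dir, "png"), showWarnings = FALSE)
  rows <- list()
  wr <- function(arr, spacing, path, uint8 = FALSE) {
    img <- RNifti::asNifti(arr)
    img <- RNifti::`pixdim<-`(img, spacing)
    RNifti::writeNifti(img, path, datatype = if (uint8) "uint8" else "auto")
  }
  for (i in seq_along(cohort$healthy)) {
    s <- cohort$healthy[[i]]
    p <- file.path(dir, "healthy", paste0(s$id, ".nii.gz"))
    wr(s$data, s$spacing, p)
    rows[[length(rows) + 1L]] <- data.frame(path = p, pool = "healthy",
                                            volume_id = NA, slice_index = i)
    if (png) write_quicklook(s, file.path(dir, "png", paste0(s$id, ".png")))
  }
  for (i in seq_along(cohort$unhealthy)) {
    s <- cohort$unhealthy[[i]]
    p <- file.path(dir, "unhealthy", paste0(s$id, ".nii.gz"))
    wr(s$data, s$spacing, p)
    wr(cohort$masks[[i]], s$spacing,
       file.path(dir, "masks", paste0(s$id, "_mask.nii.gz")), uint8 = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(path = p, pool = "unhealthy",
                                            volume_id = NA, slice_index = i)
    if (png) write_quicklook(s, file.path(dir, "png", paste0(s$id, ".png")))
  }
  for (v in seq_along(cohort$volumes)) {
    vol <- cohort$volumes[[v]]
    wr(vol$image$data, vol$image$spacing,
       file.path(dir, "volumes", paste0(vol$image$id, ".nii.gz")))
    wr(vol$mask, vol$image$spacing,
       file.path(dir, "volumes", paste0(vol$image$id, "_mask.nii.gz")),
       uint8 = TRUE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

# 8-bit PNG quick-look with a fixed HU display window.
write_quicklook <- function(slice, path, window = c(-1000, 400)) {
  x <- (slice$data - window[1]) / diff(window)
  x[x < 0] <- 0; x[x > 1] <- 1
  png::writePNG(x, path)
  invisible(path)
}
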