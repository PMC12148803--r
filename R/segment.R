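# Residual-image segmentation: synthesize a healthy counterpart with the
# trained generator, subtract, threshold (Otsu), median-denoise and refine
# with an in-plane morphological opening.

#' Normalize CT intensities from HU to \[0, 1\]
#'
#' `f(x) = clip((x + offset) / divisor, 0, 1)`. The defaults (offset 0,
#' divisor 1500) give the published normalization: values at or above
#' 1500 HU map to 1, values at or below 0 HU map to 0. The `offset`
#' parameter exists because the literal rule discards all sub-zero HU
#' contrast (air/lung); the phantom defaults work under the literal rule.
#'
#' @param x Numeric vector/matrix/array, or a [ct_slice()]/[ct_volume()].
#' @param offset Added to the HU values before scaling (default 0).
#' @param divisor Scale, HU (default 1500; must be positive).
#' @return Same shape/class as the input, normalized; `ct_*` containers get
#'   `normalized = TRUE`.
#' @export
normalize_hu <- function(x, offset = 0, divisor = 1500) {
  if (divisor <= 0) stop("divisor must be positive")
  if (inherits(x, "ct_slice") || inherits(x, "ct_volume")) {
    if (x$normalized) return(x)
    x$data <- normalize_hu(x$data, offset, divisor)
    x$normalized <- TRUE
    return(x)
  }
  y <- (x + offset) / divisor
  y[y < 0] <- 0
  y[y > 1] <- 1
  y
}

#' Residual image between a slice and its synthetic healthy counterpart
#'
#' Elementwise `max(original - synthetic, 0)`. Negative residuals are
#' clipped: tumors are hyperdense, so negative differences are synthesis
#' noise rather than tumor evidence.
#'
#' @param original,synthetic Normalized arrays of identical shape.
#' @return Nonnegative array of the same shape.
#' @export
residual_image <- function(original, synthetic) {
  if (!identical(dim(original), dim(synthetic)))
    stop("shape mismatch between original and synthetic image")
  pmax(original - synthetic, 0)
}

#' Otsu threshold of a residual image
#'
#' Maximizes the between-class variance over a 256-bin histogram spanning
#' the value range of the input. A constant input yields an empty mask.
#'
#' @param residual Nonnegative numeric array (any shape).
#' @param nbins Number of histogram bins (default 256).
#' @return Integer 0/1 array `residual > t*`, with the threshold attached as
#'   attribute `"threshold"` (NA for constant input).
#' @export
otsu_threshold <- function(residual, nbins = 256L) {
  if (!all(is.finite(residual))) stop("non-finite values in residual image")
  t_star <- otsu_level(residual, nbins)
  mask <- array(0L, dim(residual) %||% length(residual))
  if (!is.na(t_star)) mask[residual > t_star] <- 1L
  attr(mask, "threshold") <- t_star
  attr(mask, "spacing") <- attr(residual, "spacing", exact = TRUE)
  mask
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname otsu_threshold
#' @export
otsu_level <- function(residual, nbins = 256L) {
  lo <- min(residual); hi <- max(residual)
  if (hi <= lo) return(NA_real_)
  edges <- seq(lo, hi, length.out = nbins + 1L)
  counts <- tabulate(findInterval(residual, edges, all.inside = TRUE), nbins)
  p <- counts / sum(counts)
  mids <- (edges[-1L] + edges[-(nbins + 1L)]) / 2
  w0 <- cumsum(p)
  mu_t <- cumsum(p * mids)
  mu <- mu_t[nbins]
  # between-class variance at each split (threshold after bin k)
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, nbins)
  sigma_b[valid] <- (mu * w0[valid] - mu_t[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  k <- which.max(sigma_b[-nbins])
  edges[k + 1L]
}

# Neighbor-count of a binary array over a set of integer offsets,
# zero-padded at the borders.
neighbor_count <- function(mask, offsets) {
  d <- dim(mask)
  nd <- length(d)
  out <- array(0L, d)
  idx <- lapply(d, seq_len)
  for (off in offsets) {
    src <- dst <- idx
    ok <- TRUE
    for (a in seq_len(nd)) {
      o <- off[a]
      if (o == 0L) next
      if (abs(o) >= d[a]) { ok <- FALSE; break }
      if (o > 0L) {
        src[[a]] <- (1L + o):d[a]; dst[[a]] <- 1L:(d[a] - o)
      } else {
        src[[a]] <- 1L:(d[a] + o); dst[[a]] <- (1L - o):d[a]
      }
    }
    if (!ok) next
    out[dst[[1]], dst[[2]], dst[[3]]] <- out[dst[[1]], dst[[2]], dst[[3]]] +
      mask[src[[1]], src[[2]], src[[3]]]
  }
  out
}

as_vol3 <- function(mask) {
  if (is.matrix(mask)) array(mask, c(dim(mask), 1L)) else mask
}

offsets_grid <- function(deltas) {
  g <- expand.grid(deltas, deltas, deltas)
  lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ]))
}

#' Median-filter a binary mask
#'
#' Binary median filtering: a voxel is kept iff the majority of its 3x3
#' (2D, per slice) or 3x3x3 (3D) zero-padded neighborhood is set. Removes
#' isolated noise voxels while preserving solid structures.
#'
#' @param mask 0/1 matrix or 3-d array.
#' @param mode `"2d"` (per-slice 3x3) or `"3d"` (3x3x3).
#' @return Binary array of the same shape.
#' @export
median_denoise <- function(mask, mode = c("3d", "2d")) {
  mode <- match.arg(mode)
  was_mat <- is.matrix(mask)
  m <- as_vol3(mask)
  storage.mode(m) <- "integer"
  if (mode == "2d" || dim(m)[3] == 1L) {
    offs <- offsets_grid(-1:1)
    offs <- Filter(function(o) o[3] == 0L, offs)
    cnt <- neighbor_count(m, offs)
    out <- (cnt >= 5L) * 1L
  } else {
    cnt <- neighbor_count(m, offsets_grid(-1:1))
    out <- (cnt >= 14L) * 1L
  }
  out <- array(as.integer(out), dim(m))
  restore_mask_attrs(out, mask, was_mat)
}

cross_offsets_2d <- list(c(0L, 0L, 0L), c(1L, 0L, 0L), c(-1L, 0L, 0L),
                         c(0L, 1L, 0L), c(0L, -1L, 0L))

#' Morphological opening of a binary mask
#'
#' In-plane opening (erosion then dilation) with the radius-1 Euclidean
#' disk, i.e. the 3x3 cross structuring element. Removes structures thinner
#' than the element; never adds voxels outside the input.
#'
#' @param mask 0/1 matrix or 3-d array (applied per slice).
#' @return Binary array of the same shape.
#' @export
morph_refine <- function(mask) {
  was_mat <- is.matrix(mask)
  m <- as_vol3(mask)
  storage.mode(m) <- "integer"
  er <- (neighbor_count(m, cross_offsets_2d) >= 5L) * 1L  # all 5 set
  di <- (neighbor_count(array(as.integer(er), dim(m)),
                        cross_offsets_2d) >= 1L) * 1L
  out <- array(as.integer(di), dim(m))
  restore_mask_attrs(out, mask, was_mat)
}

restore_mask_attrs <- function(out, src, was_mat) {
  if (was_mat) out <- out[, , 1L]
  attr(out, "spacing") <- attr(src, "spacing", exact = TRUE)
  out
}

#' Segment tumors in a CT volume via residual images
#'
#' Runs the full inference chain: per-slice synthesis of a healthy
#' counterpart with the unhealthy-to-healthy generator, residual
#' computation, Otsu thresholding (a single volume-level threshold by
#' default), binary median filtering (3D by default; 2D for single slices)
#' and in-plane morphological opening.
#'
#' @param volume A [ct_volume()], [ct_slice()], or numeric array (assumed
#'   HU unless `normalized = TRUE`).
#' @param generator A trained generator (`gen_net`), a `train_state`, or a
#'   fitted [symcycle()] model (its `G_xy` is used).
#' @param per_slice_otsu Threshold each slice separately instead of once per
#'   volume (default FALSE: slice-wise thresholds hallucinate masks from
#'   noise on tumor-free slices).
#' @param median `"3d"` or `"2d"` median filtering.
#' @param hu_offset,hu_divisor Passed to [normalize_hu()] when the input is
#'   in HU; `hu_offset = NULL` (default) takes the offset the fitted model
#'   was trained with.
#' @param normalized Set TRUE when a plain array is already in \[0, 1\].
#' @param bn_mode Batch-normalization statistics at inference: `"batch"`
#'   (default; statistics of the slices being segmented) or `"running"`
#'   (training running averages).
#' @param batch_size Slices per generator forward pass.
#' @return Integer 0/1 array shaped like the input, with attributes
#'   `threshold` (the Otsu level(s)), `options`, and `spacing`.
#' @export
segment_volume <- function(volume, generator, per_slice_otsu = FALSE,
                           median = c("3d", "2d"), hu_offset = NULL,
                           hu_divisor = 1500, normalized = FALSE,
                           bn_mode = c("batch", "running"),
                           batch_size = 16L) {
  median <- match.arg(median)
  bn_mode <- match.arg(bn_mode)
  if (is.null(hu_offset))
    hu_offset <- if (inherits(generator, "symcycle"))
      generator$hu_offset %||% 0 else 0
  G <- extract_generator(generator)
  spacing <- NULL
  if (inherits(volume, "ct_slice")) {
    spacing <- c(volume$spacing, 1)
    arr <- array(volume$data, c(dim(volume$data), 1L))
    normalized <- volume$normalized
  } else if (inherits(volume, "ct_volume")) {
    spacing <- volume$spacing
    arr <- volume$data
    normalized <- volume$normalized
  } else {
    arr <- as_vol3(volume)
    spacing <- attr(volume, "spacing", exact = TRUE)
  }
  if (!normalized) arr <- normalize_hu(arr, hu_offset, hu_divisor)
  d <- dim(arr)
  synth <- array(0, d)
  use_batch_stats <- bn_mode == "batch"
  for (s0 in seq(1L, d[3], by = batch_size)) {
    zz <- s0:min(s0 + batch_size - 1L, d[3])
    X <- array(arr[, , zz], c(d[1], d[2], 1L, length(zz)))
    fw <- gen_forward(G, X, train = use_batch_stats, keep_cache = FALSE)
    synth[, , zz] <- fw$Y[, , 1L, ]
  }
  resid <- residual_image(arr, synth)
  if (per_slice_otsu) {
    mask <- array(0L, d)
    thr <- numeric(d[3])
    for (z in seq_len(d[3])) {
      mz <- otsu_threshold(resid[, , z])
      mask[, , z] <- mz
      thr[z] <- attr(mz, "threshold")
    }
  } else {
    mask <- otsu_threshold(resid)
    thr <- attr(mask, "threshold")
  }
  mask <- median_denoise(mask, mode = if (d[3] == 1L) "2d" else median)
  mask <- morph_refine(mask)
  if (d[3] == 1L && (inherits(volume, "ct_slice") || is.matrix(volume)))
    mask <- array(mask, d)[, , 1L]
  attr(mask, "threshold") <- thr
  attr(mask, "spacing") <- spacing
  attr(mask, "options") <- list(per_slice_otsu = per_slice_otsu,
                                median = median, hu_offset = hu_offset,
                                hu_divisor = hu_divisor, bn_mode = bn_mode)
  mask
}

extract_generator <- function(generator) {
  if (inherits(generator, "gen_net")) return(generator)
  if (inherits(generator, "train_state")) return(generator$bundle$G_xy)
  if (inherits(generator, "symcycle")) return(generator$state$bundle$G_xy)
  stop("generator must be a gen_net, train_state or fitted symcycle model")
}
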