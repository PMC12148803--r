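# Segmentation evaluation: volume overlap (Dice, PPV, SEN) and surface
# distances (HD95, ASD) under anisotropic voxel spacing, plus cohort
# aggregation.

mask_data <- function(m) {
  if (is.list(m) && !is.null(m$data)) m <- m$data
  m
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b)))
    stop("mask shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
}

#' Volume overlap metrics
#'
#' `dice()` returns `2|P n G| / (|P| + |G|) * 100`; `ppv()` (precision)
#' `|P n G| / |P| * 100`; `sen()` (sensitivity) `|P n G| / |G| * 100`.
#' Two empty masks give Dice 100 (with a warning); one empty mask gives 0.
#' PPV/SEN with an empty denominator mask return 0 with a warning.
#'
#' @param pred,gt Binary arrays of identical shape (predicted and ground
#'   truth).
#' @return Percentage in \[0, 100\].
#' @export
dice <- function(pred, gt) {
  pred <- mask_data(pred); gt <- mask_data(gt)
  check_same_shape(pred, gt)
  np <- sum(pred != 0); ng <- sum(gt != 0)
  if (np + ng == 0) {
    warning("both masks empty; Dice defined as 100")
    return(100)
  }
  200 * sum(pred != 0 & gt != 0) / (np + ng)
}

#' @rdname dice
#' @export
ppv <- function(pred, gt) {
  pred <- mask_data(pred); gt <- mask_data(gt)
  check_same_shape(pred, gt)
  np <- sum(pred != 0)
  if (np == 0) {
    warning("empty predicted mask; PPV defined as 0")
    return(0)
  }
  100 * sum(pred != 0 & gt != 0) / np
}

#' @rdname dice
#' @export
sen <- function(pred, gt) {
  pred <- mask_data(pred); gt <- mask_data(gt)
  check_same_shape(pred, gt)
  ng <- sum(gt != 0)
  if (ng == 0) {
    warning("empty ground-truth mask; SEN defined as 0")
    return(0)
  }
  100 * sum(pred != 0 & gt != 0) / ng
}

#' Extract the boundary surface of a binary mask
#'
#' Boundary voxels are mask voxels with at least one unset face neighbor
#' (4-connectivity in 2D, 6-connectivity in 3D; borders count as outside),
#' i.e. `mask & !erode(mask)`. Coordinates are voxel indices scaled by the
#' spacing, in mm.
#'
#' @param mask Binary matrix or 3-d array.
#' @param spacing Numeric spacing per axis, mm; defaults to the mask's
#'   `"spacing"` attribute or 1.
#' @return Matrix of boundary-point coordinates (one row per voxel), in mm.
#' @export
extract_surface <- function(mask, spacing = NULL) {
  m0 <- mask_data(mask)
  if (is.null(spacing))
    spacing <- attr(mask, "spacing", exact = TRUE) %||%
      rep(1, length(dim(m0) %||% 1))
  if (sum(m0 != 0) == 0)
    stop("empty mask: surface metrics are undefined")
  was_mat <- is.matrix(m0)
  m <- as_vol3(m0)
  storage.mode(m) <- "integer"
  offs <- if (was_mat) cross_offsets_2d[-1L] else
    list(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L), c(0L, -1L, 0L),
         c(0L, 0L, 1L), c(0L, 0L, -1L))
  cnt <- neighbor_count(m, offs)
  boundary <- m == 1L & cnt < length(offs)
  coords <- which(boundary, arr.ind = TRUE)
  if (was_mat) coords <- coords[, 1:2, drop = FALSE]
  if (length(spacing) != ncol(coords))
    stop("spacing length does not match mask dimensionality")
  sweep(coords, 2L, spacing, `*`)
}

# Directed nearest-neighbor distances from each row of A to the set B (mm),
# computed blockwise from the expanded squared Euclidean form.
nn_dists <- function(A, B, block = 512L) {
  nb2 <- rowSums(B^2)
  out <- numeric(nrow(A))
  for (s in seq(1L, nrow(A), by = block)) {
    ii <- s:min(s + block - 1L, nrow(A))
    Ab <- A[ii, , drop = FALSE]
    d2 <- outer(rowSums(Ab^2), nb2, `+`) - 2 * tcrossprod(Ab, B)
    out[ii] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  out
}

surface_dists <- function(pred, gt, spacing) {
  P <- extract_surface(pred, spacing)
  G <- extract_surface(gt, spacing)
  list(pg = nn_dists(P, G), gp = nn_dists(G, P))
}

#' 95th-percentile Hausdorff distance
#'
#' The maximum over both directions of the 95th percentile (linear
#' interpolation) of nearest-surface distances between the predicted and
#' ground-truth boundaries, in mm.
#'
#' @param pred,gt Binary masks (both nonempty).
#' @param spacing Voxel spacing per axis, mm.
#' @return Distance in mm.
#' @export
hd95 <- function(pred, gt, spacing = NULL) {
  ds <- surface_dists(pred, gt, spacing)
  max(stats::quantile(ds$pg, 0.95, names = FALSE, type = 7),
      stats::quantile(ds$gp, 0.95, names = FALSE, type = 7))
}

#' Average symmetric surface distance
#'
#' Mean of the nearest-surface distances pooled over both directions
#' (predicted to truth and truth to predicted), in mm.
#'
#' @inheritParams hd95
#' @return Distance in mm.
#' @export
asd <- function(pred, gt, spacing = NULL) {
  ds <- surface_dists(pred, gt, spacing)
  mean(c(ds$pg, ds$gp))
}

#' Evaluate a cohort of segmentations
#'
#' Per-case Dice/PPV/SEN/HD95/ASD plus the usual cohort summaries
#' (mean, sd, median and interquartile range). Cases where surface metrics
#' are undefined (an empty mask on either side) keep their overlap metrics;
#' their surface metrics are NA and the count is reported.
#'
#' @param preds,gts Paired lists of binary masks.
#' @param spacing Voxel spacing per axis, mm (shared by all cases).
#' @return An object of class `metric_report`: list with `per_case` (data
#'   frame), `summary` (data frame of mean/sd/median/q25/q75 per metric) and
#'   `n_undefined_surface`.
#' @export
evaluate_cohort <- function(preds, gts, spacing = NULL) {
  if (length(preds) != length(gts))
    stop("unpaired cases: ", length(preds), " predictions vs ",
         length(gts), " ground truths")
  n <- length(preds)
  per <- data.frame(case = seq_len(n), dice_pct = NA_real_,
                    ppv_pct = NA_real_, sen_pct = NA_real_,
                    hd95_mm = NA_real_, asd_mm = NA_real_)
  n_undef <- 0L
  for (i in seq_len(n)) {
    p <- mask_data(preds[[i]]); g <- mask_data(gts[[i]])
    per$dice_pct[i] <- suppressWarnings(dice(p, g))
    per$ppv_pct[i] <- suppressWarnings(ppv(p, g))
    per$sen_pct[i] <- suppressWarnings(sen(p, g))
    if (sum(p != 0) > 0 && sum(g != 0) > 0) {
      sp <- spacing %||% attr(preds[[i]], "spacing", exact = TRUE)
      per$hd95_mm[i] <- hd95(p, g, sp)
      per$asd_mm[i] <- asd(p, g, sp)
    } else {
      n_undef <- n_undef + 1L
    }
  }
  met <- c("dice_pct", "ppv_pct", "sen_pct", "hd95_mm", "asd_mm")
  summ <- do.call(rbind, lapply(met, function(m) {
    v <- per[[m]][!is.na(per[[m]])]
    data.frame(metric = m, mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
               median = median(v),
               q25 = quantile(v, 0.25, names = FALSE, type = 7),
               q75 = quantile(v, 0.75, names = FALSE, type = 7),
               n = length(v))
  }))
  structure(list(per_case = per, summary = summ,
                 n_undefined_surface = n_undef),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Segmentation metrics over", nrow(x$per_case), "cases\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s mean %7.2f +/- %6.2f  median %7.2f  IQR %.2f-%.2f\n",
                s$metric[i], s$mean[i], s$sd[i], s$median[i], s$q25[i],
                s$q75[i]))
  if (x$n_undefined_surface > 0)
    cat("  (", x$n_undefined_surface,
        "cases with undefined surface distances )\n")
  invisible(x)
}

#' Write a metric report as TSV
#'
#' @param report A `metric_report`.
#' @param path Output file; the per-case table followed by a summary block.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  utils::write.table(report$per_case, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines("", con)
  utils::write.table(report$summary, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
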