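# The user-facing model: fit the symmetry-constrained cycle-consistent
# translation model on unpaired healthy/unhealthy pools and use it to
# synthesize healthy counterparts and segment tumors.

#' Fit the symmetry-constrained cycle-consistent translation model
#'
#' Trains the five networks (two U-Net generators, two patch
#' discriminators, one bilateral-symmetry discriminator) on unpaired pools
#' of tumor-bearing (`x`) and tumor-free (`y`) slices using the three-step
#' alternating optimization. Slices in HU are normalized with
#' [normalize_hu()] before training.
#'
#' @param x Unhealthy pool: a `phantom_cohort` (in which case `y` is taken
#'   from it), a list of [ct_slice()]s/matrices, or an array.
#' @param y Healthy pool (ignored when `x` is a cohort).
#' @param gen_spec A [generator_spec()]; defaults to the published
#'   architecture at the data's resolution.
#' @param disc_spec A [discriminator_spec()]; defaults analogously.
#' @param config A [train_config()].
#' @param normalize Normalize inputs from HU (default TRUE; set FALSE when
#'   pools are already in \[0, 1\]).
#' @param hu_offset Offset passed to [normalize_hu()] (default 0, the
#'   literal published rule; 1000 keeps lung-parenchyma contrast above the
#'   clip at zero). Remembered by the fit and reused at prediction time.
#' @param keep_data Keep the (normalized) training pools in the fit, which
#'   enables [simulate.symcycle()] (default TRUE).
#' @param verbose Print per-epoch loss means.
#' @return An object of class `symcycle` with `print`, `summary`, `coef`,
#'   `predict`, `residuals`, `plot` and `simulate` methods.
#' @seealso [segment_volume()], [evaluate_cohort()]
#' @examples
#' \donttest{
#' spec <- phantom_spec(image_size = 32, pixel_spacing = 1.954,
#'                      n_healthy = 16, n_unhealthy = 16, n_volumes = 0)
#' cohort <- make_phantom_cohort(spec)
#' cfg <- train_config(total_epochs = 2, decay_epochs = 1, batch_size = 8)
#' fit <- symcycle(cohort, gen_spec = generator_spec(32, 4),
#'                 disc_spec = discriminator_spec(32, 32, 8), config = cfg)
#' print(fit)
#' }
#' @export
symcycle <- function(x, y = NULL, gen_spec = NULL, disc_spec = NULL,
                     config = train_config(), normalize = TRUE,
                     hu_offset = 0, keep_data = TRUE, verbose = FALSE) {
  cl <- match.call()
  if (inherits(x, "phantom_cohort")) {
    y <- x$healthy
    x <- x$unhealthy
  }
  X <- as_pool_array(x)
  Y <- as_pool_array(y)
  if (normalize) {
    X <- normalize_hu(X, hu_offset)
    Y <- normalize_hu(Y, hu_offset)
  }
  if (min(X) < 0 || max(X) > 1 || min(Y) < 0 || max(Y) > 1)
    stop("training pools must be normalized to [0, 1]; see normalize_hu()")
  size <- dim(X)[1]
  if (dim(X)[2] != size || !identical(dim(Y)[1:2], dim(X)[1:2]))
    stop("all slices must be square and share one size")
  if (is.null(gen_spec)) gen_spec <- generator_spec(input_size = size)
  if (is.null(disc_spec))
    disc_spec <- discriminator_spec(input_height = size, input_width = size)
  if (gen_spec$input_size != size)
    stop("gen_spec$input_size (", gen_spec$input_size,
         ") does not match the slice size (", size, ")")
  state <- train(X, Y, gen_spec, disc_spec, config, verbose = verbose)
  structure(list(state = state, gen_spec = gen_spec, disc_spec = disc_spec,
                 config = config, call = cl, image_size = size,
                 hu_offset = hu_offset,
                 loss_history = state$loss_history,
                 data = if (keep_data) list(x = X, y = Y) else NULL),
            class = "symcycle")
}

#' @export
print.symcycle <- function(x, ...) {
  cat("Symmetry-constrained cycle-consistent translation model\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("Slices %dx%d, generator base %d channels, depth %d;%s\n",
              x$image_size, x$image_size, x$gen_spec$base_channels,
              x$gen_spec$depth,
              if (x$config$similarity) " with similarity discriminator"
              else " cycle-GAN ablation (no similarity discriminator)"))
  lh <- x$loss_history
  if (!is.null(lh)) {
    last <- lh[lh$epoch == max(lh$epoch), ]
    cat(sprintf("Trained %d epochs (%d steps); final-epoch means: l_gen %.3f, l_dis %.3f%s\n",
                max(lh$epoch), nrow(lh), mean(last$l_gen), mean(last$l_dis),
                if (all(is.na(last$l_smi))) ""
                else sprintf(", l_smi %.3f", mean(last$l_smi))))
  }
  invisible(x)
}

#' @export
summary.symcycle <- function(object, ...) {
  lh <- object$loss_history
  npar <- function(net) sum(vapply(net_params(net), length, 1L))
  b <- object$state$bundle
  out <- list(
    call = object$call,
    image_size = object$image_size,
    similarity = object$config$similarity,
    epochs = if (is.null(lh)) 0L else max(lh$epoch),
    n_parameters = c(G_xy = npar(b$G_xy), G_yx = npar(b$G_yx),
                     D_x = npar(b$D_x), D_y = npar(b$D_y),
                     D_smi = npar(b$D_smi)),
    loss_first_epoch = if (is.null(lh)) NULL else
      colMeans(lh[lh$epoch == min(lh$epoch),
                  c("l_gan", "l_cycle", "l_id", "l_dis", "l_gen")]),
    loss_final_epoch = if (is.null(lh)) NULL else
      colMeans(lh[lh$epoch == max(lh$epoch),
                  c("l_gan", "l_cycle", "l_id", "l_dis", "l_gen")]))
  class(out) <- "summary.symcycle"
  out
}

#' @export
print.summary.symcycle <- function(x, ...) {
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat("Parameters per network:\n")
  print(x$n_parameters)
  if (!is.null(x$loss_first_epoch)) {
    cat("Loss means, first epoch:\n"); print(round(x$loss_first_epoch, 4))
    cat("Loss means, final epoch:\n"); print(round(x$loss_final_epoch, 4))
  }
  invisible(x)
}

#' @export
coef.symcycle <- function(object, ...) {
  b <- object$state$bundle
  c(prefix_names(net_params(b$G_xy), "G_xy."),
    prefix_names(net_params(b$G_yx), "G_yx."),
    prefix_names(net_params(b$D_x), "D_x."),
    prefix_names(net_params(b$D_y), "D_y."),
    prefix_names(net_params(b$D_smi), "D_smi."))
}

#' Predict from a fitted translation model
#'
#' @param object A fitted [symcycle()] model.
#' @param newdata A [ct_slice()], [ct_volume()], matrix or array (HU unless
#'   `normalized`).
#' @param type `"healthy"` (synthetic tumor-free counterpart),
#'   `"unhealthy"` (reverse generator), `"residual"` (clipped difference
#'   original - synthetic), or `"mask"` (full segmentation chain).
#' @param normalized Set TRUE when `newdata` is already in \[0, 1\].
#' @param ... Passed to [segment_volume()] for `type = "mask"`.
#' @return Array shaped like the input (or a 0/1 mask).
#' @export
predict.symcycle <- function(object, newdata,
                             type = c("healthy", "unhealthy", "residual",
                                      "mask"),
                             normalized = FALSE, ...) {
  type <- match.arg(type)
  if (type == "mask")
    return(segment_volume(newdata, object, normalized = normalized, ...))
  arr <- if (inherits(newdata, "ct_slice") || inherits(newdata, "ct_volume")) {
    normalized <- newdata$normalized
    newdata$data
  } else newdata
  if (!normalized) arr <- normalize_hu(arr, offset = object$hu_offset)
  d3 <- as_vol3(arr)
  d <- dim(d3)
  G <- if (type == "unhealthy") object$state$bundle$G_yx
       else object$state$bundle$G_xy
  out <- array(0, d)
  for (s0 in seq(1L, d[3], by = 16L)) {
    zz <- s0:min(s0 + 15L, d[3])
    X <- array(d3[, , zz], c(d[1], d[2], 1L, length(zz)))
    out[, , zz] <- gen_forward(G, X, train = TRUE,
                               keep_cache = FALSE)$Y[, , 1L, ]
  }
  res <- if (type == "residual") residual_image(d3, out) else out
  if (is.matrix(arr)) res[, , 1L] else res
}

#' @export
residuals.symcycle <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$data))
      stop("fit was created with keep_data = FALSE; supply newdata")
    newdata <- object$data$x[, , 1L, , drop = TRUE]
    if (length(dim(newdata)) == 2L) dim(newdata) <- c(dim(newdata), 1L)
  }
  predict(object, newdata, type = "residual", normalized = TRUE)
}

#' Plot training loss trajectories
#'
#' @param x A fitted [symcycle()] model.
#' @param components Loss columns to draw.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.symcycle <- function(x, components = c("l_gen", "l_dis", "l_gan",
                                            "l_cycle"), ...) {
  lh <- x$loss_history
  if (is.null(lh)) stop("no loss history recorded")
  components <- intersect(components, names(lh))
  graphics::matplot(seq_len(nrow(lh)), lh[components], type = "l", lty = 1,
                    xlab = "training step", ylab = "loss", ...)
  graphics::legend("topright", legend = components, col = seq_along(components),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Simulate synthetic healthy slices from the fitted model
#'
#' Draws `nsim` slices from the stored unhealthy training pool and returns
#' their synthetic healthy translations.
#'
#' @param object A fitted [symcycle()] model (with `keep_data = TRUE`).
#' @param nsim Number of slices.
#' @param seed Optional seed for the draw.
#' @param ... Unused.
#' @return List of matrices in \[0, 1\], with the source indices as names.
#' @export
simulate.symcycle <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$data))
    stop("fit was created with keep_data = FALSE; cannot simulate")
  if (!is.null(seed)) set.seed(seed)
  n <- dim(object$data$x)[4]
  ii <- sample.int(n, nsim, replace = nsim > n)
  out <- lapply(ii, function(i) {
    predict(object, object$data$x[, , 1L, i], type = "healthy",
            normalized = TRUE)
  })
  names(out) <- paste0("slice_", ii)
  out
}
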