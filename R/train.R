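# Three-step alternating optimization: (1) generators, (2) patch
# discriminators, (3) similarity discriminator, with Adam and a
# constant-then-linear learning-rate schedule.

#' Training configuration
#'
#' Defaults follow the published schedule: Adam with `beta1 = 0.5`,
#' `beta2 = 0.999`, initial learning rate `2e-4`, 200 epochs of which the
#' last 50 decay linearly to zero.
#'
#' @param total_epochs Number of epochs (default 200).
#' @param decay_epochs Length of the final linear-decay phase (default 50).
#' @param initial_lr Learning rate during the constant phase (default 2e-4).
#' @param beta1,beta2 Adam moment decay rates (defaults 0.5, 0.999).
#' @param batch_size Slices per batch (default 16).
#' @param weights A [loss_weights()] object.
#' @param similarity Train and use the similarity discriminator (FALSE gives
#'   the plain cycle-GAN ablation).
#' @param seed Integer seed driving initialization and epoch shuffles.
#' @param checkpoint_every Write a checkpoint every this many epochs (NULL
#'   for final-epoch only).
#' @param checkpoint_dir,log_path Optional output locations; the TSV loss
#'   log has columns epoch, step, l_gan, l_cycle, l_id, l_dis, l_smi, l_gen.
#' @param init_output_bias Initialize each generator's output-layer bias at
#'   the logit of the training pools' mean intensity, so synthesis starts
#'   near the identity regime instead of mid-gray (default TRUE; important
#'   for short schedules on low-dynamic-range normalized CT).
#' @param device Descriptor recorded with the run (always "cpu" here).
#' @return An object of class `train_config`.
#' @export
train_config <- function(total_epochs = 200L, decay_epochs = 50L,
                         initial_lr = 2e-4, beta1 = 0.5, beta2 = 0.999,
                         batch_size = 16L, weights = loss_weights(),
                         similarity = TRUE, seed = 1L,
                         checkpoint_every = NULL, checkpoint_dir = NULL,
                         log_path = NULL, init_output_bias = TRUE,
                         device = "cpu") {
  total_epochs <- as.integer(total_epochs)
  decay_epochs <- as.integer(decay_epochs)
  if (total_epochs < 1L) stop("total_epochs must be >= 1")
  if (decay_epochs < 0L || decay_epochs > total_epochs)
    stop("decay_epochs must lie in [0, total_epochs]")
  if (initial_lr < 0) stop("initial_lr must be >= 0")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  stopifnot(inherits(weights, "loss_weights"))
  structure(list(total_epochs = total_epochs, decay_epochs = decay_epochs,
                 initial_lr = initial_lr, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size), weights = weights,
                 similarity = isTRUE(similarity), seed = as.integer(seed),
                 checkpoint_every = checkpoint_every,
                 checkpoint_dir = checkpoint_dir, log_path = log_path,
                 init_output_bias = isTRUE(init_output_bias),
                 device = device),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Constant at `initial_lr` through epoch `total_epochs - decay_epochs`,
#' then linearly decayed, reaching exactly 0 at `total_epochs`.
#'
#' @param epoch 1-based epoch counter.
#' @param config A [train_config()].
#' @return The learning rate.
#' @export
lr_at_epoch <- function(epoch, config) {
  if (any(epoch < 1L) || any(epoch > config$total_epochs))
    stop("epoch must lie in [1, ", config$total_epochs, "]")
  e0 <- config$total_epochs - config$decay_epochs
  ifelse(epoch <= e0, config$initial_lr,
         config$initial_lr * (config$total_epochs - epoch) / config$decay_epochs)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1, beta2, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, st = st)
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}

prefix_names <- function(x, pre) {
  names(x) <- paste0(pre, names(x))
  x
}

#' Initialize a training state
#'
#' Builds the [network_bundle()] (from the current RNG stream) and fresh
#' optimizer states.
#'
#' @param gen_spec,disc_spec Architecture specs shared by the generators and
#'   the patch discriminators.
#' @param config A [train_config()].
#' @return An object of class `train_state`.
#' @export
init_train_state <- function(gen_spec, disc_spec, config) {
  bundle <- network_bundle(gen_spec, disc_spec)
  gen_par <- c(prefix_names(net_params(bundle$G_xy), "xy."),
               prefix_names(net_params(bundle$G_yx), "yx."))
  structure(list(
    bundle = bundle,
    opt = list(gen = adam_init(gen_par),
               dx = adam_init(net_params(bundle$D_x)),
               dy = adam_init(net_params(bundle$D_y)),
               smi = adam_init(net_params(bundle$D_smi))),
    epoch = 0L,
    loss_history = NULL), class = "train_state")
}

msq_grad <- function(z, target) 2 * (z - target) / length(z)
l1_grad <- function(a, b) sign(a - b) / length(a)

#' One alternating training step
#'
#' Performs the three sequential updates on one unpaired batch: generators
#' (adversarial + cycle + identity + optional symmetry terms), then the two
#' patch discriminators, then (when enabled) the similarity discriminator.
#'
#' @param batch_x Unhealthy slices `(H, W, 1, N)`, normalized to \[0, 1\].
#' @param batch_y Healthy slices, same shape contract.
#' @param state A `train_state`.
#' @param config A [train_config()].
#' @param lr Learning rate for this step.
#' @return List with the updated `state` and a one-row data frame `report`
#'   of loss components.
#' @export
train_step <- function(batch_x, batch_y, state, config, lr = config$initial_lr) {
  if (length(batch_x) == 0L || length(batch_y) == 0L)
    stop("empty batch")
  w <- config$weights
  b <- state$bundle
  use_smi <- config$similarity
  lam_s <- if (use_smi) w$lambda_s else 0

  ## ---- Step 1: generators -------------------------------------------------
  fx <- gen_forward(b$G_xy, batch_x, train = TRUE); b$G_xy <- fx$net
  yp <- fx$Y
  fy <- gen_forward(b$G_yx, batch_y, train = TRUE); b$G_yx <- fy$net
  xp <- fy$Y
  fcx <- gen_forward(b$G_yx, yp, train = TRUE); b$G_yx <- fcx$net
  xpp <- fcx$Y
  fcy <- gen_forward(b$G_xy, xp, train = TRUE); b$G_xy <- fcy$net
  ypp <- fcy$Y
  fiy <- gen_forward(b$G_xy, batch_y, train = TRUE); b$G_xy <- fiy$net
  fix_ <- gen_forward(b$G_yx, batch_x, train = TRUE); b$G_yx <- fix_$net

  dy_fake <- disc_forward(b$D_y, yp, keep_cache = TRUE)
  dx_fake <- disc_forward(b$D_x, xp, keep_cache = TRUE)

  l_gan <- gan_loss(dy_fake$Y, dx_fake$Y)
  l_cycle <- cycle_loss(batch_x, xpp, batch_y, ypp)
  l_id <- identity_loss(batch_x, fix_$Y, batch_y, fiy$Y)

  sym_term <- 0
  sc_yp <- sc_xp <- NULL
  if (lam_s > 0) {
    sc_yp <- smi_score(b$D_smi, yp, keep_cache = TRUE)
    sc_xp <- smi_score(b$D_smi, xp, keep_cache = TRUE)
    sym_term <- mean(sc_yp$s^2) + mean((abs(sc_xp$s) - 1)^2)
  }
  l_gen <- generator_total(l_gan, l_cycle, l_id, sym_term, w)
  if (!is.finite(l_gen))
    stop("divergent training: non-finite generator loss at epoch ",
         state$epoch, " (l_gan=", l_gan, ", l_cycle=", l_cycle,
         ", l_id=", l_id, ")")

  # gradient accumulation on the two synthetic batches
  d_yp <- disc_backward(b$D_y, dy_fake$cache, msq_grad(dy_fake$Y, 1),
                        need_dx = TRUE, need_param_grads = FALSE)$dX
  d_xp <- disc_backward(b$D_x, dx_fake$cache, msq_grad(dx_fake$Y, 1),
                        need_dx = TRUE, need_param_grads = FALSE)$dX

  bcx <- gen_backward(b$G_yx, fcx$cache, w$lambda_c * l1_grad(xpp, batch_x),
                      need_dx = TRUE)
  g_yx <- bcx$grads
  d_yp <- d_yp + bcx$dX
  bcy <- gen_backward(b$G_xy, fcy$cache, w$lambda_c * l1_grad(ypp, batch_y),
                      need_dx = TRUE)
  g_xy <- bcy$grads
  d_xp <- d_xp + bcy$dX

  if (lam_s > 0) {
    n_s <- length(sc_yp$s)
    d_yp <- d_yp + smi_backward(b$D_smi, sc_yp,
                                lam_s * 2 * sc_yp$s / n_s,
                                need_dx = TRUE)$dX
    d_xp <- d_xp + smi_backward(b$D_smi, sc_xp,
                                lam_s * 2 * (abs(sc_xp$s) - 1) *
                                  sign(sc_xp$s) / n_s,
                                need_dx = TRUE)$dX
  }

  g_xy <- add_grads(g_xy, gen_backward(b$G_xy, fiy$cache,
                                       w$lambda_i * l1_grad(fiy$Y, batch_y),
                                       need_dx = FALSE)$grads)
  g_yx <- add_grads(g_yx, gen_backward(b$G_yx, fix_$cache,
                                       w$lambda_i * l1_grad(fix_$Y, batch_x),
                                       need_dx = FALSE)$grads)
  g_xy <- add_grads(g_xy, gen_backward(b$G_xy, fx$cache, d_yp,
                                       need_dx = FALSE)$grads)
  g_yx <- add_grads(g_yx, gen_backward(b$G_yx, fy$cache, d_xp,
                                       need_dx = FALSE)$grads)

  gen_par <- c(prefix_names(net_params(b$G_xy), "xy."),
               prefix_names(net_params(b$G_yx), "yx."))
  gen_grad <- c(prefix_names(g_xy, "xy."), prefix_names(g_yx, "yx."))
  up <- adam_step(gen_par, gen_grad, state$opt$gen, lr,
                  config$beta1, config$beta2)
  state$opt$gen <- up$st
  nxy <- length(net_params(b$G_xy))
  b$G_xy <- net_set_params(b$G_xy, setNames(up$params[seq_len(nxy)],
                                            sub("^xy\\.", "", names(up$params)[seq_len(nxy)])))
  b$G_yx <- net_set_params(b$G_yx, setNames(up$params[-seq_len(nxy)],
                                            sub("^yx\\.", "", names(up$params)[-seq_len(nxy)])))

  ## ---- Step 2: patch discriminators (synthetic slices detached) ----------
  fdy_r <- disc_forward(b$D_y, batch_y); fdy_f <- disc_forward(b$D_y, yp)
  fdx_r <- disc_forward(b$D_x, batch_x); fdx_f <- disc_forward(b$D_x, xp)
  l_dis <- discriminator_loss(fdx_f$Y, fdy_f$Y, fdy_r$Y, fdx_r$Y)
  g_dy <- add_grads(
    disc_backward(b$D_y, fdy_r$cache, msq_grad(fdy_r$Y, 1), FALSE)$grads,
    disc_backward(b$D_y, fdy_f$cache, msq_grad(fdy_f$Y, 0), FALSE)$grads)
  g_dx <- add_grads(
    disc_backward(b$D_x, fdx_r$cache, msq_grad(fdx_r$Y, 1), FALSE)$grads,
    disc_backward(b$D_x, fdx_f$cache, msq_grad(fdx_f$Y, 0), FALSE)$grads)
  up <- adam_step(net_params(b$D_y), g_dy, state$opt$dy, lr,
                  config$beta1, config$beta2)
  state$opt$dy <- up$st; b$D_y <- net_set_params(b$D_y, up$params)
  up <- adam_step(net_params(b$D_x), g_dx, state$opt$dx, lr,
                  config$beta1, config$beta2)
  state$opt$dx <- up$st; b$D_x <- net_set_params(b$D_x, up$params)

  ## ---- Step 3: similarity discriminator ----------------------------------
  l_smi <- NA_real_
  if (use_smi) {
    sc_y <- smi_score(b$D_smi, batch_y, keep_cache = TRUE)
    sc_yp2 <- smi_score(b$D_smi, yp, keep_cache = TRUE)
    sc_x <- smi_score(b$D_smi, batch_x, keep_cache = TRUE)
    sc_xp2 <- smi_score(b$D_smi, xp, keep_cache = TRUE)
    l_smi <- mean(sc_y$s^2) + mean(sc_yp2$s^2) +
      mean((abs(sc_x$s) - 1)^2) + mean((abs(sc_xp2$s) - 1)^2)
    n_s <- length(sc_y$s)
    g_smi <- NULL
    for (it in list(list(sc = sc_y, ds = 2 * sc_y$s / n_s),
                    list(sc = sc_yp2, ds = 2 * sc_yp2$s / n_s),
                    list(sc = sc_x,
                         ds = 2 * (abs(sc_x$s) - 1) * sign(sc_x$s) / n_s),
                    list(sc = sc_xp2,
                         ds = 2 * (abs(sc_xp2$s) - 1) * sign(sc_xp2$s) / n_s)))
      g_smi <- add_grads(g_smi,
                         smi_backward(b$D_smi, it$sc, it$ds, need_dx = FALSE,
                                      need_param_grads = TRUE)$grads)
    up <- adam_step(net_params(b$D_smi), g_smi, state$opt$smi, lr,
                    config$beta1, config$beta2)
    state$opt$smi <- up$st; b$D_smi <- net_set_params(b$D_smi, up$params)
  }

  state$bundle <- b
  report <- data.frame(l_gan = l_gan, l_cycle = l_cycle, l_id = l_id,
                       l_dis = l_dis, l_smi = l_smi, l_gen = l_gen)
  if (!all(is.finite(unlist(report[c("l_gan", "l_cycle", "l_id", "l_dis",
                                     "l_gen")]))))
    stop("divergent training: non-finite loss components")
  list(state = state, report = report)
}

# Stack a list of matrices (or an (H,W,n) array) into (H, W, 1, n).
as_pool_array <- function(pool) {
  if (is.list(pool)) {
    mats <- lapply(pool, function(s) if (inherits(s, "ct_slice")) s$data else s)
    d <- dim(mats[[1]])
    arr <- array(0, c(d[1], d[2], 1L, length(mats)))
    for (i in seq_along(mats)) arr[, , 1L, i] <- mats[[i]]
    arr
  } else if (length(dim(pool)) == 3L) {
    array(pool, c(dim(pool)[1], dim(pool)[2], 1L, dim(pool)[3]))
  } else pool
}

#' Train the translation model on unpaired pools
#'
#' Runs the alternating optimization over reshuffled unpaired pools. Inputs
#' must already be normalized to \[0, 1\] (see [normalize_hu()]); the phantom
#' cohort interface of [symcycle()] handles that automatically.
#'
#' @param pool_x Unhealthy slices: list of matrices/`ct_slice`s, an
#'   `(H, W, n)` array, or an `(H, W, 1, n)` tensor.
#' @param pool_y Healthy slices, same formats.
#' @param gen_spec,disc_spec Architecture specs; see [init_train_state()].
#' @param config A [train_config()].
#' @param verbose Print per-epoch means.
#' @return The final `train_state`, with `loss_history` a data frame of
#'   per-step components.
#' @export
train <- function(pool_x, pool_y, gen_spec, disc_spec,
                  config = train_config(), verbose = FALSE) {
  X <- as_pool_array(pool_x)
  Y <- as_pool_array(pool_y)
  if (dim(X)[4] == 0L || dim(Y)[4] == 0L) stop("empty training pool")
  set.seed(config$seed)
  state <- init_train_state(gen_spec, disc_spec, config)
  if (config$init_output_bias) {
    mbar <- min(max((mean(X) + mean(Y)) / 2, 1e-4), 1 - 1e-4)
    state$bundle$G_xy$fin$b <- stats::qlogis(mbar)
    state$bundle$G_yx$fin$b <- stats::qlogis(mbar)
  }
  n_pair <- min(dim(X)[4], dim(Y)[4])
  steps_per_epoch <- max(1L, n_pair %/% config$batch_size)
  hist <- vector("list", config$total_epochs * steps_per_epoch)
  r <- 0L
  log_con <- NULL
  if (!is.null(config$log_path)) {
    log_con <- file(config$log_path, open = "wt")
    writeLines(paste(c("epoch", "step", "l_gan", "l_cycle", "l_id",
                       "l_dis", "l_smi", "l_gen"), collapse = "\t"), log_con)
    on.exit(close(log_con), add = TRUE)
  }
  for (epoch in seq_len(config$total_epochs)) {
    state$epoch <- epoch
    lr <- lr_at_epoch(epoch, config)
    ord_x <- sample.int(dim(X)[4])
    ord_y <- sample.int(dim(Y)[4])
    for (s in seq_len(steps_per_epoch)) {
      take <- ((s - 1L) * config$batch_size + 1L):
        min(s * config$batch_size, n_pair)
      bx <- X[, , , ord_x[take], drop = FALSE]
      by <- Y[, , , ord_y[take], drop = FALSE]
      res <- train_step(bx, by, state, config, lr = lr)
      state <- res$state
      r <- r + 1L
      rep_row <- cbind(epoch = epoch, step = s, res$report)
      hist[[r]] <- rep_row
      if (!is.null(log_con))
        writeLines(paste(unlist(rep_row), collapse = "\t"), log_con)
    }
    if (verbose) {
      em <- do.call(rbind, hist[(r - steps_per_epoch + 1L):r])
      message(sprintf("epoch %3d lr %.2e l_gen %.4f l_gan %.4f l_dis %.4f",
                      epoch, lr, mean(em$l_gen), mean(em$l_gan),
                      mean(em$l_dis)))
    }
    if (!is.null(config$checkpoint_dir) &&
        (!is.null(config$checkpoint_every) &&
         epoch %% config$checkpoint_every == 0L ||
         epoch == config$total_epochs)) {
      dir.create(config$checkpoint_dir, showWarnings = FALSE,
                 recursive = TRUE)
      save_checkpoint(state, file.path(config$checkpoint_dir,
                                       sprintf("epoch_%04d.rds", epoch)))
    }
  }
  state$loss_history <- do.call(rbind, hist[seq_len(r)])
  state
}

#' Save / load a training checkpoint
#'
#' Checkpoints embed the full network bundle (with architecture specs),
#' optimizer state and epoch counter; a round-trip restores bit-identical
#' forward passes.
#'
#' @param state A `train_state` (or fitted `symcycle` model).
#' @param path File path.
#' @return `load_checkpoint` returns the restored object.
#' @export
save_checkpoint <- function(state, path) {
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  readRDS(path)
}
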