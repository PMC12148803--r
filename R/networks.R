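# Network constructors and hand-written forward/backward passes.
#
# Two generators translate between tumor-bearing ("unhealthy", x) and
# tumor-free ("healthy", y) slices; two patch discriminators judge realism;
# a third discriminator scores left/right lung-half similarity.

#' Generator architecture description
#'
#' The generator is a U-Net: an entry convolution (stride 1) producing
#' `base_channels` feature maps, `depth` down-sampling steps that halve the
#' spatial size and double the channel count, and `depth` mirrored
#' up-sampling steps with skip connections concatenating same-resolution
#' encoder features. All convolutions are 3x3 with padding 1; batch
#' normalization and leaky-ReLU follow every convolution; the output layer
#' maps back to one channel through a logistic activation so outputs stay in
#' \[0, 1\] like the normalized inputs.
#'
#' @param input_size Image side in pixels; must be divisible by
#'   `2^depth`. Default 512, the full CT resolution.
#' @param base_channels Feature maps produced by the entry layer (default 32).
#' @param depth Number of down/up-sampling steps (default 4).
#' @param kernel Convolution kernel size (default 3).
#' @param slope Negative slope of the leaky-ReLU (default 0.2).
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(input_size = 512L, base_channels = 32L,
                           depth = 4L, kernel = 3L, slope = 0.2) {
  input_size <- as.integer(input_size)
  depth <- as.integer(depth)
  if (input_size %% (2L^depth) != 0L)
    stop("input_size (", input_size, ") must be divisible by 2^depth (",
         2L^depth, ")")
  if (base_channels < 1L || depth < 1L) stop("base_channels and depth must be >= 1")
  structure(list(input_size = input_size,
                 base_channels = as.integer(base_channels),
                 depth = depth, kernel = as.integer(kernel), slope = slope),
            class = "generator_spec")
}

#' Discriminator architecture description
#'
#' A patch discriminator: an entry convolution to `first_channels` maps
#' (no normalization), then `n_downsamples` stride-2 convolutions each
#' doubling the channels, with instance normalization and leaky-ReLU, and a
#' final convolution to a single-channel score map. With the default three
#' down-samplings the score map is 1/8 of the input in each dimension
#' (512x512 input gives a 64x64x1 map).
#'
#' @param input_height,input_width Input size in pixels; each must be
#'   divisible by `2^n_downsamples`.
#' @param first_channels Feature maps of the entry layer (default 64).
#' @param n_downsamples Number of stride-2 layers (default 3).
#' @param kernel,slope As in [generator_spec()].
#' @return An object of class `discriminator_spec`.
#' @export
discriminator_spec <- function(input_height = 512L, input_width = 512L,
                               first_channels = 64L, n_downsamples = 3L,
                               kernel = 3L, slope = 0.2) {
  input_height <- as.integer(input_height)
  input_width <- as.integer(input_width)
  n_downsamples <- as.integer(n_downsamples)
  div <- 2L^n_downsamples
  if (input_height %% div != 0L || input_width %% div != 0L)
    stop("input size ", input_height, "x", input_width,
         " not divisible by 2^n_downsamples (", div, ")")
  structure(list(input_height = input_height, input_width = input_width,
                 first_channels = as.integer(first_channels),
                 n_downsamples = n_downsamples,
                 kernel = as.integer(kernel), slope = slope),
            class = "discriminator_spec")
}

init_W <- function(k, cin, cout) {
  matrix(stats::rnorm(k * k * cin * cout, sd = 0.02), nrow = k * k * cin)
}

#' Build a generator network
#'
#' Instantiates the U-Net described by a [generator_spec()] with randomly
#' initialized weights (N(0, 0.02^2), drawn from the current RNG stream).
#'
#' @param spec A [generator_spec()].
#' @return An object of class `gen_net` holding all layer parameters.
#' @export
build_generator <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  k <- spec$kernel; b <- spec$base_channels; D <- spec$depth
  enc <- vector("list", D + 1L)
  # channels: entry 1 -> b; down j: b*2^(j-1) -> b*2^j
  chans <- c(1L, b * 2L^(0:D))
  for (i in seq_len(D + 1L)) {
    cout <- chans[i + 1L]
    enc[[i]] <- list(W = init_W(k, chans[i], cout), b = numeric(cout),
                     gamma = rep(1, cout), beta = numeric(cout),
                     rm = numeric(cout), rv = rep(1, cout))
  }
  dec <- vector("list", D)
  for (i in seq_len(D)) {            # i-th decoder step handles level D-i+1
    lvl <- D - i + 1L
    cin <- b * 2L^lvl
    cout <- b * 2L^(lvl - 1L)
    # transposed-conv weights live on the upsampled (cout-channel) canvas:
    # shape ((k*k*cout) x cin)
    dec[[i]] <- list(tW = init_W(k, cout, cin), tb = numeric(cout),
                     g1 = rep(1, cout), b1 = numeric(cout),
                     rm1 = numeric(cout), rv1 = rep(1, cout),
                     W = init_W(k, 2L * cout, cout), b = numeric(cout),
                     g2 = rep(1, cout), b2 = numeric(cout),
                     rm2 = numeric(cout), rv2 = rep(1, cout))
  }
  fin <- list(W = init_W(k, b, 1L), b = numeric(1L))
  structure(list(spec = spec, enc = enc, dec = dec, fin = fin),
            class = "gen_net")
}

#' Build a patch discriminator
#'
#' @param spec A [discriminator_spec()].
#' @return An object of class `disc_net`.
#' @export
build_patch_discriminator <- function(spec) {
  stopifnot(inherits(spec, "discriminator_spec"))
  k <- spec$kernel; f <- spec$first_channels; nd <- spec$n_downsamples
  chans <- c(1L, f * 2L^(0:nd))
  layers <- vector("list", nd + 2L)
  layers[[1L]] <- list(W = init_W(k, 1L, f), b = numeric(f), stride = 1L,
                       norm = FALSE)
  for (i in seq_len(nd)) {
    cin <- chans[i + 1L]; cout <- chans[i + 2L]
    layers[[i + 1L]] <- list(W = init_W(k, cin, cout), b = numeric(cout),
                             stride = 2L, norm = TRUE,
                             gamma = rep(1, cout), beta = numeric(cout))
  }
  layers[[nd + 2L]] <- list(W = init_W(k, chans[nd + 2L], 1L), b = numeric(1L),
                            stride = 1L, norm = FALSE, final = TRUE)
  structure(list(spec = spec, layers = layers), class = "disc_net")
}

#' Build the lung-symmetry discriminator
#'
#' Same layer recipe as [build_patch_discriminator()], applied to half-width
#' inputs (a left or mirrored right lung half). Its score maps are reduced to
#' a scalar symmetry score by spatial averaging in [smi_score()].
#'
#' @param spec A [discriminator_spec()] whose `input_width` is half the slice
#'   width.
#' @return An object of class `disc_net`.
#' @export
build_similarity_discriminator <- function(spec) {
  build_patch_discriminator(spec)
}

# ---- forward / backward ----------------------------------------------------

#' Generator forward pass
#'
#' @param net A `gen_net`.
#' @param X Input tensor `(H, W, 1, N)` (or a plain `H x W` matrix) with
#'   values in \[0, 1\].
#' @param train Logical; use batch statistics (and update running averages)
#'   in batch normalization.
#' @param keep_cache Logical; retain intermediate values for a backward pass.
#' @return List with `Y` (same shape as input), `cache`, and the (possibly
#'   updated) `net`.
#' @export
gen_forward <- function(net, X, train = TRUE, keep_cache = train) {
  was_matrix <- is.matrix(X)
  if (was_matrix) X <- array(X, c(dim(X), 1L, 1L))
  sp <- net$spec; k <- sp$kernel; sl <- sp$slope; D <- sp$depth
  d <- dim(X)
  if (d[1] %% 2L^D != 0L || d[2] %% 2L^D != 0L)
    stop("input ", d[1], "x", d[2], " not divisible by 2^depth (", 2L^D, ")")
  cache <- if (keep_cache) list(enc = vector("list", D + 1L),
                                dec = vector("list", D)) else NULL
  skips <- vector("list", D)
  h <- X
  for (i in seq_len(D + 1L)) {
    blk <- net$enc[[i]]
    s <- if (i == 1L) 1L else 2L
    a <- conv_fwd(h, blk$W, blk$b, k, s, 1L)
    bn <- bn_fwd(a, blk$gamma, blk$beta, blk$rm, blk$rv, train = train)
    net$enc[[i]]$rm <- bn$rm; net$enc[[i]]$rv <- bn$rv
    z <- lrelu_fwd(bn$Y, sl)
    if (keep_cache) cache$enc[[i]] <- list(x = h, bnin = bn$Y, bn = bn$cache)
    if (i <= D) skips[[i]] <- z
    h <- z
  }
  for (i in seq_len(D)) {
    blk <- net$dec[[i]]
    lvl <- D - i + 1L
    tin <- h
    a1 <- tconv_fwd(h, blk$tW, blk$tb, k, 1L)
    bn1 <- bn_fwd(a1, blk$g1, blk$b1, blk$rm1, blk$rv1, train = train)
    net$dec[[i]]$rm1 <- bn1$rm; net$dec[[i]]$rv1 <- bn1$rv
    z1 <- lrelu_fwd(bn1$Y, sl)
    cc <- cat_channels(z1, skips[[lvl]])
    a2 <- conv_fwd(cc, blk$W, blk$b, k, 1L, 1L)
    bn2 <- bn_fwd(a2, blk$g2, blk$b2, blk$rm2, blk$rv2, train = train)
    net$dec[[i]]$rm2 <- bn2$rm; net$dec[[i]]$rv2 <- bn2$rv
    z2 <- lrelu_fwd(bn2$Y, sl)
    if (keep_cache)
      cache$dec[[i]] <- list(tin = tin, bn1in = bn1$Y, bn1 = bn1$cache,
                             cc = cc, bn2in = bn2$Y, bn2 = bn2$cache,
                             nA = dim(z1)[3])
    h <- z2
  }
  pre <- conv_fwd(h, net$fin$W, net$fin$b, k, 1L, 1L)
  Y <- sigmoid_fwd(pre)
  if (keep_cache) { cache$fin_x <- h; cache$Y <- Y }
  out <- if (was_matrix) Y[, , 1L, 1L] else Y
  list(Y = out, cache = cache, net = net)
}

#' Generator backward pass
#'
#' Backpropagates a gradient with respect to the generator output through the
#' cached forward pass, returning parameter gradients (named like the
#' parameter vector of [net_params()]) and optionally the input gradient.
#'
#' @param net A `gen_net`.
#' @param cache Cache from [gen_forward()] with `keep_cache = TRUE`.
#' @param dY Gradient w.r.t. the output, same shape as the output tensor.
#' @param need_dx Return the gradient w.r.t. the input.
#' @return List with `grads` (named list) and `dX` (or NULL).
#' @export
gen_backward <- function(net, cache, dY, need_dx = TRUE) {
  sp <- net$spec; k <- sp$kernel; sl <- sp$slope; D <- sp$depth
  grads <- list()
  dpre <- sigmoid_bwd(cache$Y, dY)
  cb <- conv_bwd(cache$fin_x, net$fin$W, dpre, k, 1L, 1L, TRUE)
  grads[["fin.W"]] <- cb$dWm; grads[["fin.b"]] <- cb$db
  dh <- cb$dX
  dskips <- vector("list", D)
  for (i in rev(seq_len(D))) {
    blk <- net$dec[[i]]; ch <- cache$dec[[i]]
    lvl <- D - i + 1L
    dz2 <- dh
    dbn2 <- lrelu_bwd(ch$bn2in, dz2, sl)
    bb2 <- bn_bwd(ch$bn2, blk$g2, dbn2)
    grads[[paste0("dec", i, ".g2")]] <- bb2$dgamma
    grads[[paste0("dec", i, ".b2")]] <- bb2$dbeta
    cb <- conv_bwd(ch$cc, blk$W, bb2$dX, k, 1L, 1L, TRUE)
    grads[[paste0("dec", i, ".W")]] <- cb$dWm
    grads[[paste0("dec", i, ".b")]] <- cb$db
    sp2 <- split_channels(cb$dX, ch$nA)
    dskips[[lvl]] <- sp2$B
    dbn1 <- lrelu_bwd(ch$bn1in, sp2$A, sl)
    bb1 <- bn_bwd(ch$bn1, blk$g1, dbn1)
    grads[[paste0("dec", i, ".g1")]] <- bb1$dgamma
    grads[[paste0("dec", i, ".b1")]] <- bb1$dbeta
    tb <- tconv_bwd(ch$tin, blk$tW, bb1$dX, k, 1L, TRUE)
    grads[[paste0("dec", i, ".tW")]] <- tb$dWm
    grads[[paste0("dec", i, ".tb")]] <- tb$db
    dh <- tb$dX
  }
  for (i in rev(seq_len(D + 1L))) {
    blk <- net$enc[[i]]; ch <- cache$enc[[i]]
    if (i <= D) dh <- dh + dskips[[i]]
    dbn <- lrelu_bwd(ch$bnin, dh, sl)
    bb <- bn_bwd(ch$bn, blk$gamma, dbn)
    grads[[paste0("enc", i, ".gamma")]] <- bb$dgamma
    grads[[paste0("enc", i, ".beta")]] <- bb$dbeta
    s <- if (i == 1L) 1L else 2L
    cb <- conv_bwd(ch$x, blk$W, bb$dX, k, s, 1L,
                   need_dx = (i > 1L) || need_dx)
    grads[[paste0("enc", i, ".W")]] <- cb$dWm
    grads[[paste0("enc", i, ".b")]] <- cb$db
    dh <- cb$dX
  }
  list(grads = grads, dX = dh)
}

#' Discriminator forward pass
#'
#' @param net A `disc_net`.
#' @param X Input tensor `(H, W, 1, N)` or matrix.
#' @param keep_cache Retain intermediates for [disc_backward()].
#' @return List with score map `Y` (`(H/2^nd, W/2^nd, 1, N)`), `cache`.
#' @export
disc_forward <- function(net, X, keep_cache = TRUE) {
  if (is.matrix(X)) X <- array(X, c(dim(X), 1L, 1L))
  sp <- net$spec; k <- sp$kernel; sl <- sp$slope
  d <- dim(X)
  div <- 2L^sp$n_downsamples
  if (d[1] %% div != 0L || d[2] %% div != 0L)
    stop("input ", d[1], "x", d[2], " not divisible by 2^n_downsamples (",
         div, ")")
  cache <- if (keep_cache) vector("list", length(net$layers)) else NULL
  h <- X
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    a <- conv_fwd(h, ly$W, ly$b, k, ly$stride, 1L)
    if (isTRUE(ly$final)) {
      if (keep_cache) cache[[i]] <- list(x = h)
      h <- a
      break
    }
    if (ly$norm) {
      nf <- in_fwd(a, ly$gamma, ly$beta)
      z <- lrelu_fwd(nf$Y, sl)
      if (keep_cache) cache[[i]] <- list(x = h, nin = nf$Y, nf = nf$cache)
    } else {
      z <- lrelu_fwd(a, sl)
      if (keep_cache) cache[[i]] <- list(x = h, nin = a)
    }
    h <- z
  }
  list(Y = h, cache = cache)
}

#' Discriminator backward pass
#'
#' @param net A `disc_net`; `cache` from [disc_forward()]; `dY` gradient on
#'   the score map.
#' @param need_dx Return input gradient (needed when the gradient continues
#'   into a generator).
#' @param need_param_grads Collect parameter gradients (FALSE when the
#'   discriminator is frozen and only the input gradient is wanted).
#' @return List with `grads` and `dX`.
#' @export
disc_backward <- function(net, cache, dY, need_dx = TRUE,
                          need_param_grads = TRUE) {
  sp <- net$spec; k <- sp$kernel; sl <- sp$slope
  grads <- list()
  nl <- length(net$layers)
  dh <- dY
  for (i in rev(seq_len(nl))) {
    ly <- net$layers[[i]]; ch <- cache[[i]]
    if (!isTRUE(ly$final)) {
      dh <- lrelu_bwd(ch$nin, dh, sl)
      if (ly$norm) {
        bb <- in_bwd(ch$nf, ly$gamma, dh)
        if (need_param_grads) {
          grads[[paste0("l", i, ".gamma")]] <- bb$dgamma
          grads[[paste0("l", i, ".beta")]] <- bb$dbeta
        }
        dh <- bb$dX
      }
    }
    cb <- conv_bwd(ch$x, ly$W, dh, k, ly$stride, 1L,
                   need_dx = (i > 1L) || need_dx)
    if (need_param_grads) {
      grads[[paste0("l", i, ".W")]] <- cb$dWm
      grads[[paste0("l", i, ".b")]] <- cb$db
    }
    dh <- cb$dX
  }
  list(grads = grads, dX = dh)
}

#' Split a slice into its left half and mirrored right half
#'
#' Both halves come out in the same medial-to-lateral orientation, so a
#' perfectly mirror-symmetric slice yields two identical arrays. Works on a
#' matrix or an `(H, W, C, N)` tensor (split along columns).
#'
#' @param x Matrix or 4-d array with even width.
#' @return List with `left` and `right` (mirrored).
#' @export
split_halves <- function(x) {
  d <- if (is.matrix(x)) dim(x) else dim(x)[1:2]
  W <- d[2]
  if (W %% 2L != 0L) stop("slice width ", W, " is odd; cannot split halves")
  h <- W %/% 2L
  if (is.matrix(x)) {
    list(left = x[, seq_len(h), drop = FALSE],
         right = x[, W:(h + 1L), drop = FALSE])
  } else {
    list(left = x[, seq_len(h), , , drop = FALSE],
         right = x[, W:(h + 1L), , , drop = FALSE])
  }
}

#' Scalar symmetry scores from the similarity discriminator
#'
#' For each sample, the discriminator is applied to the left half and the
#' mirrored right half; the score maps are averaged spatially and the
#' difference `mean(D(left)) - mean(D(right_mirrored))` is returned. A value
#' near 0 means the discriminator finds the halves alike.
#'
#' @param net The similarity `disc_net`.
#' @param X Tensor `(H, W, 1, N)` or matrix with even width.
#' @param keep_cache Retain caches (for training the generators through the
#'   score).
#' @return List with `s` (length-N vector), and when `keep_cache`, the two
#'   forward caches and half dimensions.
#' @export
smi_score <- function(net, X, keep_cache = FALSE) {
  if (is.matrix(X)) X <- array(X, c(dim(X), 1L, 1L))
  hs <- split_halves(X)
  fl <- disc_forward(net, hs$left, keep_cache = keep_cache)
  fr <- disc_forward(net, hs$right, keep_cache = keep_cache)
  dmap <- dim(fl$Y)
  per_n <- function(Y) colMeans(matrix(Y, ncol = dim(Y)[4]))
  s <- per_n(fl$Y) - per_n(fr$Y)
  if (!keep_cache) return(list(s = s))
  list(s = s, cache_l = fl$cache, cache_r = fr$cache, map_dim = dmap)
}

# Backpropagate d(loss)/d(s) through the similarity score into the full-width
# input. Returns dX (H, W, 1, N) and, if requested, parameter grads summed
# over both halves.
smi_backward <- function(net, sc, ds, need_dx = TRUE,
                         need_param_grads = FALSE) {
  md <- sc$map_dim
  m <- md[1] * md[2]
  # d s_n / d map_l = 1/m ; d s_n / d map_r = -1/m  (per sample n)
  dmap_l <- array(rep(ds, each = m) / m, md)
  dmap_r <- array(rep(-ds, each = m) / m, md)
  bl <- disc_backward(net, sc$cache_l, dmap_l, need_dx = need_dx,
                      need_param_grads = need_param_grads)
  br <- disc_backward(net, sc$cache_r, dmap_r, need_dx = need_dx,
                      need_param_grads = need_param_grads)
  grads <- NULL
  if (need_param_grads) {
    grads <- bl$grads
    for (nm in names(br$grads)) grads[[nm]] <- grads[[nm]] + br$grads[[nm]]
  }
  dX <- NULL
  if (need_dx) {
    dl <- bl$dX; dr <- br$dX
    d <- dim(dl)
    W2 <- 2L * d[2]
    dX <- array(0, c(d[1], W2, d[3], d[4]))
    dX[, seq_len(d[2]), , ] <- dl
    dX[, W2:(d[2] + 1L), , ] <- dr   # un-mirror the right-half gradient
  }
  list(dX = dX, grads = grads)
}

#' Bundle the five networks of the translation model
#'
#' @param gen_spec A [generator_spec()] shared by both generators.
#' @param disc_spec A [discriminator_spec()] shared by `D_x` and `D_y`.
#' @param smi_spec A [discriminator_spec()] for the similarity discriminator;
#'   by default derived from `disc_spec` with half the width. May be `NULL`
#'   when the similarity branch is disabled.
#' @return An object of class `network_bundle` with elements `G_xy`, `G_yx`,
#'   `D_x`, `D_y`, `D_smi`.
#' @export
network_bundle <- function(gen_spec, disc_spec, smi_spec = NULL) {
  if (is.null(smi_spec)) {
    if (disc_spec$input_width %% 2L != 0L)
      stop("slice width ", disc_spec$input_width,
           " is odd; similarity discriminator needs an even width")
    smi_spec <- discriminator_spec(
      input_height = disc_spec$input_height,
      input_width = disc_spec$input_width %/% 2L,
      first_channels = disc_spec$first_channels,
      n_downsamples = disc_spec$n_downsamples,
      kernel = disc_spec$kernel, slope = disc_spec$slope)
  }
  structure(list(G_xy = build_generator(gen_spec),
                 G_yx = build_generator(gen_spec),
                 D_x = build_patch_discriminator(disc_spec),
                 D_y = build_patch_discriminator(disc_spec),
                 D_smi = build_similarity_discriminator(smi_spec)),
            class = "network_bundle")
}

# ---- flat parameter access (for the optimizer and for coef()) -------------

net_params <- function(net) {
  out <- list()
  if (inherits(net, "gen_net")) {
    for (i in seq_along(net$enc))
      for (nm in c("W", "b", "gamma", "beta"))
        out[[paste0("enc", i, ".", nm)]] <- net$enc[[i]][[nm]]
    for (i in seq_along(net$dec))
      for (nm in c("tW", "tb", "g1", "b1", "W", "b", "g2", "b2"))
        out[[paste0("dec", i, ".", nm)]] <- net$dec[[i]][[nm]]
    out[["fin.W"]] <- net$fin$W; out[["fin.b"]] <- net$fin$b
  } else {
    for (i in seq_along(net$layers)) {
      ly <- net$layers[[i]]
      out[[paste0("l", i, ".W")]] <- ly$W
      out[[paste0("l", i, ".b")]] <- ly$b
      if (isTRUE(ly$norm)) {
        out[[paste0("l", i, ".gamma")]] <- ly$gamma
        out[[paste0("l", i, ".beta")]] <- ly$beta
      }
    }
  }
  out
}

net_set_params <- function(net, params) {
  if (inherits(net, "gen_net")) {
    for (i in seq_along(net$enc))
      for (nm in c("W", "b", "gamma", "beta"))
        net$enc[[i]][[nm]] <- params[[paste0("enc", i, ".", nm)]]
    for (i in seq_along(net$dec))
      for (nm in c("tW", "tb", "g1", "b1", "W", "b", "g2", "b2"))
        net$dec[[i]][[nm]] <- params[[paste0("dec", i, ".", nm)]]
    net$fin$W <- params[["fin.W"]]; net$fin$b <- params[["fin.b"]]
  } else {
    for (i in seq_along(net$layers)) {
      net$layers[[i]]$W <- params[[paste0("l", i, ".W")]]
      net$layers[[i]]$b <- params[[paste0("l", i, ".b")]]
      if (isTRUE(net$layers[[i]]$norm)) {
        net$layers[[i]]$gamma <- params[[paste0("l", i, ".gamma")]]
        net$layers[[i]]$beta <- params[[paste0("l", i, ".beta")]]
      }
    }
  }
  net
}
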