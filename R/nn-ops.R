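# Low-level tensor primitives for the translation networks.
#
# Tensors are dense double arrays with dim (H, W, C, N): rows, columns,
# channels, batch. Convolutions are evaluated as im2col + BLAS gemm; the
# gather/scatter/layout steps run in C++ (src/tensor_kernels.cpp) and the
# column-index tables, which depend only on the geometry, are cached per
# shape.

.idx_cache <- new.env(parent = emptyenv())

# Geometry + linear-index table for a convolution. `idx` maps patch element
# (dr, dc, channel) x output position (oi, oj, sample), column-major, to a
# linear index into the zero-padded input array.
conv_geom <- function(H, W, C, k, s, p, N) {
  key <- paste(H, W, C, k, s, p, N, sep = ".")
  g <- .idx_cache[[key]]
  if (!is.null(g)) return(g)
  Hp <- H + 2L * p
  Wp <- W + 2L * p
  if (Hp < k || Wp < k)
    stop("input ", H, "x", W, " too small for kernel ", k)
  Ho <- (Hp - k) %/% s + 1L
  Wo <- (Wp - k) %/% s + 1L
  if (as.double(Hp) * Wp * C * N >= .Machine$integer.max)
    stop("tensor of dim ", Hp, "x", Wp, "x", C, "x", N, " exceeds index range")
  dr <- rep.int(0:(k - 1L), k)
  dc <- rep(0:(k - 1L), each = k)
  within <- rep(dr + Hp * dc, C) + rep(Hp * Wp * (0:(C - 1L)), each = k * k)
  oi <- s * (0:(Ho - 1L))
  oj <- s * (0:(Wo - 1L))
  pos <- rep(oi, Wo) + Hp * rep(oj, each = Ho)
  if (N > 1L)
    pos <- rep(pos, N) + Hp * Wp * C * rep(0:(N - 1L), each = Ho * Wo)
  idx <- outer(as.integer(within), as.integer(pos), `+`) + 1L
  dim(idx) <- NULL
  g <- list(idx = idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp,
            k2C = k * k * C, plen = as.double(Hp) * Wp * C * N)
  .idx_cache[[key]] <- g
  g
}

# Forward convolution: X (H,W,C,N), Wm ((k*k*C) x F), b length F.
# Returns (Ho, Wo, F, N).
conv_fwd <- function(X, Wm, b, k, s, p) {
  d <- dim(X)
  g <- conv_geom(d[1], d[2], d[3], k, s, p, d[4])
  Xp <- cpp_pad4(X, d[1], d[2], d[3], d[4], p)
  M <- cpp_gather(Xp, g$idx, g$k2C)
  Fch <- ncol(Wm)
  Y <- crossprod(Wm, M) + b
  out <- cpp_chlast(Y, g$Ho * g$Wo, Fch, d[4])
  dim(out) <- c(g$Ho, g$Wo, Fch, d[4])
  out
}

# Backward convolution. Returns list(dX, dWm, db); dX omitted when need_dx is
# FALSE (first layer of a network trained on fixed inputs).
conv_bwd <- function(X, Wm, dY, k, s, p, need_dx = TRUE) {
  d <- dim(X)
  dd <- dim(dY)
  g <- conv_geom(d[1], d[2], d[3], k, s, p, d[4])
  Fch <- dd[3]
  dYmat <- cpp_chfirst(dY, dd[1] * dd[2], Fch, dd[4])
  Xp <- cpp_pad4(X, d[1], d[2], d[3], d[4], p)
  M <- cpp_gather(Xp, g$idx, g$k2C)
  dWm <- tcrossprod(M, dYmat)
  db <- rowSums(dYmat)
  dX <- NULL
  if (need_dx) {
    dM <- Wm %*% dYmat
    dXp <- cpp_scatter_add(g$idx, dM, g$plen)
    dX <- cpp_unpad4(dXp, d[1], d[2], d[3], d[4], p)
    dim(dX) <- d
  }
  list(dX = dX, dWm = dWm, db = db)
}

# Transposed convolution, stride 2, kernel k, pad p: exact spatial doubling
# (output_padding 1 in the usual framework convention). Weight Wm is
# ((k*k*Cout) x Cin); forward is the adjoint of a stride-2 convolution from
# the (2H, 2W, Cout) canvas down to (H, W, Cin).
tconv_fwd <- function(X, Wm, b, k, p) {
  d <- dim(X)
  H2 <- 2L * d[1]; W2 <- 2L * d[2]
  Cout <- nrow(Wm) %/% (k * k)
  g <- conv_geom(H2, W2, Cout, k, 2L, p, d[4])
  stopifnot(g$Ho == d[1], g$Wo == d[2])
  Xmat <- cpp_chfirst(X, d[1] * d[2], d[3], d[4])
  dM <- Wm %*% Xmat
  Yp <- cpp_scatter_add(g$idx, dM, g$plen)
  Y <- cpp_unpad4(Yp, H2, W2, Cout, d[4], p)
  dim(Y) <- c(H2, W2, Cout, d[4])
  Y + rep(b, each = H2 * W2)
}

tconv_bwd <- function(X, Wm, dY, k, p, need_dx = TRUE) {
  d <- dim(X)
  dd <- dim(dY)
  Cout <- dd[3]
  g <- conv_geom(dd[1], dd[2], Cout, k, 2L, p, d[4])
  dYp <- cpp_pad4(dY, dd[1], dd[2], Cout, dd[4], p)
  Mg <- cpp_gather(dYp, g$idx, g$k2C)
  Xmat <- cpp_chfirst(X, d[1] * d[2], d[3], d[4])
  dWm <- tcrossprod(Mg, Xmat)
  db <- rowSums(cpp_chfirst(dY, dd[1] * dd[2], Cout, dd[4]))
  dX <- NULL
  if (need_dx) {
    dXmat <- crossprod(Wm, Mg)
    dX <- cpp_chlast(dXmat, d[1] * d[2], d[3], d[4])
    dim(dX) <- d
  }
  list(dX = dX, dWm = dWm, db = db)
}

lrelu_fwd <- function(X, slope) {
  Y <- cpp_lrelu(X, slope)
  dim(Y) <- dim(X)
  Y
}

lrelu_bwd <- function(X, dY, slope) {
  dX <- cpp_lrelu_grad(X, dY, slope)
  dim(dX) <- dim(X)
  dX
}

sigmoid_fwd <- function(X) 1 / (1 + exp(-X))
sigmoid_bwd <- function(Y, dY) dY * Y * (1 - Y)

# Batch normalization over (H, W, N) per channel. Returns the output, a
# backward cache and updated running statistics. Uses biased batch variance
# (the usual convention) and running-average momentum 0.1.
bn_fwd <- function(X, gamma, beta, rm, rv, eps = 1e-5, train = TRUE,
                   momentum = 0.1) {
  d <- dim(X)
  C <- d[3]; N <- d[4]
  Xm <- matrix(X, ncol = C * N)
  if (train) {
    cs <- colMeans(Xm)
    cq <- colMeans(Xm * Xm)
    mu <- rowMeans(matrix(cs, C, N))
    va <- rowMeans(matrix(cq, C, N)) - mu^2
    rm <- (1 - momentum) * rm + momentum * mu
    rv <- (1 - momentum) * rv + momentum * va
  } else {
    mu <- rm; va <- rv
  }
  invsd <- 1 / sqrt(va + eps)
  HW <- d[1] * d[2]
  # y = a*x + c with per-channel a = gamma*invsd, c = beta - mu*a
  a <- gamma * invsd
  xhat <- Xm * rep(rep(invsd, N), each = HW) -
    rep(rep(mu * invsd, N), each = HW)
  Y <- Xm * rep(rep(a, N), each = HW) +
    rep(rep(beta - mu * a, N), each = HW)
  list(Y = array(Y, d), cache = list(xhat = xhat, invsd = invsd, d = d),
       rm = rm, rv = rv)
}

bn_bwd <- function(cache, gamma, dY) {
  d <- cache$d
  C <- d[3]; N <- d[4]
  HW <- d[1] * d[2]
  m <- HW * N                     # elements per channel
  dYm <- matrix(dY, ncol = C * N)
  dxhat <- dYm * rep(rep(gamma, N), each = HW)
  s1 <- rowSums(matrix(colSums(dxhat), C, N))
  s2 <- rowSums(matrix(colSums(dxhat * cache$xhat), C, N))
  dgamma <- rowSums(matrix(colSums(dYm * cache$xhat), C, N))
  dbeta <- rowSums(matrix(colSums(dYm), C, N))
  dX <- (dxhat - rep(rep(s1, N) / m, each = HW) -
           cache$xhat * rep(rep(s2, N) / m, each = HW)) *
    rep(rep(cache$invsd, N), each = HW)
  list(dX = array(dX, d), dgamma = dgamma, dbeta = dbeta)
}

# Instance normalization: per channel AND sample over (H, W). No running
# statistics (the usual discriminator convention).
in_fwd <- function(X, gamma, beta, eps = 1e-5) {
  d <- dim(X)
  C <- d[3]; N <- d[4]
  Xm <- matrix(X, ncol = C * N)
  mu <- colMeans(Xm)
  va <- colMeans(Xm * Xm) - mu^2
  invsd <- 1 / sqrt(va + eps)
  HW <- d[1] * d[2]
  xhat <- Xm * rep(invsd, each = HW) - rep(mu * invsd, each = HW)
  a <- invsd * rep(gamma, N)
  Y <- Xm * rep(a, each = HW) + rep(rep(beta, N) - mu * a, each = HW)
  list(Y = array(Y, d), cache = list(xhat = xhat, invsd = invsd, d = d))
}

in_bwd <- function(cache, gamma, dY) {
  d <- cache$d
  C <- d[3]; N <- d[4]
  HW <- d[1] * d[2]
  dYm <- matrix(dY, ncol = C * N)
  dxhat <- dYm * rep(rep(gamma, N), each = HW)
  s1 <- colMeans(dxhat)
  s2 <- colMeans(dxhat * cache$xhat)
  dgamma <- rowSums(matrix(colSums(dYm * cache$xhat), C, N))
  dbeta <- rowSums(matrix(colSums(dYm), C, N))
  dX <- (dxhat - rep(s1, each = HW) - cache$xhat * rep(s2, each = HW)) *
    rep(cache$invsd, each = HW)
  list(dX = array(dX, d), dgamma = dgamma, dbeta = dbeta)
}

# Channel concatenation and its split (U-Net skip connections).
cat_channels <- function(A, B) {
  da <- dim(A); db <- dim(B)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- A
  out[, , da[3] + seq_len(db[3]), ] <- B
  out
}

split_channels <- function(X, nA) {
  d <- dim(X)
  list(A = X[, , seq_len(nA), , drop = FALSE],
       B = X[, , (nA + 1L):d[3], , drop = FALSE])
}
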