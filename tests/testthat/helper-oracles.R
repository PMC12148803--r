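# Independent brute-force oracles used across the suite.

# Otsu by exhaustive search: try every bin edge of a 256-bin histogram over
# the value range and maximize between-class variance directly.
oracle_otsu <- function(x, nbins = 256L) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(NA_real_)
  edges <- seq(lo, hi, length.out = nbins + 1L)
  mids <- (edges[-1L] + edges[-(nbins + 1L)]) / 2
  counts <- tabulate(findInterval(x, edges, all.inside = TRUE), nbins)
  best <- -Inf; best_t <- NA_real_
  for (k in 1:(nbins - 1L)) {
    n0 <- sum(counts[1:k]); n1 <- sum(counts) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:k] * mids[1:k]) / n0
    mu1 <- sum(counts[(k + 1):nbins] * mids[(k + 1):nbins]) / n1
    v <- (n0 / sum(counts)) * (n1 / sum(counts)) * (mu0 - mu1)^2
    if (v > best) { best <- v; best_t <- edges[k + 1L] }
  }
  best_t
}

# Directed nearest-neighbor distances by explicit double loop.
oracle_nn <- function(A, B) {
  out <- numeric(nrow(A))
  for (i in seq_len(nrow(A))) {
    best <- Inf
    for (j in seq_len(nrow(B)))
      best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
    out[i] <- best
  }
  out
}

oracle_hd95 <- function(P, G) {
  max(quantile(oracle_nn(P, G), 0.95, names = FALSE, type = 7),
      quantile(oracle_nn(G, P), 0.95, names = FALSE, type = 7))
}

oracle_asd <- function(P, G) mean(c(oracle_nn(P, G), oracle_nn(G, P)))

# Binary 3x3 (2D) median by direct neighborhood inspection, zero-padded.
oracle_median2d <- function(m) {
  d <- dim(m)
  out <- m * 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    vals <- integer(0)
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      vals <- c(vals, if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2])
        m[ii, jj] else 0L)
    }
    out[i, j] <- as.integer(median(vals))
  }
  out
}

# Binary opening with the 3x3 cross, by definition (erosion: every translate
# of the element fits; dilation: union of translates), zero-padded.
oracle_open2d <- function(m) {
  d <- dim(m)
  cross <- list(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  er <- m * 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    ok <- TRUE
    for (o in cross) {
      ii <- i + o[1]; jj <- j + o[2]
      v <- if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2]) m[ii, jj] else 0L
      if (v == 0L) { ok <- FALSE; break }
    }
    er[i, j] <- as.integer(ok)
  }
  di <- m * 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    any1 <- FALSE
    for (o in cross) {
      ii <- i + o[1]; jj <- j + o[2]
      v <- if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2]) er[ii, jj] else 0L
      if (v == 1L) { any1 <- TRUE; break }
    }
    di[i, j] <- as.integer(any1)
  }
  di
}

# Random blobby binary mask (union of a few rasterized disks).
random_mask <- function(size = 16L, ndisk = 2L, rmax = 4) {
  m <- matrix(0L, size, size)
  cx <- matrix(rep(seq_len(size), each = size), size, size)
  cy <- matrix(rep(seq_len(size), times = size), size, size)
  for (k in seq_len(ndisk)) {
    c0 <- runif(2, rmax + 1, size - rmax)
    r <- runif(1, 1, rmax)
    m[(cx - c0[1])^2 + (cy - c0[2])^2 <= r^2] <- 1L
  }
  m
}

# Small deterministic phantom spec for fast tests.
tiny_phantom_spec <- function(...) {
  args <- utils::modifyList(
    list(image_size = 32, pixel_spacing = 1.954, n_healthy = 6,
         n_unhealthy = 6, n_volumes = 1, volume_depth = 16,
         tumor_radius_range = c(3, 7), seed = 7),
    list(...))
  do.call(phantom_spec, args)
}

# strip attributes for bare array comparison
bare <- function(m) array(as.integer(m), dim(m))
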