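test_that("generator maps inputs to same-shape outputs in [0, 1]", {
  set.seed(2)
  G <- build_generator(generator_spec(64, 4, 4))
  X <- array(runif(64 * 64 * 2), c(64, 64, 1, 2))
  Y <- gen_forward(G, X, train = FALSE, keep_cache = FALSE)$Y
  expect_equal(dim(Y), dim(X))
  expect_true(all(Y >= 0 & Y <= 1))
  # deterministic given fixed weights and input
  Y2 <- gen_forward(G, X, train = FALSE, keep_cache = FALSE)$Y
  expect_identical(Y, Y2)
})

test_that("shape contracts hold for every power-of-two size >= 2^depth", {
  set.seed(3)
  for (size in c(16L, 32L, 64L)) {
    G <- build_generator(generator_spec(size, 2, 4))
    X <- matrix(runif(size * size), size, size)
    expect_equal(dim(gen_forward(G, X, train = FALSE)$Y), dim(X))
    D <- build_patch_discriminator(discriminator_spec(size, size, 4, 3))
    Ym <- disc_forward(D, X, keep_cache = FALSE)$Y
    expect_equal(dim(Ym), c(size / 8L, size / 8L, 1L, 1L))
  }
})

test_that("encoder channel widths double per step down to the bottleneck", {
  sp <- generator_spec(64, 32, 4)
  G <- build_generator(sp)
  # entry layer produces base_channels maps; bottleneck has base * 2^depth
  expect_equal(ncol(G$enc[[1]]$W), 32L)
  expect_equal(ncol(G$enc[[5]]$W), 512L)
  widths <- vapply(G$enc, function(b) ncol(b$W), 1L)
  expect_equal(widths, c(32L, 64L, 128L, 256L, 512L))
})

test_that("invalid input sizes fail before any computation", {
  expect_error(generator_spec(100, 8, 4), "divisible")
  G <- build_generator(generator_spec(32, 2, 4))
  expect_error(gen_forward(G, matrix(0, 40, 40)), "divisible")
  D <- build_patch_discriminator(discriminator_spec(32, 32, 4, 3))
  expect_error(disc_forward(D, matrix(0, 20, 20)), "divisible")
  expect_error(discriminator_spec(30, 30, 4, 3), "divisible")
})

test_that("split_halves partitions and mirrors correctly", {
  x <- matrix(seq_len(6 * 8), 6, 8)
  h <- split_halves(x)
  expect_equal(dim(h$left), c(6, 4))
  expect_equal(dim(h$right), c(6, 4))
  # un-mirroring the right half and concatenating reconstructs the input
  expect_identical(cbind(h$left, h$right[, rev(seq_len(4))]), x)
  # mirror-symmetric input gives two identical halves
  xs <- cbind(x[, 1:4], x[, 4:1])
  hs <- split_halves(xs)
  expect_identical(hs$left, hs$right)
  expect_error(split_halves(matrix(0, 6, 7)), "odd")
})

test_that("similarity scores vanish on mirror-symmetric slices", {
  set.seed(4)
  D <- build_similarity_discriminator(discriminator_spec(16, 8, 4, 2))
  half <- matrix(runif(16 * 8), 16, 8)
  sym <- cbind(half, half[, rev(seq_len(8))])
  sc <- smi_score(D, sym)
  expect_equal(sc$s, 0)
  # and the two half score maps coincide elementwise (shared weights)
  h <- split_halves(sym)
  expect_equal(disc_forward(D, h$left, keep_cache = FALSE)$Y,
               disc_forward(D, h$right, keep_cache = FALSE)$Y)
})

test_that("network bundle wires the similarity discriminator at half width", {
  set.seed(5)
  b <- network_bundle(generator_spec(32, 2, 4),
                      discriminator_spec(32, 32, 4, 3))
  expect_s3_class(b, "network_bundle")
  expect_equal(b$D_smi$spec$input_width, 16L)
  expect_equal(b$D_smi$spec$input_height, 32L)
  # generators share a spec, as do the patch discriminators
  expect_identical(b$G_xy$spec, b$G_yx$spec)
  expect_identical(b$D_x$spec, b$D_y$spec)
})

test_that("backpropagation matches finite differences on a tiny network", {
  set.seed(42)
  G <- build_generator(generator_spec(8, 2, 2))
  X <- array(runif(8 * 8 * 2), c(8, 8, 1, 2))
  R <- array(rnorm(8 * 8 * 2), c(8, 8, 1, 2))
  fw <- gen_forward(G, X, train = TRUE)
  bw <- gen_backward(G, fw$cache, R, need_dx = TRUE)
  p <- symcycle:::net_params(G)
  eps <- 1e-5
  loss_at <- function(params) {
    sum(gen_forward(symcycle:::net_set_params(G, params), X,
                    train = TRUE)$Y * R)
  }
  for (nm in c("enc1.W", "enc3.gamma", "dec1.tW", "dec2.W", "fin.b")) {
    i <- sample(length(p[[nm]]), 1)
    pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- p; pm[[nm]][i] <- pm[[nm]][i] - eps
    num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
    expect_equal(bw$grads[[nm]][i], num, tolerance = 1e-4)
  }
  i <- sample(length(X), 1)
  Xp <- X; Xp[i] <- Xp[i] + eps
  Xm <- X; Xm[i] <- Xm[i] - eps
  num <- (sum(gen_forward(G, Xp, train = TRUE)$Y * R) -
            sum(gen_forward(G, Xm, train = TRUE)$Y * R)) / (2 * eps)
  expect_equal(bw$dX[i], num, tolerance = 1e-4)
})
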