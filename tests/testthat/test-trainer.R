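test_that("learning-rate schedule is constant then linearly decayed to zero", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(1, cfg), 2e-4)
  expect_equal(lr_at_epoch(150, cfg), 2e-4)
  expect_equal(lr_at_epoch(175, cfg), 1e-4)
  expect_equal(lr_at_epoch(200, cfg), 0)
  # full schedule against the linear-interpolation oracle
  e <- 1:200
  oracle <- ifelse(e <= 150, 2e-4, 2e-4 * (200 - e) / 50)
  expect_equal(lr_at_epoch(e, cfg), oracle)
  expect_true(all(diff(lr_at_epoch(e, cfg)) <= 0))
  expect_error(lr_at_epoch(0, cfg), "epoch")
  expect_error(lr_at_epoch(201, cfg), "epoch")
  expect_error(train_config(total_epochs = 10, decay_epochs = 20),
               "decay_epochs")
  expect_error(train_config(total_epochs = -1), "total_epochs")
})

tiny_pools <- function(n = 8, size = 16) {
  set.seed(99)
  x <- array(runif(size * size * n, 0, 0.1), c(size, size, n))
  y <- array(runif(size * size * n, 0, 0.1), c(size, size, n))
  list(x = x, y = y)
}

tiny_cfg <- function(...) {
  train_config(total_epochs = 2, decay_epochs = 1, batch_size = 4,
               seed = 5, ...)
}

tiny_specs <- function(size = 16) {
  list(gen = generator_spec(size, 2, 3),
       disc = discriminator_spec(size, size, 4, 3))
}

test_that("training is deterministic given seed and data", {
  p <- tiny_pools(); sp <- tiny_specs()
  s1 <- train(p$x, p$y, sp$gen, sp$disc, tiny_cfg())
  s2 <- train(p$x, p$y, sp$gen, sp$disc, tiny_cfg())
  expect_identical(s1$loss_history, s2$loss_history)
  expect_identical(symcycle:::net_params(s1$bundle$G_xy),
                   symcycle:::net_params(s2$bundle$G_xy))
  # loss log has epochs x steps rows
  expect_equal(nrow(s1$loss_history), 2 * 2)
})

test_that("a zero learning rate leaves network outputs unchanged", {
  p <- tiny_pools(); sp <- tiny_specs()
  cfg <- tiny_cfg()
  set.seed(cfg$seed)
  state <- init_train_state(sp$gen, sp$disc, cfg)
  X <- array(p$x[, , 1:4], c(16, 16, 1, 4))
  Y <- array(p$y[, , 1:4], c(16, 16, 1, 4))
  # lr = 0 leaves all parameters untouched (batch-norm running averages are
  # data statistics, not parameters, so compare batch-statistics forwards)
  before <- gen_forward(state$bundle$G_xy, X, train = TRUE,
                        keep_cache = FALSE)$Y
  res <- train_step(X, Y, state, cfg, lr = 0)
  after <- gen_forward(res$state$bundle$G_xy, X, train = TRUE,
                       keep_cache = FALSE)$Y
  expect_equal(before, after, tolerance = 1e-12)
  expect_equal(symcycle:::net_params(state$bundle$G_xy),
               symcycle:::net_params(res$state$bundle$G_xy),
               tolerance = 1e-12)
  expect_error(train_step(X[, , , 0, drop = FALSE], Y, state, cfg), "empty")
})

test_that("disabling the similarity weight reproduces plain cycle-GAN updates", {
  p <- tiny_pools(); sp <- tiny_specs()
  # lambda_s = 0 with the similarity discriminator still being trained must
  # give generator parameters identical to the no-similarity ablation
  cfg_on <- tiny_cfg(weights = loss_weights(lambda_s = 0), similarity = TRUE)
  cfg_off <- tiny_cfg(weights = loss_weights(lambda_s = 0), similarity = FALSE)
  s_on <- train(p$x, p$y, sp$gen, sp$disc, cfg_on)
  s_off <- train(p$x, p$y, sp$gen, sp$disc, cfg_off)
  expect_equal(symcycle:::net_params(s_on$bundle$G_xy),
               symcycle:::net_params(s_off$bundle$G_xy), tolerance = 1e-12)
  expect_equal(s_on$loss_history$l_gen, s_off$loss_history$l_gen,
               tolerance = 1e-12)
  # the ablation never evaluates the similarity discriminator
  expect_true(all(is.na(s_off$loss_history$l_smi)))
  expect_false(any(is.na(s_on$loss_history$l_smi)))
})

test_that("training writes a TSV loss log and checkpoints that round-trip", {
  p <- tiny_pools(); sp <- tiny_specs()
  dir <- withr::local_tempdir()
  log <- file.path(dir, "loss.tsv")
  cfg <- tiny_cfg(log_path = log, checkpoint_dir = dir)
  st <- train(p$x, p$y, sp$gen, sp$disc, cfg)
  tab <- utils::read.delim(log)
  expect_equal(nrow(tab), nrow(st$loss_history))
  expect_equal(names(tab), c("epoch", "step", "l_gan", "l_cycle", "l_id",
                             "l_dis", "l_smi", "l_gen"))
  expect_equal(tab$l_gen, st$loss_history$l_gen, tolerance = 1e-9)
  ck <- file.path(dir, "epoch_0002.rds")
  expect_true(file.exists(ck))
  restored <- load_checkpoint(ck)
  X <- array(p$x[, , 1:2], c(16, 16, 1, 2))
  expect_identical(gen_forward(restored$bundle$G_xy, X, train = FALSE)$Y,
                   gen_forward(st$bundle$G_xy, X, train = FALSE)$Y)
  # logged generator loss always dominates its weighted components
  w <- cfg$weights
  expect_true(all(tab$l_gen >= tab$l_gan + w$lambda_c * tab$l_cycle +
                    w$lambda_i * tab$l_id - 1e-9))
})

test_that("the fitted model object supports the standard methods", {
  set.seed(77)
  spec <- phantom_spec(image_size = 16, pixel_spacing = 3.9, n_healthy = 8,
                       n_unhealthy = 8, n_volumes = 0,
                       tumor_radius_range = c(4, 8), seed = 2)
  co <- make_phantom_cohort(spec)
  cfg <- tiny_cfg()
  fit <- symcycle(co, gen_spec = generator_spec(16, 2, 3),
                  disc_spec = discriminator_spec(16, 16, 4, 3), config = cfg)
  expect_s3_class(fit, "symcycle")
  expect_output(print(fit), "cycle-consistent")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.symcycle")
  expect_output(print(sm), "Parameters per network")
  cf <- coef(fit)
  expect_true(any(grepl("^G_xy\\.", names(cf))))
  expect_true(any(grepl("^D_smi\\.", names(cf))))
  ph <- predict(fit, co$unhealthy[[1]], type = "healthy")
  expect_equal(dim(ph), dim(co$unhealthy[[1]]$data))
  expect_true(all(ph >= 0 & ph <= 1))
  r <- residuals(fit)
  expect_true(min(r) >= 0)
  m <- predict(fit, co$unhealthy[[1]], type = "mask")
  expect_true(all(m %in% c(0L, 1L)))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
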