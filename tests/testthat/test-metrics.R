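test_that("overlap metrics match direct-count oracles and boundary cases", {
  a <- array(0L, c(4, 4, 2)); a[1:2, 1:2, 1] <- 1L
  expect_equal(dice(a, a), 100)
  expect_equal(ppv(a, a), 100)
  expect_equal(sen(a, a), 100)
  b <- array(0L, c(4, 4, 2)); b[3:4, 3:4, 2] <- 1L
  expect_equal(dice(a, b), 0)
  # |pred| = 4, |gt| = 8, overlap 4
  gt <- array(0L, c(4, 4, 2)); gt[1:2, 1:2, ] <- 1L
  expect_equal(dice(a, gt), 200 * 4 / 12)
  expect_equal(ppv(a, gt), 100)
  expect_equal(sen(a, gt), 50)
  # strict subset: PPV 100, SEN < 100
  expect_lt(sen(a, gt), 100)
  expect_error(dice(a, array(0L, c(2, 2))), "shape")
  expect_warning(d0 <- dice(array(0L, c(2, 2)), array(0L, c(2, 2))),
                 "empty")
  expect_equal(d0, 100)
  expect_warning(p0 <- ppv(matrix(0L, 4, 4), a[, , 1]), "empty")
  expect_equal(p0, 0)
})

test_that("surface extraction finds boundary voxels under face connectivity", {
  cube <- array(0L, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- 1L
  s <- extract_surface(cube, spacing = c(1, 1, 1))
  expect_equal(nrow(s), 26)            # 27 voxels, only the center interior
  one <- array(0L, c(3, 3, 3)); one[2, 2, 2] <- 1L
  s1 <- extract_surface(one, spacing = c(1, 1, 1))
  expect_equal(nrow(s1), 1)
  expect_equal(as.numeric(s1), c(2, 2, 2))
  # spacing scales coordinates per axis
  s2 <- extract_surface(one, spacing = c(2, 1, 1))
  expect_equal(as.numeric(s2), c(4, 2, 2))
  expect_error(extract_surface(array(0L, c(3, 3, 3))), "empty")
})

test_that("surface distances match Euclidean and brute-force oracles", {
  a <- array(0L, c(8, 8, 1)); a[2, 2, 1] <- 1L
  b <- array(0L, c(8, 8, 1)); b[2, 5, 1] <- 1L
  expect_equal(hd95(a, b, c(1, 1, 1)), 3)
  expect_equal(hd95(a, a, c(1, 1, 1)), 0)
  expect_equal(asd(a, a, c(1, 1, 1)), 0)
  # two parallel unit-width segments offset by 2 mm
  p <- array(0L, c(8, 8, 1)); p[2:6, 2, 1] <- 1L
  g <- array(0L, c(8, 8, 1)); g[2:6, 4, 1] <- 1L
  expect_equal(asd(p, g, c(1, 1, 1)), 2)
  # distances scale linearly with spacing
  expect_equal(hd95(a, b, c(2, 2, 2)), 6)
  expect_equal(asd(p, g, c(0.5, 0.5, 1)), 1)
  # random mask pairs against the O(n^2) brute-force oracle
  set.seed(41)
  for (i in 1:20) {
    m1 <- random_mask(14); m2 <- random_mask(14)
    if (sum(m1) == 0 || sum(m2) == 0) next
    sp <- c(runif(1, 0.5, 2), runif(1, 0.5, 2))
    P <- extract_surface(m1, sp); G <- extract_surface(m2, sp)
    expect_lte(nrow(P), 500); expect_lte(nrow(G), 500)
    expect_equal(hd95(m1, m2, sp), oracle_hd95(P, G), tolerance = 1e-6)
    expect_equal(asd(m1, m2, sp), oracle_asd(P, G), tolerance = 1e-6)
    # symmetry of both surface metrics
    expect_equal(hd95(m1, m2, sp), hd95(m2, m1, sp))
    expect_equal(asd(m1, m2, sp), asd(m2, m1, sp))
    # PPV/SEN duality under argument swap
    expect_equal(suppressWarnings(ppv(m1, m2)), suppressWarnings(sen(m2, m1)))
  }
})

test_that("metrics are translation invariant", {
  set.seed(42)
  m <- random_mask(10)
  big1 <- matrix(0L, 20, 20); big1[1:10, 1:10] <- m
  big2 <- matrix(0L, 20, 20); big2[6:15, 9:18] <- m
  shifted_self1 <- matrix(0L, 20, 20); shifted_self1[3:12, 4:13] <- m
  # a mask compared with itself translated inside a larger canvas keeps
  # identical metric values regardless of absolute position
  ref <- matrix(0L, 20, 20); ref[3:12, 4:13] <- m
  expect_equal(hd95(shifted_self1, ref, c(1, 1)), 0)
  expect_equal(dice(shifted_self1, ref), 100)
})

test_that("cohort evaluation aggregates per-case metrics with IQR oracle", {
  a <- array(0L, c(6, 6, 1)); a[2:4, 2:4, 1] <- 1L
  rep1 <- evaluate_cohort(list(a), list(a), spacing = c(1, 1, 1))
  expect_equal(rep1$summary$mean[rep1$summary$metric == "dice_pct"], 100)
  expect_equal(rep1$summary$sd[rep1$summary$metric == "dice_pct"], 0)
  expect_equal(rep1$summary$median[rep1$summary$metric == "hd95_mm"], 0)
  # identical-mask cohort
  rep2 <- evaluate_cohort(rep(list(a), 4), rep(list(a), 4), c(1, 1, 1))
  expect_true(all(rep2$per_case$dice_pct == 100))
  expect_true(all(rep2$per_case$hd95_mm == 0))
  # 5-case synthetic cohort: IQR equals the direct percentile computation
  set.seed(43)
  preds <- replicate(5, random_mask(12), simplify = FALSE)
  gts <- replicate(5, random_mask(12), simplify = FALSE)
  rep3 <- evaluate_cohort(preds, gts, c(1, 1))
  dv <- rep3$per_case$dice_pct
  expect_equal(rep3$summary$q25[rep3$summary$metric == "dice_pct"],
               quantile(dv, 0.25, names = FALSE, type = 7))
  expect_equal(rep3$summary$q75[rep3$summary$metric == "dice_pct"],
               quantile(dv, 0.75, names = FALSE, type = 7))
  expect_error(evaluate_cohort(preds, gts[1:3]), "unpaired")
  # undefined surface metrics are excluded and counted
  e <- matrix(0L, 12, 12)
  rep4 <- evaluate_cohort(c(preds, list(e)), c(gts, list(gts[[1]])), c(1, 1))
  expect_equal(rep4$n_undefined_surface, 1L)
  expect_true(is.na(rep4$per_case$hd95_mm[6]))
  # report writing round-trips the per-case table
  f <- withr::local_tempfile(fileext = ".tsv")
  write_metric_report(rep3, f)
  expect_true(file.exists(f))
})
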