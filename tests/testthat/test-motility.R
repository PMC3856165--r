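test_that("difference image counts added and lost pixels symmetrically", {
  a <- square_mask(20, 20, 6, 6, 10)
  expect_equal(sum(difference_image(a, a)), 0)

  # pure addition: k ones appear
  empty <- matrix(0L, 20, 20)
  expect_equal(sum(difference_image(empty, a)), 100)

  # 10x10 square shifted right by one column: one column lost + one gained
  b <- square_mask(20, 20, 6, 7, 10)
  d <- difference_image(a, b)
  expect_equal(sum(d), 20)
  expect_true(all(d[6:15, 6] == 1) && all(d[6:15, 16] == 1))

  # symmetry in the arguments
  expect_identical(difference_image(a, b), difference_image(b, a))
  expect_error(difference_image(a, matrix(0L, 5, 5)), "identical dimensions")
})

test_that("cell area is the exhaustive 1-pixel count", {
  expect_equal(cell_area(matrix(0L, 8, 8)), 0L)
  expect_equal(cell_area(square_mask(20, 20, 6, 6, 10)), 100L)
  set.seed(7)
  m <- matrix(as.integer(runif(600) < 0.4), 20, 30)
  acc <- 0L
  for (i in 1:20) for (j in 1:30) if (m[i, j] == 1L) acc <- acc + 1L
  expect_equal(cell_area(m), acc)
})

test_that("boxcar averaging equals the windowed mean with zero padding", {
  expect_equal(boxcar_average(matrix(0L, 10, 10), 9), matrix(0, 10, 10))

  # single 1-pixel, w = 9: 1/81 wherever the window reaches it
  m <- matrix(0L, 25, 25); m[13, 13] <- 1L
  b <- boxcar_average(m, 9)
  expect_equal(b[13, 13], 1 / 81)
  expect_equal(b[9, 9], 1 / 81)
  expect_equal(b[8, 13], 0)
  expect_equal(sum(b > 0), 81)

  # random image against the double-loop oracle
  set.seed(17)
  d <- matrix(as.integer(runif(32 * 32) < 0.3), 32, 32)
  expect_equal(boxcar_average(d, 9), naive_boxcar(d, 9), tolerance = 1e-14)
  expect_equal(boxcar_average(d, 5), naive_boxcar(d, 5), tolerance = 1e-14)

  expect_error(boxcar_average(d, 8), "odd")
})

test_that("weighted redistribution zeroes unchanged pixels", {
  m <- matrix(0L, 25, 25); m[13, 13] <- 1L
  theta <- weighted_redistribution(boxcar_average(m, 9), m)
  expect_equal(sum(theta > 0), 1)
  expect_equal(theta[13, 13], 1 / 81)

  set.seed(19)
  d <- matrix(as.integer(runif(400) < 0.2), 20, 20)
  bx <- boxcar_average(d, 5)
  th <- weighted_redistribution(bx, d)
  expect_true(all(th[d == 0] == 0))
  expect_true(all(th <= bx))
  expect_identical(th[d == 1], bx[d == 1])
})

test_that("area-normalized index M1 follows redistributed count over mean area", {
  a <- square_mask(20, 20, 6, 6, 10)
  b <- square_mask(20, 20, 6, 7, 10)

  # static series has zero M1 throughout
  static <- binary_series(list(a, a, a), 300)
  expect_equal(motility_m1(static)$intervals$M1, c(0, 0))

  # shifted square: R = 20, mean area 100 -> M1 = 0.2
  r <- motility_m1(binary_series(list(a, b), 300))
  expect_equal(r$area_mean, 100)
  expect_equal(r$intervals$R, 20L)
  expect_equal(r$m1_mean, 0.2)

  # adding an identical static blob to both frames halves M1
  a2 <- cbind(a, a); b2 <- cbind(b, a)
  r2 <- motility_m1(binary_series(list(a2, b2), 300))
  expect_equal(r2$m1_mean, 0.1)

  expect_error(motility_m1(binary_series(list(matrix(0L, 5, 5),
                                              matrix(0L, 5, 5)), 300)),
               "undefined")
})

test_that("boxcar-weighted index M2 matches the brute-force oracle and rewards clustering", {
  a <- square_mask(20, 20, 6, 6, 10)
  expect_equal(motility_m2(binary_series(list(a, a), 300))$m2_mean, 0)

  # single changed pixel at w = 9 scores 1/81
  e <- matrix(0L, 31, 31); p1 <- e; p1[16, 16] <- 1L
  m2_single <- motility_m2(binary_series(list(e, p1), 300))$m2_mean
  expect_equal(m2_single, 1 / 81)

  # 3x3 and 9x9 changed blocks: oracle agreement and monotone clustering
  b3 <- matrix(0L, 41, 41); b3[20:22, 20:22] <- 1L
  b9 <- matrix(0L, 41, 41); b9[17:25, 17:25] <- 1L
  m2_3 <- motility_m2(binary_series(list(matrix(0L, 41, 41), b3), 300))$m2_mean
  m2_9 <- motility_m2(binary_series(list(matrix(0L, 41, 41), b9), 300))$m2_mean
  expect_equal(m2_3, naive_m2(list(matrix(0L, 41, 41), b3), 9)[1],
               tolerance = 1e-14)
  expect_equal(m2_9, naive_m2(list(matrix(0L, 41, 41), b9), 9)[1],
               tolerance = 1e-14)
  expect_equal(m2_3, 9 / 81)
  expect_gt(m2_9, m2_3)
  expect_gt(m2_3, m2_single)

  # N counts the nonzero weighted pixels (= changed pixels)
  r <- motility_m2(binary_series(list(matrix(0L, 41, 41), b3), 300))
  expect_equal(r$intervals$N, 9L)
})

test_that("clustering monotonicity: M2 is nondecreasing in solid block size", {
  canvas <- matrix(0L, 41, 41)
  m2k <- vapply(1:9, function(k) {
    blk <- canvas
    blk[21:(20 + k), 21:(20 + k)] <- 1L
    motility_m2(binary_series(list(canvas, blk), 300))$m2_mean
  }, numeric(1))
  expect_true(all(diff(m2k) >= 0))
  oracle <- vapply(1:9, function(k) {
    blk <- canvas
    blk[21:(20 + k), 21:(20 + k)] <- 1L
    naive_m2(list(canvas, blk), 9)[1]
  }, numeric(1))
  expect_equal(m2k, oracle, tolerance = 1e-14)
})

test_that("boxcar sweep reproduces the closed-form 1/w^2 single-pixel values", {
  e <- matrix(0L, 31, 31); p1 <- e; p1[16, 16] <- 1L
  sw <- boxcar_sweep(binary_series(list(e, p1), 300), c(3, 9, 15))
  expect_equal(sw$m2_mean, c(1 / 9, 1 / 81, 1 / 225))

  a <- square_mask(20, 20, 6, 6, 10)
  sw0 <- boxcar_sweep(binary_series(list(a, a, a), 300), c(3, 9, 15))
  expect_equal(sw0$m2_mean, c(0, 0, 0))
})

test_that("control normalization divides by the control mean", {
  expect_equal(normalize_to_control(c(2, 2, 2), c(2, 2)), c(1, 1, 1))
  expect_equal(normalize_to_control(c(2, 4), c(1, 3)), c(1, 2))
  expect_error(normalize_to_control(1, numeric(0)), "non-empty")
  expect_error(normalize_to_control(1, c(0, 0)), "positive")
})

test_that("paired comparison reproduces the textbook paired t statistic", {
  # identical lists: zero difference with flagged degenerate statistic
  r0 <- paired_comparison(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$mean_diff, 0)
  expect_equal(r0$statistic, 0)
  expect_true(r0$zero_variance)

  r1 <- paired_comparison(c(1, 1, 1, 1), c(0, 0, 0, 0))
  expect_equal(r1$mean_diff, 1)
  expect_true(r1$zero_variance)

  set.seed(23)
  before <- runif(8); after <- before - rnorm(8, 0.3, 0.2)
  r <- paired_comparison(before, after)
  d <- before - after
  t_hand <- mean(d) / (sd(d) / sqrt(8))
  p_hand <- 2 * pt(-abs(t_hand), df = 7)
  ci_hand <- mean(d) + c(-1, 1) * qt(0.975, 7) * sd(d) / sqrt(8)
  expect_equal(r$statistic, t_hand, tolerance = 1e-12)
  expect_equal(r$p_value, p_hand, tolerance = 1e-12)
  expect_equal(c(r$conf_low, r$conf_high), ci_hand, tolerance = 1e-12)
  expect_equal(r$mean_before, mean(before))

  expect_error(paired_comparison(1, c(1, 2)), "equal length")
  expect_error(paired_comparison(1, 1), "at least two")
})
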