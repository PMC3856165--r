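test_that("maximum-intensity projection matches the voxel-wise maximum", {
  # constant stack
  zs <- zstack_series(list(array(3, c(4, 5, 6)), array(7, c(4, 5, 6))), 300)
  fs <- max_intensity_project(zs)
  expect_equal(fs$frames[[1]], matrix(3, 5, 6))
  expect_equal(fs$frames[[2]], matrix(7, 5, 6))
  expect_equal(fs$frame_interval, 300)

  # Z = 1 stack passes through unchanged
  f <- matrix(runif(30), 5, 6)
  zs1 <- zstack_series(list(array(f, c(1, 5, 6)), array(f, c(1, 5, 6))), 60)
  expect_equal(max_intensity_project(zs1)$frames[[1]], f)

  # random stack against an exhaustive loop over z
  set.seed(11)
  st <- array(runif(4 * 5 * 5), c(4, 5, 5))
  proj <- max_intensity_project(zstack_series(list(st, st), 60))$frames[[1]]
  expected <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) expected[i, j] <- max(st[, i, j])
  expect_equal(proj, expected)

  # permutation invariance over the z axis
  st2 <- st[c(3, 1, 4, 2), , ]
  proj2 <- max_intensity_project(zstack_series(list(st2, st2), 60))$frames[[1]]
  expect_identical(proj, proj2)
})

test_that("z-stack series rejects inconsistent stack shapes", {
  expect_error(
    zstack_series(list(array(0, c(2, 4, 4)), array(0, c(3, 4, 4))), 60),
    "identical dimensions"
  )
})

test_that("translation alignment recovers constructed integer shifts", {
  set.seed(21)
  base <- matrix(runif(40 * 40), 40, 40)
  base <- base + 4 * outer(dnorm(1:40, 20, 6), dnorm(1:40, 20, 6))

  # identical frames: zero shifts, frames unchanged
  fs <- frame_series(list(base, base, base), 60)
  al <- align_translation(fs, 5)
  expect_equal(alignment_shifts(al)$shift_row, c(0, 0, 0))
  expect_equal(alignment_shifts(al)$shift_col, c(0, 0, 0))
  expect_identical(al$frames[[2]], base)

  # frame 2 translated by (+3, -2) is brought back by (-3, +2)
  shifted <- shift_frame(base, 3, -2)
  al2 <- align_translation(frame_series(list(base, shifted), 60), 5)
  sh <- alignment_shifts(al2)
  expect_equal(c(sh$shift_row[2], sh$shift_col[2]), c(-3, 2))
  # realigned frame equals the original on the common support
  common <- al2$frames[[2]] != 0
  expect_equal(al2$frames[[2]][common], base[common])

  # max_shift = 0 is the identity
  al0 <- align_translation(frame_series(list(base, shifted), 60), 0)
  expect_identical(al0$frames[[2]], shifted)
})

test_that("Sobel binarization marks step edges and matches a stencil oracle", {
  # uniform frame: zero gradient everywhere -> empty mask
  expect_equal(sum(binarize_edges(matrix(5, 12, 12))), 0)

  # ideal vertical step: a contiguous vertical band at the step, zeros away
  step <- cbind(matrix(0, 12, 10), matrix(100, 12, 10))
  m <- binarize_edges(step, threshold_scale = 2)
  expect_true(all(m[, 10] == 1) && all(m[, 11] == 1))
  expect_true(all(m[, c(1:7, 14:20)] == 0))

  # random frame: gradient magnitude equals the naive 3x3 stencil
  set.seed(31)
  fr <- matrix(runif(18 * 15), 18, 15)
  g <- sobel_magnitude(fr)
  expect_equal(g, naive_sobel(fr), tolerance = 1e-12)
  thr <- 1.5 * sqrt(mean(naive_sobel(fr)^2))
  expect_identical(binarize_edges(fr, 1.5),
                   matrix(as.integer(naive_sobel(fr) > thr), 18, 15))

  # offset invariance of the gradient
  expect_identical(binarize_edges(fr, 1.5), binarize_edges(fr + 42, 1.5))
})

test_that("disk dilation covers the exact lattice disk and is extensive", {
  m <- matrix(0L, 31, 31); m[16, 16] <- 1L
  d6 <- dilate_mask(m, 6)
  expect_equal(sum(d6), 113)  # lattice points with dx^2 + dy^2 <= 36

  # radius 0 is the identity
  expect_identical(dilate_mask(m, 0), m)

  # two points 20 px apart give two disjoint 113-px disks
  m2 <- matrix(0L, 41, 41); m2[21, 11] <- 1L; m2[21, 31] <- 1L
  expect_equal(sum(dilate_mask(m2, 6)), 226)

  # extensive, monotone in radius, stable under a further radius-0 pass
  set.seed(41)
  rnd <- matrix(as.integer(runif(900) < 0.05), 30, 30)
  d2 <- dilate_mask(rnd, 2); d4 <- dilate_mask(rnd, 4)
  expect_true(all(d2[rnd == 1L] == 1L))
  expect_true(all(d4[d2 == 1L] == 1L))
  expect_identical(dilate_mask(d2, 0), d2)

  expect_error(dilate_mask(rnd, -1), "non-negative")
})

test_that("preprocessing pipeline is deterministic and dilation grows masks", {
  mv <- generate_movie(synthetic_cell_config(n_frames = 3, seed = 5))

  bs1 <- preprocess_series(mv$series)
  bs2 <- preprocess_series(mv$series)
  expect_identical(bs1$masks, bs2$masks)

  # constant series -> all-zero masks
  const <- frame_series(list(matrix(0.5, 16, 16), matrix(0.5, 16, 16)), 60)
  expect_true(all(vapply(preprocess_series(const)$masks, sum, numeric(1)) == 0))

  # duplicated frame -> identical masks
  dup <- frame_series(list(mv$series$frames[[1]], mv$series$frames[[1]]), 60)
  bsd <- preprocess_series(dup)
  expect_identical(bsd$masks[[1]], bsd$masks[[2]])

  # dilation strictly enlarges a nonempty edge mask
  edge_area <- cell_area(binarize_edges(mv$series$frames[[1]]))
  dil_area <- cell_area(bs1$masks[[1]])
  expect_gt(edge_area, 0)
  expect_gt(dil_area, edge_area)
})
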