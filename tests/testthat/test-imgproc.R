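test_that("median smoothing matches a brute-force neighborhood median", {
  img <- matrix(runif(64), 8, 8)
  expect_identical(median_smooth(img, 1L), img)
  const <- matrix(0.4, 7, 9)
  expect_equal(median_smooth(const, 5L), const)
  spike <- matrix(0, 9, 9); spike[5, 5] <- 1
  expect_equal(median_smooth(spike, 3L), matrix(0, 9, 9))
  withr::with_seed(11, {
    for (k in c(3L, 5L)) {
      x <- matrix(runif(12 * 10), 12, 10)
      expect_equal(median_smooth(x, k), oracle_median_filter(x, k))
    }
  })
  expect_error(median_smooth(img, 2L), "odd")
  expect_error(median_smooth(img, 0L), "odd")
})

test_that("median smoothing never widens the intensity range", {
  withr::with_seed(3, {
    x <- matrix(runif(400, 0.2, 0.9), 20, 20)
    y <- median_smooth(x, 5L)
    expect_gte(min(y), min(x))
    expect_lte(max(y), max(x))
  })
})

test_that("adaptive equalization stays in range and preserves rank order", {
  const <- matrix(0.5, 16, 16)
  out <- equalize_adaptive(const, c(2L, 2L), 0.01)
  expect_equal(max(out) - min(out), 0)
  withr::with_seed(5, {
    x <- matrix(runif(64 * 64), 64, 64)
    y <- equalize_adaptive(x, c(8L, 8L), 0.01)
    expect_gte(min(y), 0)
    expect_lte(max(y), 1)
    expect_identical(dim(y), dim(x))
  })
  # single global tile on a two-level image: levels stay distinct, in order
  two <- matrix(rep(c(0.2, 0.8), each = 128), 16, 16)
  eq <- equalize_adaptive(two, c(1L, 1L), 0.5)
  lo <- unique(eq[two == 0.2]); hi <- unique(eq[two == 0.8])
  expect_length(lo, 1)
  expect_length(hi, 1)
  expect_lt(lo, hi)
})

test_that("Sobel segmentation finds steps and rings, not flat regions", {
  const <- matrix(0.7, 32, 32)
  expect_false(any(sobel_edge_mask(const)))
  step <- cbind(matrix(0, 40, 20), matrix(1, 40, 20))
  sm <- sobel_edge_mask(step)
  hit_cols <- which(apply(sm, 2, any))
  expect_true(all(hit_cols %in% 19:22))
  expect_gt(length(hit_cols), 0)
  # hand-convolved response at the step is 4 (gx = 1+2+1 across the jump)
  expect_equal(oracle_sobel_at(step, 20, 20), 4)
  disk <- disk_image(96, 25)
  dm <- sobel_edge_mask(disk)
  ctr <- 48:49
  expect_false(any(dm[ctr, ctr]))
  d <- sqrt((row(disk) - 48.5)^2 + (col(disk) - 48.5)^2)
  expect_true(all(abs(d[dm] - 25) < 3))
})

test_that("Gaussian spreading is linear and mass-conserving", {
  empty <- matrix(FALSE, 40, 40)
  expect_equal(gaussian_spread(empty, 21L, 3), matrix(0, 40, 40))
  one <- matrix(FALSE, 41, 41); one[21, 21] <- TRUE
  resp <- gaussian_spread(one, 21L, 3)
  ker <- sproutquant:::gaussian_kernel2d(21L, 3)
  expect_equal(resp[11:31, 11:31], ker, tolerance = 1e-8)
  expect_equal(sum(resp), 1, tolerance = 1e-8)
  two <- matrix(FALSE, 41, 41); two[21, 15] <- TRUE; two[25, 30] <- TRUE
  a <- matrix(FALSE, 41, 41); a[21, 15] <- TRUE
  b <- matrix(FALSE, 41, 41); b[25, 30] <- TRUE
  expect_equal(gaussian_spread(two, 15L, 2),
               gaussian_spread(a, 15L, 2) + gaussian_spread(b, 15L, 2),
               tolerance = 1e-8)
  withr::with_seed(7, {
    m <- matrix(FALSE, 60, 60)
    m[cbind(sample(25:35, 8, TRUE), sample(25:35, 8, TRUE))] <- TRUE
    expect_equal(sum(gaussian_spread(m, 15L, 2)), sum(m), tolerance = 1e-6)
  })
})

test_that("nonzero-statistics threshold follows median + coeff * sample SD", {
  m <- matrix(0, 4, 4); m[1, 1] <- 2; m[2, 2] <- 4; m[3, 3] <- 6
  th <- nonzero_stats_threshold(m, 0.3)
  expect_equal(th$threshold, 4 + 0.3 * 2)
  expect_identical(which(th$mask), which(m == 6))
  flat <- matrix(0, 3, 3); flat[1, ] <- 0.5
  th2 <- nonzero_stats_threshold(flat, 0.3)
  expect_equal(th2$threshold, 0.5)
  expect_false(any(th2$mask))
  expect_warning(z <- nonzero_stats_threshold(matrix(0, 3, 3), 0.3),
                 "nonzero")
  expect_equal(z$threshold, 0)
  expect_false(any(z$mask))
})

test_that("threshold is scale-equivariant and agrees with the oracle", {
  withr::with_seed(42, {
    for (i in 1:100) {
      x <- matrix(0, 32, 32)
      idx <- sample(length(x), sample(2:40, 1))
      x[idx] <- runif(length(idx))
      th <- nonzero_stats_threshold(x, 0.3)
      expect_equal(th$threshold, oracle_nonzero_threshold(x, 0.3),
                   tolerance = 1e-12)
      sc <- nonzero_stats_threshold(3.7 * x, 0.3)
      expect_equal(sc$threshold, 3.7 * th$threshold, tolerance = 1e-12)
      expect_identical(sc$mask, th$mask)
    }
  })
})

test_that("intensity normalization divides by the dtype maximum", {
  raw <- matrix(c(0, 255), 1, 2)
  expect_equal(normalize_intensity(raw, 8L), matrix(c(0, 1), 1, 2))
  raw16 <- matrix(c(0, 65535, 32768), 1, 3)
  n <- normalize_intensity(raw16, 16L)
  expect_equal(n[1, 2], 1)
  expect_equal(n[1, 3], 32768 / 65535)
  expect_error(normalize_intensity(matrix(300, 1, 1), 8L), "range")
})
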