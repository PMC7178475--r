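test_that("the activity kernel follows 2^(2R - cityblock distance)", {
  expect_identical(weight_kernel(1), matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1), 3, 3))
  expect_equal(weight_kernel(1)[2, 2], 4)
  k2 <- weight_kernel(2)
  expect_equal(k2[3, 3], 16)      # centre: 2^(2R)
  expect_equal(k2[1, 1], 1)       # corner at r = 4: 2^(4-4)
  expect_equal(k2[1, 3], 4)       # axial edge at r = 2
  expect_error(weight_kernel(0), ">= 1")
})

test_that("weighted local energy matches its closed forms and the oracle", {
  expect_equal(wle(matrix(0, 8, 8), 1), matrix(0, 8, 8))
  ones <- wle(matrix(1, 8, 8), 1)
  expect_equal(ones[4, 4], 16)    # sum of the R=1 kernel
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  expect_equal(wle(imp, 1)[5, 5], 4)
  set.seed(1)
  L <- matrix(rnorm(16 * 16), 16, 16)
  for (R in 1:2) {
    expect_lt(max(abs(wle(L, R) - wle_naive(L, R))), 1e-10)
  }
})

test_that("the modified Laplacian vanishes on affine images and peaks on impulses", {
  expect_equal(eml(matrix(5, 8, 8)), matrix(0, 8, 8))
  ramp <- outer(1:10, 1:10, function(u, v) 3 * u + 2 * v)
  expect_lt(max(abs(eml(ramp)[2:9, 2:9])), 1e-10)
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  expect_equal(eml(imp)[5, 5], 4 + 2 * sqrt(2))
  set.seed(2)
  L <- matrix(rnorm(16 * 16), 16, 16)
  expect_lt(max(abs(eml(L) - eml_naive(L))), 1e-10)
})

test_that("the weighted Laplacian sum matches the brute-force oracle", {
  expect_equal(wseml(matrix(3, 8, 8), 1), matrix(0, 8, 8))
  set.seed(3)
  L <- matrix(rnorm(16 * 16), 16, 16)
  for (R in 1:2) {
    expect_lt(max(abs(wseml(L, R) - wseml_naive(L, R))), 1e-10)
  }
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  expect_equal(wseml(imp, 1), wseml_naive(imp, 1))
})

test_that("approximation fusion selects by activity product with ties to A", {
  A <- matrix(4.2, 12, 12)
  expect_equal(fuse_low1(A, A), A)
  B <- matrix(0, 12, 12); B[6, 6] <- 1
  A5 <- matrix(5, 12, 12)
  out <- fuse_low1(A5, B)
  expect_equal(out[6, 6], B[6, 6])        # B wins where its activity is positive
  expect_equal(out[1, 1], 5)              # tie at zero activity goes to A
  # pure selection: every output pixel is one of the two inputs
  set.seed(4)
  X <- matrix(rnorm(16 * 16), 16, 16); Y <- matrix(rnorm(16 * 16), 16, 16)
  sel <- fuse_low1(X, Y)
  expect_true(all(sel == X | sel == Y))
  # swapping the inputs can differ only at exact activity ties
  act_x <- wle(X, 1) * wseml(X, 1)
  act_y <- wle(Y, 1) * wseml(Y, 1)
  swapped <- fuse_low1(Y, X)
  differs <- sel != swapped
  expect_true(all(act_x[differs] == act_y[differs]))
  expect_error(fuse_low1(X, matrix(0, 8, 8)), "shape")
})

test_that("spatial frequency follows the printed index ranges and normaliser", {
  expect_equal(spatial_frequency(matrix(2, 6, 6)), 0)
  cb <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(spatial_frequency(cb), sqrt(0.5))
  set.seed(5)
  M <- matrix(runif(12 * 9), 12, 9)
  expect_equal(spatial_frequency(M), sf_naive(M), tolerance = 1e-12)
  expect_equal(spatial_frequency(3 * M), 3 * spatial_frequency(M))
  expect_error(spatial_frequency(matrix(1, 1, 5)), "2x2")
})

test_that("second-component fusion is the scalar spatial-frequency blend", {
  A <- matrix(1:36, 6, 6); B <- matrix(36:1, 6, 6)
  expect_equal(fuse_low2(A, B, matrix(0.5, 6, 6)), B)   # SF of a constant is 0
  expect_equal(fuse_low2(A, A, matrix(runif(36), 6, 6)), A)
  # a map engineered to SF = 0.5 gives the midpoint blend
  W <- matrix(0, 8, 8)
  target <- 0.5
  W[, seq(1, 8, 2)] <- sqrt(target^2 * 64 / (2 * 7 * 7) / 2) * 2
  w <- spatial_frequency(W)
  expect_equal(fuse_low2(A, B, matrix(0, 6, 6) + W[3, 3]), B)
  blend <- fuse_low2(A, B, W)
  expect_equal(blend, A * w + B * (1 - w))
  expect_error(fuse_low2(A, matrix(0, 3, 3), W), "shape")
})

test_that("detail fusion blends with the weight band in both modes", {
  set.seed(6)
  HA <- matrix(rnorm(64), 8, 8); HB <- matrix(rnorm(64), 8, 8)
  expect_equal(fuse_high(HA, HB, matrix(0, 8, 8)), HB)
  expect_equal(fuse_high(HA, HB, matrix(1, 8, 8)), HA)
  W <- matrix(rnorm(64, sd = 2), 8, 8)
  expect_equal(fuse_high(HA, HA, W), HA)
  lit <- fuse_high(HA, HB, W, mode = "literal")
  expect_equal(lit, W * HA + (1 - W) * HB)
  off <- fuse_high(HA, HB, W, mode = "offset")
  lo <- pmin(HA, HB); hi <- pmax(HA, HB)
  expect_true(all(off >= lo - 1e-12 & off <= hi + 1e-12))
  expect_error(fuse_high(HA, HB, matrix(0, 4, 4)), "shape")
})

test_that("all three rules are idempotent on identical inputs", {
  set.seed(7)
  X <- matrix(runif(100, -3, 3), 10, 10)
  W <- matrix(runif(100), 10, 10)
  expect_equal(fuse_low1(X, X), X)
  expect_equal(fuse_low2(X, X, W), X)
  expect_equal(fuse_high(X, X, W, "literal"), X)
  expect_equal(fuse_high(X, X, W, "offset"), X)
})

test_that("fusion config validates its fields", {
  cfg <- fusion_config()
  expect_equal(cfg$radius, 1L)
  expect_equal(cfg$weight_band_mode, "literal")
  expect_true(cfg$clamp_sf)
  expect_error(fusion_config(radius = 0), ">= 1")
  expect_error(fusion_config(weight_band_mode = "banana"))
})
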