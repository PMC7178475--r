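test_that("patch dataset generation is deterministic and balanced", {
  corpus <- small_corpus()
  ds1 <- make_patch_dataset(corpus$sharp, c(1, 3), 16L, 100L, seed = 3)
  ds2 <- make_patch_dataset(corpus$sharp, c(1, 3), 16L, 100L, seed = 3)
  expect_identical(ds1, ds2)
  ds3 <- make_patch_dataset(corpus$sharp, c(1, 3), 16L, 100L, seed = 4)
  expect_false(identical(ds1$x1, ds3$x1))
  expect_equal(as.vector(table(ds1$y)), c(50, 50))
  expect_true(all(ds1$x1 >= 0 & ds1$x1 <= 1))
})

test_that("the blurred partner of a textured patch has lower variance", {
  corpus <- small_corpus()
  ds <- make_patch_dataset(corpus$sharp, blur_sigma = 2, patch_size = 16L,
                           n_pairs = 40L, seed = 8)
  v_sharp <- v_blur <- numeric(40)
  for (p in seq_len(40)) {
    sharp <- if (ds$y[p] == 1) ds$x1[p, , ] else ds$x2[p, , ]
    blur <- if (ds$y[p] == 1) ds$x2[p, , ] else ds$x1[p, , ]
    v_sharp[p] <- stats::var(as.vector(sharp))
    v_blur[p] <- stats::var(as.vector(blur))
  }
  # smoothing drains patch variance; a crop can occasionally gain a little
  # variance from an edge blurred in from just outside its window
  expect_gte(mean(v_blur < v_sharp), 0.9)
  expect_lt(mean(v_blur), mean(v_sharp))
})

test_that("patch dataset preconditions are enforced", {
  corpus <- small_corpus()
  expect_error(make_patch_dataset(corpus$sharp, blur_sigma = 0), "positive")
  expect_error(make_patch_dataset(corpus$sharp, patch_size = 500), "exceeds")
  expect_error(make_patch_dataset(list()), "non-empty")
})

test_that("the pair forward pass is a two-way softmax", {
  params <- init_patchnet(16L, seed = 2)
  set.seed(1)
  x <- matrix(runif(256), 16, 16); y <- matrix(runif(256), 16, 16)
  p <- forward_pair(x, y, params)
  expect_equal(unname(sum(p)), 1, tolerance = 1e-6)
  expect_true(all(p >= 0 & p <= 1))
  expect_error(forward_pair(matrix(0, 8, 8), y, params), "16x16")
})

test_that("both branches run through one shared parameter set", {
  params <- init_patchnet(16L, seed = 2)
  # the parameter object holds a single branch: no duplicated conv tensors
  expect_setequal(grep("conv", names(params), value = TRUE),
                  c("conv1", "conv2", "conv3"))
  # make the head treat the two feature halves symmetrically-swapped:
  # then swapping the input order must exactly swap the class scores,
  # which can only hold if both patches pass through identical branch weights
  feat <- params$feat
  params$fc$b[] <- 0
  half1 <- params$fc$W[seq_len(feat), ]
  params$fc$W[feat + seq_len(feat), ] <- half1[, 2:1]
  set.seed(3)
  x <- matrix(runif(256), 16, 16); y <- matrix(runif(256), 16, 16)
  p_xy <- forward_pair(x, y, params)
  p_yx <- forward_pair(y, x, params)
  expect_equal(unname(p_xy["p1"]), unname(p_yx["p0"]), tolerance = 1e-10)
  # mutating the shared conv weights changes both orderings' outputs
  params$conv1$W <- params$conv1$W * 1.5
  expect_false(isTRUE(all.equal(forward_pair(x, y, params), p_xy)))
  expect_false(isTRUE(all.equal(forward_pair(y, x, params), p_yx)))
})

test_that("training reduces the loss and is seed-reproducible", {
  corpus <- small_corpus()
  ds <- make_patch_dataset(corpus$sharp, c(1, 3), 16L, 200L, seed = 12)
  net_a <- train_network(ds, epochs = 2L, seed = 5)
  expect_lt(net_a$loss_log[2], net_a$loss_log[1])
  net_b <- train_network(ds, epochs = 2L, seed = 5)
  expect_identical(net_a$params, net_b$params)
  bad <- ds; bad$y[] <- 1L
  expect_error(train_network(bad, epochs = 1L), "single class")
})

test_that("a modestly trained network separates sharp from blurred patches", {
  net <- small_net()
  ds_test <- make_patch_dataset(small_corpus()$sharp, c(1, 3), 16L, 300L,
                                seed = 77)
  expect_gt(patchnet_accuracy(net, ds_test), 0.9)
  p1 <- predict(net, ds_test)
  expect_true(all(p1 >= 0 & p1 <= 1))
})

test_that("the weight map covers the image, stays in [0,1] and favours sharp", {
  net <- small_net()
  pair <- make_pair(phantom_spec(c(96L, 96L), seed = 41),
                    phantom_spec(c(96L, 96L), seed = 41, modality = "mri_like"))
  sharp <- pair$mri
  blurred <- gaussian_blur(sharp, 2.5)
  W <- weight_map(sharp, blurred, net, stride = 4L)
  expect_identical(dim(W), dim(sharp))
  expect_true(all(W >= 0 & W <= 1))
  expect_gt(mean(W), 0.5)
  expect_error(weight_map(sharp, matrix(0, 8, 8), net), "shape")
})

test_that("a non-overlapping stride writes exactly one score per pixel", {
  net <- small_net()
  set.seed(13)
  a <- matrix(runif(64 * 64, 0, 255), 64, 64)
  b <- matrix(runif(64 * 64, 0, 255), 64, 64)
  W <- weight_map(a, b, net, stride = 16L)
  # every 16x16 tile is filled with a single probability
  for (u in seq(1, 64, 16)) {
    for (v in seq(1, 64, 16)) {
      tile <- W[u:(u + 15), v:(v + 15)]
      expect_equal(max(tile) - min(tile), 0)
    }
  }
})

test_that("weight-map decomposition mirrors the source band structure", {
  fb <- build_filter_bank(2, c(4, 8), c(64, 64))
  wm <- decompose_weight(matrix(0.5, 64, 64), fb)
  expect_lt(max(abs(wm$low - 0.5)), 1e-8)
  for (lev in wm$highs) for (band in lev) expect_lt(max(abs(band)), 1e-8)
  expect_length(wm$highs, 2)
  expect_length(wm$highs[[2]], 8)
  # a step-edge map has sign changes in its high-pass bands
  step <- matrix(0, 64, 64); step[, 33:64] <- 1
  wm2 <- decompose_weight(step, fb)
  finest <- do.call(cbind, lapply(wm2$highs[[2]], as.vector))
  expect_lt(min(finest), -1e-4)
  expect_gt(max(finest), 1e-4)
})
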