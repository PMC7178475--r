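#' Sharp/blurred patch-pair training set
#'
#' Samples `n_pairs` patch pairs from the source images. Each source is
#' Gaussian-blurred once with `blur_sigma`; for every pair a random image
#' and location give a sharp patch and its blurred partner at the same
#' location. Pairs alternate orientation for an exact 50/50 label split:
#' label 1 means the first patch is the sharp one, label 0 the swapped
#' order. Patches are scaled to \[0, 1\] (inputs are on the 0..255 scale);
#' near-constant patches (no texture to judge sharpness by) are skipped.
#'
#' @param source_images list of numeric matrices, each at least
#'   `patch_size` in both dimensions, 0..255 scale.
#' @param blur_sigma Gaussian blur standard deviation (pixels), > 0; a
#'   length-2 range draws one sigma per source image.
#' @param patch_size side length of the square patches.
#' @param n_pairs number of training pairs, >= 1.
#' @param seed sampling seed (sampling and blur are fully deterministic).
#' @return list of class `patch_dataset`: `x1`, `x2` (arrays
#'   `n_pairs x patch_size x patch_size`), `y` (integer labels),
#'   `patch_size`.
#' @export
make_patch_dataset <- function(source_images, blur_sigma = 2, patch_size = 16L,
                               n_pairs = 1000L, seed = 1L) {
  if (!is.list(source_images) || length(source_images) == 0L) {
    stop("source_images must be a non-empty list of matrices")
  }
  patch_size <- as.integer(patch_size)
  for (img in source_images) {
    if (any(dim(img) < patch_size)) {
      stop("patch_size (", patch_size,
           ") exceeds a source image of size ",
           paste(dim(img), collapse = "x"))
    }
  }
  if (any(blur_sigma <= 0)) stop("blur_sigma must be positive")
  if (n_pairs < 1) stop("n_pairs must be >= 1")

  rng <- seeded_rng(seed)
  sigmas <- if (length(blur_sigma) == 2L) {
    rng$runif(length(source_images), blur_sigma[1], blur_sigma[2])
  } else {
    rep(blur_sigma[1], length(source_images))
  }
  blurred <- lapply(seq_along(source_images), function(i) {
    gaussian_blur(source_images[[i]], sigmas[i])
  })

  x1 <- array(0, c(n_pairs, patch_size, patch_size))
  x2 <- array(0, c(n_pairs, patch_size, patch_size))
  y <- integer(n_pairs)
  for (p in seq_len(n_pairs)) {
    for (try in 1:50) {
      i <- rng$sample_int(length(source_images), 1L)
      img <- source_images[[i]]
      u <- rng$sample_int(nrow(img) - patch_size + 1L, 1L)
      v <- rng$sample_int(ncol(img) - patch_size + 1L, 1L)
      sharp <- img[u:(u + patch_size - 1L), v:(v + patch_size - 1L)]
      if (stats::sd(sharp) > 1 || try == 50L) break
    }
    blur <- blurred[[i]][u:(u + patch_size - 1L), v:(v + patch_size - 1L)]
    if (p %% 2L == 1L) {               # alternate orientation: exact 50/50
      x1[p, , ] <- sharp / 255; x2[p, , ] <- blur / 255; y[p] <- 1L
    } else {
      x1[p, , ] <- blur / 255; x2[p, , ] <- sharp / 255; y[p] <- 0L
    }
  }
  structure(list(x1 = x1, x2 = x2, y = y, patch_size = patch_size),
            class = "patch_dataset")
}

#' Initialise dual-branch network parameters
#'
#' Both branches share one parameter set by construction: three 3x3
#' convolution layers (widths 16, 32, 64) with rectifier nonlinearity, a
#' 2x2 max-pool after the second, then one fully-connected layer from the
#' concatenated branch features to 2 logits.
#'
#' @param patch_size input patch side length (default 16).
#' @param seed initialisation seed (He-scaled normal draws).
#' @return list of class `patchnet_params`.
#' @export
init_patchnet <- function(patch_size = 16L, seed = 1L) {
  patch_size <- as.integer(patch_size)
  if (patch_size < 12L || patch_size %% 2L != 0L) {
    stop("patch_size must be an even integer >= 12 (two valid 3x3 convs, ",
         "a 2x2 pool, then another 3x3 conv must fit)")
  }
  widths <- c(16L, 32L, 64L)
  rng <- seeded_rng(seed)
  he <- function(k, cin, cout) {
    array(rng$rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
          c(k, k, cin, cout))
  }
  side <- (patch_size - 4L) %/% 2L - 2L        # after conv,conv,pool,conv
  feat <- side * side * widths[3]
  structure(list(
    conv1 = list(W = he(3L, 1L, widths[1]), b = numeric(widths[1])),
    conv2 = list(W = he(3L, widths[1], widths[2]), b = numeric(widths[2])),
    conv3 = list(W = he(3L, widths[2], widths[3]), b = numeric(widths[3])),
    fc = list(W = matrix(rng$rnorm(2L * feat * 2L, sd = sqrt(2 / (2 * feat))),
                         2L * feat, 2L),
              b = numeric(2L)),
    patch_size = patch_size, widths = widths, feat = feat, seed = seed),
    class = "patchnet_params")
}

#' Class probabilities for one patch pair
#'
#' Runs both patches through the shared branch, concatenates the features,
#' applies the fully-connected layer and a two-way softmax. `p1` is the
#' probability that the first patch is the high-quality (sharp) one.
#'
#' @param patch_1,patch_2 `patch_size` x `patch_size` matrices on the
#'   \[0, 1\] scale.
#' @param params a `patchnet_params` or trained `patchnet` object.
#' @return named numeric vector `c(p0, p1)`, summing to 1.
#' @export
forward_pair <- function(patch_1, patch_2, params) {
  params <- as_patchnet_params(params)
  ps <- params$patch_size
  patch_1 <- as.matrix(patch_1); patch_2 <- as.matrix(patch_2)
  if (!all(dim(patch_1) == c(ps, ps)) || !all(dim(patch_2) == c(ps, ps))) {
    stop("patches must be ", ps, "x", ps)
  }
  x1 <- array(patch_1, c(1L, ps, ps))
  x2 <- array(patch_2, c(1L, ps, ps))
  p <- patchnet_forward_pairs(x1, x2, params)$prob
  c(p0 = p[1, 1], p1 = p[1, 2])
}

#' Train the dual-branch network
#'
#' Minimises the two-class cross-entropy with Adam over minibatches; the
#' seed fixes initialisation and batch order, so training is fully
#' reproducible (single-threaded numerics assumed).
#'
#' @param dataset a [make_patch_dataset()] result with both labels present.
#' @param epochs passes over the data.
#' @param learning_rate Adam step size.
#' @param seed training seed.
#' @param batch_size pairs per minibatch.
#' @param verbose print per-epoch mean loss.
#' @return object of class `patchnet`: `params`, `loss_log` (mean loss per
#'   epoch), `patch_size`.
#' @export
train_network <- function(dataset, epochs = 20L, learning_rate = 1e-3,
                          seed = 1L, batch_size = 64L, verbose = FALSE) {
  stopifnot(inherits(dataset, "patch_dataset"))
  if (length(unique(dataset$y)) < 2L) {
    stop("dataset holds a single class; two-class training is degenerate")
  }
  params <- init_patchnet(dataset$patch_size, seed = seed)
  opt <- adam_state(params)
  rng <- seeded_rng(seed + 31L)
  n <- length(dataset$y)
  loss_log <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- rng$sample_int(n, n)
    losses <- c()
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      step <- patchnet_train_step(dataset$x1[idx, , , drop = FALSE],
                                  dataset$x2[idx, , , drop = FALSE],
                                  dataset$y[idx], params, opt, learning_rate)
      params <- step$params
      losses <- c(losses, step$loss)
    }
    loss_log[ep] <- mean(losses)
    if (verbose) {
      message(sprintf("epoch %d/%d  loss %.4f", ep, epochs, loss_log[ep]))
    }
  }
  structure(list(params = params, loss_log = loss_log,
                 patch_size = dataset$patch_size),
            class = "patchnet")
}

#' @export
print.patchnet <- function(x, ...) {
  cat("Dual-branch patch network (shared weights)\n")
  cat("  patch size: ", x$patch_size, "x", x$patch_size, "\n", sep = "")
  cat("  conv widths: ", paste(x$params$widths, collapse = " -> "), "\n",
      sep = "")
  cat("  epochs trained: ", length(x$loss_log),
      ", final loss: ", signif(x$loss_log[length(x$loss_log)], 4), "\n",
      sep = "")
  invisible(x)
}

#' Predict sharp-first probabilities for a patch dataset
#' @param object a trained `patchnet`.
#' @param dataset a `patch_dataset`.
#' @param ... unused.
#' @return numeric vector of `p1` per pair.
#' @export
predict.patchnet <- function(object, dataset, ...) {
  stopifnot(inherits(dataset, "patch_dataset"))
  patchnet_forward_pairs(dataset$x1, dataset$x2, object$params)$prob[, 2]
}

#' Held-out accuracy of a trained network on a labelled dataset
#' @param net trained `patchnet`.
#' @param dataset labelled `patch_dataset`.
#' @export
patchnet_accuracy <- function(net, dataset) {
  p1 <- predict(net, dataset)
  mean(as.integer(p1 > 0.5) == dataset$y)
}

#' Initial weight map from a registered image pair
#'
#' Slides a `patch_size` window in lockstep over both images with the
#' given stride (the final window is pinned to the image edge so every
#' pixel is covered), writes the sharp-first probability `p1` — the
#' probability that `image_a`'s patch is the high-quality one — to every
#' pixel of the window, and averages overlapping writes.
#'
#' @param image_a,image_b registered same-shape matrices, 0..255 scale.
#' @param params trained `patchnet` (or bare `patchnet_params`).
#' @param stride window step in pixels.
#' @return matrix of the image shape with values in \[0, 1\].
#' @export
weight_map <- function(image_a, image_b, params, stride = 2L) {
  params <- as_patchnet_params(params)
  image_a <- as.matrix(image_a); image_b <- as.matrix(image_b)
  if (!all(dim(image_a) == dim(image_b))) {
    stop("images differ in shape: ", paste(dim(image_a), collapse = "x"),
         " vs ", paste(dim(image_b), collapse = "x"))
  }
  ps <- params$patch_size
  m <- nrow(image_a); n <- ncol(image_a)
  if (m < ps || n < ps) stop("images smaller than the patch size")
  stride <- max(1L, as.integer(stride))
  us <- unique(c(seq(1L, m - ps + 1L, by = stride), m - ps + 1L))
  vs <- unique(c(seq(1L, n - ps + 1L, by = stride), n - ps + 1L))
  locs <- expand.grid(u = us, v = vs)
  acc <- matrix(0, m, n)
  cnt <- matrix(0, m, n)
  a <- image_a / 255; b <- image_b / 255
  chunk <- 256L
  for (start in seq(1L, nrow(locs), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(locs))
    nb <- length(idx)
    x1 <- array(0, c(nb, ps, ps)); x2 <- array(0, c(nb, ps, ps))
    for (q in seq_len(nb)) {
      u <- locs$u[idx[q]]; v <- locs$v[idx[q]]
      x1[q, , ] <- a[u:(u + ps - 1L), v:(v + ps - 1L)]
      x2[q, , ] <- b[u:(u + ps - 1L), v:(v + ps - 1L)]
    }
    p1 <- patchnet_forward_pairs(x1, x2, params)$prob[, 2]
    for (q in seq_len(nb)) {
      u <- locs$u[idx[q]]; v <- locs$v[idx[q]]
      ur <- u:(u + ps - 1L); vr <- v:(v + ps - 1L)
      acc[ur, vr] <- acc[ur, vr] + p1[q]
      cnt[ur, vr] <- cnt[ur, vr] + 1
    }
  }
  acc / cnt
}

#' Decompose a weight map into transform bands
#'
#' The low-frequency component is the recombined approximation
#' (`low1 + low2` — the rules use a single low band of the weight map);
#' the high-pass bands mirror the source band structure. High-pass values
#' of a \[0, 1\] map straddle zero by construction.
#'
#' @param W_S weight map matrix (values in \[0, 1\]).
#' @param fb the same filter bank used for the sources.
#' @return list of class `weight_maps`: `W_S`, `low`, `highs`.
#' @export
decompose_weight <- function(W_S, fb) {
  co <- nsst_decompose(W_S, fb, provenance = "weight_map")
  structure(list(W_S = W_S, low = co$low1 + co$low2, highs = co$highs),
            class = "weight_maps")
}

as_patchnet_params <- function(params) {
  if (inherits(params, "patchnet")) params <- params$params
  if (!inherits(params, "patchnet_params")) {
    stop("`params` must be a patchnet or patchnet_params object")
  }
  params
}

# --- network internals (im2col convolutions, shared-branch forward/backward)

# x: (n, H, W, C). Valid 3x3 correlation via im2col + one matrix product.
conv_im2col <- function(x) {
  d <- dim(x)
  n <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  Ho <- H - 2L; Wo <- W - 2L
  blocks <- vector("list", 9L)
  o <- 0L
  for (dj in 0:2) {
    for (di in 0:2) {
      o <- o + 1L
      blk <- x[, (1L + di):(Ho + di), (1L + dj):(Wo + dj), , drop = FALSE]
      dim(blk) <- c(n * Ho * Wo, C)
      blocks[[o]] <- blk
    }
  }
  list(cols = do.call(cbind, blocks), n = n, Ho = Ho, Wo = Wo,
       C = C, H = H, W = W)
}

conv_forward <- function(x, layer, keep_cache = FALSE) {
  ic <- conv_im2col(x)
  cout <- dim(layer$W)[4]
  Wmat <- matrix(aperm(layer$W, c(3, 1, 2, 4)), ncol = cout)
  out <- ic$cols %*% Wmat
  out <- out + rep(layer$b, each = nrow(out))
  dim(out) <- c(ic$n, ic$Ho, ic$Wo, cout)
  if (keep_cache) list(out = out, ic = ic, Wmat = Wmat) else list(out = out)
}

conv_backward <- function(dout, cache, cin, need_dx = TRUE) {
  ic <- cache$ic
  cout <- dim(dout)[4]
  dim(dout) <- c(ic$n * ic$Ho * ic$Wo, cout)
  dWmat <- crossprod(ic$cols, dout)
  dW <- aperm(array(dWmat, c(cin, 3L, 3L, cout)), c(2, 3, 1, 4))
  db <- colSums(dout)
  dx <- NULL
  if (need_dx) {
    dcols <- dout %*% t(cache$Wmat)
    dx <- array(0, c(ic$n, ic$H, ic$W, cin))
    o <- 0L
    for (dj in 0:2) {
      for (di in 0:2) {
        o <- o + 1L
        blk <- dcols[, (o - 1L) * cin + seq_len(cin), drop = FALSE]
        dim(blk) <- c(ic$n, ic$Ho, ic$Wo, cin)
        sl <- dx[, (1L + di):(ic$Ho + di), (1L + dj):(ic$Wo + dj), ,
                 drop = FALSE]
        dx[, (1L + di):(ic$Ho + di), (1L + dj):(ic$Wo + dj), ] <- sl + blk
      }
    }
  }
  list(dW = dW, db = db, dx = dx)
}

maxpool_forward <- function(x) {
  d <- dim(x)
  ri <- seq(1L, d[2], by = 2L); ci <- seq(1L, d[3], by = 2L)
  s11 <- x[, ri, ci, , drop = FALSE];      s21 <- x[, ri + 1L, ci, , drop = FALSE]
  s12 <- x[, ri, ci + 1L, , drop = FALSE]; s22 <- x[, ri + 1L, ci + 1L, , drop = FALSE]
  m <- pmax(s11, s21, s12, s22)
  list(out = m, slices = list(s11, s21, s12, s22), m = m, dims = d)
}

maxpool_backward <- function(dout, cache) {
  d <- cache$dims
  dx <- array(0, d)
  ri <- seq(1L, d[2], by = 2L); ci <- seq(1L, d[3], by = 2L)
  claimed <- array(FALSE, dim(cache$m))
  put <- list(list(ri, ci), list(ri + 1L, ci), list(ri, ci + 1L),
              list(ri + 1L, ci + 1L))
  for (s in 1:4) {
    hit <- (cache$slices[[s]] == cache$m) & !claimed
    claimed <- claimed | hit
    dx[, put[[s]][[1]], put[[s]][[2]], ] <- dout * hit
  }
  dx
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# One branch over a stacked patch batch; caches only when training.
branch_forward <- function(x, params, keep_cache = FALSE) {
  n <- dim(x)[1]
  dim(x) <- c(dim(x), 1L)
  c1 <- conv_forward(x, params$conv1, keep_cache)
  a1 <- relu(c1$out)
  c2 <- conv_forward(a1, params$conv2, keep_cache)
  a2 <- relu(c2$out)
  pl <- maxpool_forward(a2)
  c3 <- conv_forward(pl$out, params$conv3, keep_cache)
  a3 <- relu(c3$out)
  feat <- a3
  dim(feat) <- c(n, params$feat)
  if (!keep_cache) return(list(feat = feat))
  list(feat = feat, c1 = c1, a1 = a1, c2 = c2, a2 = a2, pl = pl,
       c3 = c3, a3 = a3)
}

patchnet_forward_pairs <- function(x1, x2, params, keep_cache = FALSE) {
  n <- dim(x1)[1]
  xall <- array(0, c(2L * n, dim(x1)[2], dim(x1)[3]))
  xall[seq_len(n), , ] <- x1
  xall[n + seq_len(n), , ] <- x2
  br <- branch_forward(xall, params, keep_cache)
  concat <- cbind(br$feat[seq_len(n), , drop = FALSE],
                  br$feat[n + seq_len(n), , drop = FALSE])
  logits <- concat %*% params$fc$W +
    rep(params$fc$b, each = n)
  mx <- pmax(logits[, 1], logits[, 2])
  e <- exp(logits - mx)
  prob <- e / rowSums(e)
  list(prob = prob, logits = logits, concat = concat, branch = br, n = n)
}

patchnet_train_step <- function(x1, x2, y, params, opt, lr) {
  fw <- patchnet_forward_pairs(x1, x2, params, keep_cache = TRUE)
  n <- fw$n
  eps <- 1e-12
  loss <- -mean(log(fw$prob[cbind(seq_len(n), y + 1L)] + eps))
  Y <- matrix(0, n, 2L)
  Y[cbind(seq_len(n), y + 1L)] <- 1
  dlogits <- (fw$prob - Y) / n
  g <- list()
  g[["fc.W"]] <- crossprod(fw$concat, dlogits)
  g[["fc.b"]] <- colSums(dlogits)
  dconcat <- dlogits %*% t(params$fc$W)
  feat <- params$feat
  dfeat <- rbind(dconcat[, seq_len(feat), drop = FALSE],
                 dconcat[, feat + seq_len(feat), drop = FALSE])
  br <- fw$branch
  da3 <- array(dfeat, dim(br$a3))
  dc3 <- da3 * (br$c3$out > 0)
  bk3 <- conv_backward(dc3, br$c3, cin = params$widths[2], need_dx = TRUE)
  g[["conv3.W"]] <- bk3$dW; g[["conv3.b"]] <- bk3$db
  da2 <- maxpool_backward(bk3$dx, br$pl)
  dc2 <- da2 * (br$c2$out > 0)
  bk2 <- conv_backward(dc2, br$c2, cin = params$widths[1], need_dx = TRUE)
  g[["conv2.W"]] <- bk2$dW; g[["conv2.b"]] <- bk2$db
  dc1 <- bk2$dx * (br$c1$out > 0)
  bk1 <- conv_backward(dc1, br$c1, cin = 1L, need_dx = FALSE)
  g[["conv1.W"]] <- bk1$dW; g[["conv1.b"]] <- bk1$db

  params <- adam_update(params, g, opt, lr)
  list(params = params, loss = loss)
}

adam_state <- function(params) {
  env <- new.env()
  env$t <- 0L
  env$m <- list(); env$v <- list()
  env
}

adam_update <- function(params, g, opt, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  opt$t <- opt$t + 1L
  t <- opt$t
  for (key in names(g)) {
    grad <- g[[key]]
    if (is.null(opt$m[[key]])) {
      opt$m[[key]] <- grad * 0
      opt$v[[key]] <- grad * 0
    }
    opt$m[[key]] <- beta1 * opt$m[[key]] + (1 - beta1) * grad
    opt$v[[key]] <- beta2 * opt$v[[key]] + (1 - beta2) * grad^2
    mhat <- opt$m[[key]] / (1 - beta1^t)
    vhat <- opt$v[[key]] / (1 - beta2^t)
    step <- lr * mhat / (sqrt(vhat) + eps)
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    params[[parts[1]]][[parts[2]]] <- params[[parts[1]]][[parts[2]]] - step
  }
  params
}
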