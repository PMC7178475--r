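# Brute-force reference implementations, kept deliberately naive (double
# loops, direct formula transcription) and independent of the package's
# vectorised code paths.

reflect_idx <- function(i, m) {
  if (i < 1) 1 - i else if (i > m) 2 * m + 1 - i else i
}

at_sym <- function(L, u, v) {
  L[reflect_idx(u, nrow(L)), reflect_idx(v, ncol(L))]
}

wle_naive <- function(L, R) {
  W <- outer(abs(-R:R), abs(-R:R), function(a, b) 2^(2 * R - (a + b)))
  out <- matrix(0, nrow(L), ncol(L))
  for (u in seq_len(nrow(L))) {
    for (v in seq_len(ncol(L))) {
      s <- 0
      for (i in -R:R) {
        for (j in -R:R) {
          s <- s + W[i + R + 1, j + R + 1] * at_sym(L, u + i, v + j)^2
        }
      }
      out[u, v] <- s
    }
  }
  out
}

eml_naive <- function(L) {
  out <- matrix(0, nrow(L), ncol(L))
  for (u in seq_len(nrow(L))) {
    for (v in seq_len(ncol(L))) {
      c0 <- at_sym(L, u, v)
      out[u, v] <-
        abs(2 * c0 - at_sym(L, u - 1, v) - at_sym(L, u + 1, v)) +
        abs(2 * c0 - at_sym(L, u, v - 1) - at_sym(L, u, v + 1)) +
        abs(2 * c0 - at_sym(L, u - 1, v - 1) - at_sym(L, u + 1, v + 1)) / sqrt(2) +
        abs(2 * c0 - at_sym(L, u - 1, v + 1) - at_sym(L, u + 1, v - 1)) / sqrt(2)
    }
  }
  out
}

wseml_naive <- function(L, R) {
  W <- outer(abs(-R:R), abs(-R:R), function(a, b) 2^(2 * R - (a + b)))
  E <- eml_naive(L)
  out <- matrix(0, nrow(L), ncol(L))
  for (u in seq_len(nrow(L))) {
    for (v in seq_len(ncol(L))) {
      s <- 0
      for (i in -R:R) {
        for (j in -R:R) {
          s <- s + W[i + R + 1, j + R + 1] * at_sym(E, u + i, v + j)
        }
      }
      out[u, v] <- s
    }
  }
  out
}

sf_naive <- function(M) {
  m <- nrow(M); n <- ncol(M)
  rf <- 0; cf <- 0
  for (i in 1:(m - 1)) {
    for (j in 1:(n - 1)) {
      rf <- rf + (M[i, j] - M[i, j + 1])^2
      cf <- cf + (M[i, j] - M[i + 1, j])^2
    }
  }
  sqrt(rf / (m * n) + cf / (m * n))
}

mi_naive <- function(R_img, F_img, L = 256) {
  r <- pmin(pmax(round(R_img), 0), L - 1)
  f <- pmin(pmax(round(F_img), 0), L - 1)
  N <- length(r)
  h <- matrix(0, L, L)
  for (i in seq_len(N)) h[r[i] + 1, f[i] + 1] <- h[r[i] + 1, f[i] + 1] + 1
  h <- h / N
  hr <- rowSums(h); hf <- colSums(h)
  s <- 0
  for (u in 1:L) {
    for (v in 1:L) {
      if (h[u, v] > 0) s <- s + h[u, v] * log2(h[u, v] / (hr[u] * hf[v]))
    }
  }
  s
}

entropy_naive <- function(X, L = 256) {
  x <- pmin(pmax(round(X), 0), L - 1)
  p <- tabulate(x + 1, nbins = L) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

ssim_naive <- function(X, Y, win = 11, sigma = 1.5) {
  C1 <- (0.01 * 255)^2; C2 <- (0.03 * 255)^2
  off <- seq_len(win) - (win + 1) / 2
  g <- exp(-off^2 / (2 * sigma^2))
  w <- outer(g, g); w <- w / sum(w)
  m <- nrow(X) - win + 1; n <- ncol(X) - win + 1
  vals <- c()
  for (u in 1:m) {
    for (v in 1:n) {
      px <- X[u:(u + win - 1), v:(v + win - 1)]
      py <- Y[u:(u + win - 1), v:(v + win - 1)]
      mx <- sum(w * px); my <- sum(w * py)
      sxx <- sum(w * px^2) - mx^2
      syy <- sum(w * py^2) - my^2
      sxy <- sum(w * px * py) - mx * my
      vals <- c(vals, (2 * mx * my + C1) * (2 * sxy + C2) /
                        ((mx^2 + my^2 + C1) * (sxx + syy + C2)))
    }
  }
  mean(vals)
}

sd_naive <- function(F_img) {
  mu <- sum(F_img) / length(F_img)
  sqrt(sum((F_img - mu)^2) / length(F_img))
}

ei_naive <- function(F_img) {
  m <- nrow(F_img); n <- ncol(F_img)
  vals <- c()
  for (u in 2:m) {
    for (v in 2:n) {
      dx <- F_img[u, v] - F_img[u - 1, v]
      dy <- F_img[u, v] - F_img[u, v - 1]
      vals <- c(vals, sqrt(dx^2 + dy^2))
    }
  }
  mean(vals)
}

ag_naive <- function(F_img) {
  m <- nrow(F_img); n <- ncol(F_img)
  s <- 0
  for (u in 1:(m - 1)) {
    for (v in 1:(n - 1)) {
      fx <- F_img[u + 1, v] - F_img[u, v]
      fy <- F_img[u, v + 1] - F_img[u, v]
      s <- s + sqrt((fx^2 + fy^2) / 2)
    }
  }
  s / (m * n)
}

ncc_naive <- function(X, Y, b = 256) {
  x <- as.numeric(X); y <- as.numeric(Y)
  N <- length(x)
  rx <- rank(x, ties.method = "first")
  ry <- rank(y, ties.method = "first")
  s <- 0
  for (i in 1:b) {
    for (j in 1:b) {
      cnt <- sum(rx > (i - 1) * N / b & rx <= i * N / b &
                 ry > (j - 1) * N / b & ry <= j * N / b)
      if (cnt > 0) s <- s + (cnt / N) * log(cnt / N, base = b)
    }
  }
  2 + s
}

qncie_naive <- function(A, B, F_img, b = 256) {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- ncc_naive(A, B, b)
  R[1, 3] <- R[3, 1] <- ncc_naive(A, F_img, b)
  R[2, 3] <- R[3, 2] <- ncc_naive(B, F_img, b)
  lam <- eigen(R, symmetric = TRUE, only.values = TRUE)$values / 3
  s <- 0
  for (l in lam) if (l > 0) s <- s + l * log(l, base = b)
  1 + s
}

circ_shift <- function(m, a, b) {
  m[(seq_len(nrow(m)) - 1 - a) %% nrow(m) + 1,
    (seq_len(ncol(m)) - 1 - b) %% ncol(m) + 1]
}
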