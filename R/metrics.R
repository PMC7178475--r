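#' Mutual information between two images (bits)
#'
#' Both images are quantised to `L` gray levels (rounded and clipped to
#' `0 .. L-1`); MI is computed from the joint gray-level histogram
#' normalised to a probability table, log base 2.
#'
#' @param R_img,F_img same-shape numeric matrices on a 0..L-1 scale.
#' @param L number of gray levels (256 for 8-bit images).
#' @export
mutual_information <- function(R_img, F_img, L = 256L) {
  R_img <- as.matrix(R_img); F_img <- as.matrix(F_img)
  if (length(R_img) == 0L) stop("empty image")
  if (!all(dim(R_img) == dim(F_img))) stop("images differ in shape")
  r <- quantize_levels(R_img, L)
  f <- quantize_levels(F_img, L)
  joint <- tabulate(r * L + f + 1L, nbins = L * L) / length(r)
  jm <- matrix(joint, L, L, byrow = TRUE)        # rows: r levels, cols: f levels
  pr <- rowSums(jm); pf <- colSums(jm)
  nz <- which(jm > 0, arr.ind = TRUE)
  p <- jm[nz]
  sum(p * log2(p / (pr[nz[, 1]] * pf[nz[, 2]])))
}

#' Total fusion mutual information: MI(A,F) + MI(B,F)
#' @param A,B source images; `F_img` the fused image.
#' @inheritParams mutual_information
#' @export
mi_fusion <- function(A, B, F_img, L = 256L) {
  mutual_information(A, F_img, L) + mutual_information(B, F_img, L)
}

#' Mean structural similarity of a fused image against both sources
#'
#' SSIM with an 11x11 Gaussian window (sigma 1.5) over fully-valid window
#' positions, 8-bit stabilising constants C1 = (0.01*255)^2,
#' C2 = (0.03*255)^2; the score is the average of SSIM(A,F) and SSIM(B,F).
#'
#' @param A,B source images; `F_img` the fused image; all same shape.
#' @export
mssim <- function(A, B, F_img) {
  (ssim_pair(A, F_img) + ssim_pair(B, F_img)) / 2
}

ssim_pair <- function(X, Y, win_size = 11L, sigma = 1.5,
                      C1 = (0.01 * 255)^2, C2 = (0.03 * 255)^2) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y))) stop("images differ in shape")
  if (any(dim(X) < win_size)) {
    stop("image smaller than the ", win_size, "x", win_size, " SSIM window")
  }
  w <- gaussian_kernel(win_size, sigma)
  mu_x <- valid_correlate(X, w)
  mu_y <- valid_correlate(Y, w)
  sxx <- valid_correlate(X * X, w) - mu_x^2
  syy <- valid_correlate(Y * Y, w) - mu_y^2
  sxy <- valid_correlate(X * Y, w) - mu_x * mu_y
  num <- (2 * mu_x * mu_y + C1) * (2 * sxy + C2)
  den <- (mu_x^2 + mu_y^2 + C1) * (sxx + syy + C2)
  mean(num / den)
}

#' Standard deviation of an image (population, 1/(M*N) normaliser)
#' @param F_img numeric matrix.
#' @export
sd_image <- function(F_img) {
  F_img <- as.matrix(F_img)
  if (length(F_img) == 0L) stop("empty image")
  sqrt(mean((F_img - mean(F_img))^2))
}

#' Edge intensity: mean backward-difference gradient magnitude
#'
#' Per pixel, `sqrt(dx^2 + dy^2)` with backward differences
#' `dx(u,v) = F(u,v) - F(u-1,v)`, `dy(u,v) = F(u,v) - F(u,v-1)`; the score
#' is the mean magnitude over the valid region (rows and columns >= 2).
#'
#' @param F_img numeric matrix, at least 2 x 2.
#' @export
edge_intensity <- function(F_img) {
  F_img <- as.matrix(F_img)
  m <- nrow(F_img); n <- ncol(F_img)
  if (m < 2L || n < 2L) stop("need at least a 2x2 image")
  core <- F_img[2:m, 2:n]
  dx <- core - F_img[1:(m - 1), 2:n]
  dy <- core - F_img[2:m, 1:(n - 1)]
  mean(sqrt(dx^2 + dy^2))
}

#' Average gradient
#'
#' `AG = (1/(M*N)) * sum sqrt((fx^2 + fy^2)/2)` over the forward-difference
#' region (the normaliser is the full pixel count, as conventionally
#' printed, although the sums have (M-1)(N-1) terms).
#'
#' @param F_img numeric matrix, at least 2 x 2.
#' @export
avg_gradient <- function(F_img) {
  F_img <- as.matrix(F_img)
  m <- nrow(F_img); n <- ncol(F_img)
  if (m < 2L || n < 2L) stop("need at least a 2x2 image")
  core <- F_img[1:(m - 1), 1:(n - 1)]
  fx <- F_img[2:m, 1:(n - 1)] - core
  fy <- F_img[1:(m - 1), 2:n] - core
  sum(sqrt((fx^2 + fy^2) / 2)) / (m * n)
}

#' Pairwise nonlinear correlation coefficient (rank-grid NCC)
#'
#' Ranks both variables (ties broken by position, identically for both),
#' partitions the rank plane into a `b x b` grid and computes
#' `NCC = 2 + sum (n_i/N) log_b (n_i/N)` over the cell counts, with
#' `0 log 0 = 0`. Identical variables give 1; independent ones give ~0.
#'
#' @param X,Y same-length numeric data (matrices are flattened).
#' @param b rank-grid size per axis (and the log base), >= 2.
#' @export
ncc_rank <- function(X, Y, b = 256L) {
  x <- as.numeric(X); y <- as.numeric(Y)
  if (length(x) != length(y)) stop("variables differ in length")
  b <- as.integer(b)
  if (b < 2L) stop("b must be >= 2")
  N <- length(x)
  if (b * b > N) {
    warning("rank grid has more cells (", b * b, ") than samples (", N, ")")
  }
  bi <- ceiling(rank(x, ties.method = "first") * b / N)
  bj <- ceiling(rank(y, ties.method = "first") * b / N)
  counts <- tabulate((bi - 1L) * b + bj, nbins = b * b)
  p <- counts[counts > 0] / N
  2 + sum(p * log(p, base = b))
}

#' Nonlinear correlation information entropy of a fusion triple
#'
#' Assembles the 3x3 nonlinear correlation matrix of (A, B, F) — unit
#' diagonal, pairwise [ncc_rank()] off-diagonal — and aggregates its
#' eigenvalues: `Q = 1 + sum (lambda_i/3) log_b (lambda_i/3)`. Equals 1
#' for three identical images and ~`1 - log_b 3` for three independent
#' ones.
#'
#' @param A,B source images; `F_img` the fused image; same shapes.
#' @param b rank-grid size / log base.
#' @export
qncie <- function(A, B, F_img, b = 256L) {
  A <- as.matrix(A); B <- as.matrix(B); F_img <- as.matrix(F_img)
  if (!all(dim(A) == dim(B)) || !all(dim(A) == dim(F_img))) {
    stop("images differ in shape")
  }
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- ncc_rank(A, B, b)
  R[1, 3] <- R[3, 1] <- ncc_rank(A, F_img, b)
  R[2, 3] <- R[3, 2] <- ncc_rank(B, F_img, b)
  lam <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0) / 3
  pos <- lam > 0
  1 + sum(lam[pos] * log(lam[pos], base = b))
}

#' Score a fused image with all six fusion metrics
#'
#' @param A,B registered source images (0..255 scale); `F_img` the fused
#'   image.
#' @param L gray levels for the mutual-information histograms.
#' @param b rank-grid size for the nonlinear correlation entropy.
#' @return one-row data frame with columns `ei`, `ag`, `sd`, `mi`,
#'   `mssim`, `qncie`.
#' @examples
#' a <- matrix(rep(c(0, 255), each = 128), 16, 16)
#' evaluate_fusion(a, a, a)
#' @export
evaluate_fusion <- function(A, B, F_img, L = 256L, b = 256L) {
  data.frame(ei = edge_intensity(F_img),
             ag = avg_gradient(F_img),
             sd = sd_image(F_img),
             mi = mi_fusion(A, B, F_img, L),
             mssim = mssim(A, B, F_img),
             qncie = qncie(A, B, F_img, b))
}

quantize_levels <- function(x, L) {
  q <- round(x)
  q[q < 0] <- 0
  q[q > L - 1] <- L - 1
  q
}

gaussian_kernel <- function(size, sigma) {
  off <- seq_len(size) - (size + 1) / 2
  g <- exp(-off^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Correlation with a kernel over fully-valid positions only (no padding).
valid_correlate <- function(x, kernel) {
  km <- nrow(kernel); kn <- ncol(kernel)
  m <- nrow(x) - km + 1L; n <- ncol(x) - kn + 1L
  out <- matrix(0, m, n)
  for (i in seq_len(km)) {
    for (j in seq_len(kn)) {
      out <- out + kernel[i, j] * x[(i - 1) + 1:m, (j - 1) + 1:n]
    }
  }
  out
}
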