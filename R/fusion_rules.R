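#' Fusion rule configuration
#'
#' @param radius window radius R of the weighted-local-energy /
#'   weighted-sum-of-modified-Laplacian activity measures.
#' @param weight_band_mode how the detail-band blend uses the weight map's
#'   high-pass bands: `"literal"` uses the raw band (values may be negative,
#'   the blend extrapolates); `"offset"` adds 0.5 and clips to \[0, 1\] so the
#'   blend is convex.
#' @param clamp_sf clamp the spatial-frequency scalar into \[0, 1\] before it
#'   is used as a blend weight.
#' @return a list of class `fusion_config`.
#' @export
fusion_config <- function(radius = 1L, weight_band_mode = c("literal", "offset"),
                          clamp_sf = TRUE) {
  radius <- as.integer(radius)
  if (length(radius) != 1L || is.na(radius) || radius < 1L) {
    stop("`radius` must be an integer >= 1")
  }
  weight_band_mode <- match.arg(weight_band_mode)
  structure(list(radius = radius, weight_band_mode = weight_band_mode,
                 clamp_sf = isTRUE(clamp_sf)),
            class = "fusion_config")
}

#' Activity-measure weighting kernel
#'
#' The (2R+1) x (2R+1) matrix whose entry at offset (i, j) from the centre
#' is 2^(2R - r), r = |i| + |j| the city-block distance. At R = 1 this is
#' the classic \[1 2 1; 2 4 2; 1 2 1\] kernel.
#'
#' @param R window radius, integer >= 1.
#' @export
weight_kernel <- function(R) {
  R <- as.integer(R)
  if (length(R) != 1L || is.na(R) || R < 1L) stop("R must be an integer >= 1")
  off <- -R:R
  r <- outer(abs(off), abs(off), `+`)
  2^(2 * R - r)
}

#' Weighted local energy
#'
#' Window-weighted sum of squared coefficients,
#' `WLE(u,v) = sum_{i,j} W(i,j) L(u+i, v+j)^2`, with the [weight_kernel()]
#' weights and symmetric (mirror) boundary extension. An energy-preservation
#' activity measure for the coarsest approximation band.
#'
#' @param L 2-D numeric matrix.
#' @param R window radius.
#' @return matrix of `dim(L)`.
#' @export
wle <- function(L, R = 1L) {
  kernel_correlate(as.matrix(L)^2, weight_kernel(R))
}

#' Eight-neighbourhood modified Laplacian
#'
#' `EML(u,v)` sums the absolute axial second differences plus the diagonal
#' ones scaled by 1/sqrt(2), with symmetric boundary extension. A
#' detail-extraction activity measure.
#'
#' @param L 2-D numeric matrix.
#' @return matrix of `dim(L)`.
#' @export
eml <- function(L) {
  L <- as.matrix(L)
  P <- pad_symmetric(L, 1L)
  m <- nrow(L); n <- ncol(L)
  ctr <- P[2:(m + 1), 2:(n + 1)]
  up    <- P[1:m,       2:(n + 1)]
  down  <- P[3:(m + 2), 2:(n + 1)]
  left  <- P[2:(m + 1), 1:n]
  right <- P[2:(m + 1), 3:(n + 2)]
  ul <- P[1:m,       1:n]
  lr <- P[3:(m + 2), 3:(n + 2)]
  ur <- P[1:m,       3:(n + 2)]
  ll <- P[3:(m + 2), 1:n]
  abs(2 * ctr - up - down) + abs(2 * ctr - left - right) +
    (abs(2 * ctr - ul - lr) + abs(2 * ctr - ur - ll)) / sqrt(2)
}

#' Weighted sum of the modified Laplacian
#'
#' The [eml()] field correlated with the [weight_kernel()] (the Laplacian
#' enters unsquared), symmetric boundary extension.
#'
#' @inheritParams wle
#' @export
wseml <- function(L, R = 1L) {
  kernel_correlate(eml(L), weight_kernel(R))
}

#' Fuse the coarsest approximation by activity maximum selection
#'
#' Pixel-wise selection: take A's coefficient where
#' `WLE_A * WSEML_A >= WLE_B * WSEML_B`, otherwise B's (ties go to A).
#'
#' @param L_A1,L_B1 coarsest approximation bands, same shape.
#' @param R activity window radius.
#' @export
fuse_low1 <- function(L_A1, L_B1, R = 1L) {
  L_A1 <- as.matrix(L_A1); L_B1 <- as.matrix(L_B1)
  if (!all(dim(L_A1) == dim(L_B1))) {
    stop("approximation bands differ in shape: ",
         paste(dim(L_A1), collapse = "x"), " vs ",
         paste(dim(L_B1), collapse = "x"))
  }
  act_a <- wle(L_A1, R) * wseml(L_A1, R)
  act_b <- wle(L_B1, R) * wseml(L_B1, R)
  out <- L_B1
  take_a <- act_a >= act_b
  out[take_a] <- L_A1[take_a]
  out
}

#' Spatial frequency of a map
#'
#' Root of the summed squared row and column first differences:
#' `RF = sqrt(sum (M(i,j) - M(i,j+1))^2 / (m n))`, `CF` likewise down the
#' columns, `SF = sqrt(RF^2 + CF^2)`. Both sums run over
#' `i = 1..M-1, j = 1..N-1` while the normaliser is the full pixel count
#' `m*n`, following the conventional printed form.
#'
#' @param M 2-D numeric matrix, at least 2 x 2.
#' @return scalar SF (not clamped; clamping is the blend's concern).
#' @export
spatial_frequency <- function(M) {
  M <- as.matrix(M)
  m <- nrow(M); n <- ncol(M)
  if (m < 2L || n < 2L) {
    stop("spatial frequency needs at least a 2x2 map, got ", m, "x", n)
  }
  core <- M[1:(m - 1), 1:(n - 1), drop = FALSE]
  rf2 <- sum((core - M[1:(m - 1), 2:n])^2) / (m * n)
  cf2 <- sum((core - M[2:m, 1:(n - 1)])^2) / (m * n)
  sqrt(rf2 + cf2)
}

#' Fuse the second approximation component by spatial-frequency blend
#'
#' A single global scalar `w = SF(W_S_low)` (clamped to \[0, 1\] when
#' `clamp` is set) blends the bands: `L_F2 = w * L_A2 + (1 - w) * L_B2`.
#'
#' @param L_A2,L_B2 second approximation components, same shape.
#' @param W_S_low low-frequency component of the weight map.
#' @param clamp clamp the scalar into \[0, 1\].
#' @export
fuse_low2 <- function(L_A2, L_B2, W_S_low, clamp = TRUE) {
  L_A2 <- as.matrix(L_A2); L_B2 <- as.matrix(L_B2)
  if (!all(dim(L_A2) == dim(L_B2))) {
    stop("second approximation bands differ in shape")
  }
  w <- spatial_frequency(W_S_low)
  if (clamp) w <- min(w, 1)
  L_A2 * w + L_B2 * (1 - w)
}

#' Fuse one detail band by weight-band blend
#'
#' `H_F = W * H_A + (1 - W) * H_B` pixel-wise, with W the matching
#' high-pass band of the weight map. In `"literal"` mode W is used raw
#' (high-pass values straddle zero, so the blend can extrapolate); in
#' `"offset"` mode W + 0.5 is clipped to \[0, 1\] first.
#'
#' @param H_A,H_B detail bands of the two sources, same shape.
#' @param W_band matching high-pass band of the weight map.
#' @param mode `"literal"` or `"offset"`.
#' @export
fuse_high <- function(H_A, H_B, W_band, mode = c("literal", "offset")) {
  mode <- match.arg(mode)
  H_A <- as.matrix(H_A); H_B <- as.matrix(H_B); W_band <- as.matrix(W_band)
  if (!all(dim(H_A) == dim(H_B)) || !all(dim(H_A) == dim(W_band))) {
    stop("detail bands and weight band must share one shape")
  }
  W <- if (mode == "offset") pmin(pmax(W_band + 0.5, 0), 1) else W_band
  W * H_A + (1 - W) * H_B
}

# Correlation of `x` with a small (possibly 1-D) kernel under symmetric
# boundary extension, as a shift-and-add over kernel offsets.
kernel_correlate <- function(x, kernel) {
  rr <- (nrow(kernel) - 1L) %/% 2L
  rc <- (ncol(kernel) - 1L) %/% 2L
  P <- pad_symmetric(x, rr, rc)
  m <- nrow(x); n <- ncol(x)
  out <- matrix(0, m, n)
  for (i in seq_len(nrow(kernel))) {
    for (j in seq_len(ncol(kernel))) {
      out <- out + kernel[i, j] * P[(i - 1) + 1:m, (j - 1) + 1:n]
    }
  }
  out
}

# Mirror padding, half-sample symmetric convention (edge row/column repeats).
pad_symmetric <- function(x, rr, rc = rr) {
  m <- nrow(x); n <- ncol(x)
  if (rr >= m || rc >= n) stop("padding radius exceeds image size")
  ri <- if (rr > 0) c(rr:1, 1:m, m:(m - rr + 1)) else 1:m
  ci <- if (rc > 0) c(rc:1, 1:n, n:(n - rc + 1)) else 1:n
  x[ri, ci, drop = FALSE]
}
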