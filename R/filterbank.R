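#' Non-subsampled shearlet filter bank
#'
#' Tabulates, for a fixed image size, everything the transform needs:
#' per-stage pyramid low/high frequency responses (a-trous upsampled
#' B3-spline pair) and per-level directional shear windows (raised-cosine
#' bumps equally spaced in the pseudo-polar angle induced by the shearlet
#' dilation/shear matrices).
#'
#' The bank carries `levels + 1` pyramid stages: the extra stage splits the
#' coarsest pyramid low-pass into the two approximation components `low1`
#' (its low output) and `low2` (its high output) that the fusion rules
#' treat separately.
#'
#' @param levels number of pyramid stages K (>= 1).
#' @param directions_per_level integer vector of length `levels`, coarse to
#'   fine; each entry a power of two >= 2.
#' @param image_shape length-2 integer vector `(rows, cols)` the frequency
#'   windows are tabulated for.
#' @return an object of class `nsst_filter_bank` with fields `levels`,
#'   `directions_per_level`, `pyr_analysis` (per stage, `$low`/`$high`
#'   frequency-response matrices), `pyr_synthesis` (per stage, all-ones
#'   responses: reconstruction is additive), `shear_windows` (per level, a
#'   list of direction windows) and `build_size`.
#' @examples
#' fb <- build_filter_bank(2, c(4, 8), c(64, 64))
#' # directional windows tile the frequency plane exactly:
#' max(abs(Reduce(`+`, fb$shear_windows[[1]]) - 1))
#' @export
build_filter_bank <- function(levels, directions_per_level, image_shape) {
  if (length(levels) != 1L || !is.finite(levels) || levels < 1 ||
      levels != round(levels)) {
    stop("`levels` must be a positive integer (got ", deparse(levels), ")")
  }
  levels <- as.integer(levels)
  directions_per_level <- as.integer(directions_per_level)
  if (length(directions_per_level) != levels) {
    stop("`directions_per_level` must have length `levels` (",
         levels, "), got ", length(directions_per_level))
  }
  for (l in seq_len(levels)) {
    d <- directions_per_level[l]
    if (d < 2 || bitwAnd(d, d - 1L) != 0L) {
      stop("direction count at level ", l,
           " must be a power of two >= 2, got ", d)
    }
  }
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape < 8L)) {
    stop("`image_shape` must be two dimensions, each >= 8 ",
         "(smaller grids cannot carry the filter support)")
  }

  om1 <- fft_omega(image_shape[1])          # row frequencies, column-constant
  om2 <- fft_omega(image_shape[2])
  W1 <- matrix(om1, image_shape[1], image_shape[2])
  W2 <- matrix(om2, image_shape[1], image_shape[2], byrow = TRUE)

  # Pyramid stage j filters the current approximation with the B3-spline
  # low-pass dilated by 2^(j-1) (a-trous: H0(z^(2^j)) in the cascade).
  pyr_analysis <- vector("list", levels + 1L)
  pyr_synthesis <- vector("list", levels + 1L)
  ones <- matrix(1, image_shape[1], image_shape[2])
  for (j in seq_len(levels + 1L)) {
    low <- atrous_lowpass_response(W1, 2^(j - 1)) *
           atrous_lowpass_response(W2, 2^(j - 1))
    pyr_analysis[[j]] <- list(low = low, high = 1 - low)
    pyr_synthesis[[j]] <- list(low = ones, high = ones)
  }

  shear_windows <- vector("list", levels)
  u <- pseudo_polar_angle(W1, W2)
  for (l in seq_len(levels)) {
    shear_windows[[l]] <- directional_windows(u, directions_per_level[l])
  }

  structure(
    list(levels = levels,
         directions_per_level = directions_per_level,
         pyr_analysis = pyr_analysis,
         pyr_synthesis = pyr_synthesis,
         shear_windows = shear_windows,
         build_size = image_shape),
    class = "nsst_filter_bank")
}

#' @export
print.nsst_filter_bank <- function(x, ...) {
  cat("Non-subsampled shearlet filter bank\n")
  cat("  image size: ", x$build_size[1], "x", x$build_size[2], "\n", sep = "")
  cat("  pyramid levels: ", x$levels, " (+1 split stage)\n", sep = "")
  cat("  directions (coarse to fine): ",
      paste(x$directions_per_level, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Angular FFT frequencies in (-pi, pi] for an n-point grid, FFT index order.
fft_omega <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  2 * pi * k / n
}

# 1-D frequency response of the binomial [1,4,6,4,1]/16 low-pass dilated by
# `s` (samples s steps apart): cos^4(s*omega/2). Real, DC gain 1, gain 0 at
# the (dilated) Nyquist.
atrous_lowpass_response <- function(omega, s) {
  cos(s * omega / 2)^4
}

# Pseudo-polar angle coordinate with period 4 covering 180 degrees:
# u = omega2/omega1 (slope) on the horizontal cone |omega1| >= |omega2|,
# u = 2 - omega1/omega2 on the vertical cone. Equal steps in u are integer
# shears of the slope, i.e. the grid the shear matrix generates.
pseudo_polar_angle <- function(W1, W2) {
  u <- matrix(0, nrow(W1), ncol(W1))
  horiz <- abs(W1) >= abs(W2) & (W1 != 0)
  u[horiz] <- W2[horiz] / W1[horiz]
  vert <- !horiz & (W2 != 0)
  u[vert] <- 2 - W1[vert] / W2[vert]
  # DC point stays at u = 0; any assignment works since windows sum to 1.
  u
}

# d raised-cosine bumps equally spaced in pseudo-polar angle; adjacent bumps
# overlap as cos^2/sin^2 so their pixel-wise sum is exactly 1.
directional_windows <- function(u, d) {
  step <- 4 / d
  lapply(seq_len(d), function(k) {
    centre <- -1 + (k - 1) * step
    delta <- ((u - centre + 2) %% 4) - 2
    w <- matrix(0, nrow(u), ncol(u))
    inside <- abs(delta) < step
    w[inside] <- cos(pi * delta[inside] / (2 * step))^2
    w
  })
}
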