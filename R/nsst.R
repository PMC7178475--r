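#' Non-subsampled shearlet decomposition
#'
#' Runs the undecimated pyramid for `fb$levels` stages; at each stage the
#' high-pass output is split into directional bands by multiplying its
#' spectrum with the level's shear windows. One additional pyramid stage
#' then splits the coarsest low-pass into the two approximation components
#' `low1` (coarsest) and `low2` (second component). Nothing is decimated,
#' so every band has the shape of the input.
#'
#' @param image 2-D numeric matrix, finite, shape equal to `fb$build_size`.
#' @param fb a filter bank from [build_filter_bank()].
#' @param provenance optional identifier stored with the coefficients.
#' @return an object of class `nsst_coeffs`: `low1`, `low2` (matrices),
#'   `highs` (list indexed `[[level]][[direction]]`, level 1 = coarsest),
#'   `shape`, `provenance`.
#' @seealso [nsst_reconstruct()]
#' @export
nsst_decompose <- function(image, fb, provenance = NULL) {
  stopifnot(inherits(fb, "nsst_filter_bank"))
  image <- as.matrix(image)
  if (!all(dim(image) == fb$build_size)) {
    stop("image shape (", paste(dim(image), collapse = "x"),
         ") does not match the filter bank's build size (",
         paste(fb$build_size, collapse = "x"), ")")
  }
  if (!all(is.finite(image))) stop("image must be finite")

  n <- length(image)
  cur <- stats::fft(image)                      # spectrum of the running low-pass
  K <- fb$levels
  highs <- vector("list", K)
  for (stage in seq_len(K)) {                   # stage 1 = finest scale
    level <- K + 1L - stage                     # stored coarse -> fine
    high_spec <- cur * fb$pyr_analysis[[stage]]$high
    cur <- cur * fb$pyr_analysis[[stage]]$low
    wins <- fb$shear_windows[[level]]
    highs[[level]] <- lapply(wins, function(w) {
      Re(stats::fft(high_spec * w, inverse = TRUE)) / n
    })
  }
  split_stage <- fb$pyr_analysis[[K + 1L]]
  low2 <- Re(stats::fft(cur * split_stage$high, inverse = TRUE)) / n
  low1 <- Re(stats::fft(cur * split_stage$low, inverse = TRUE)) / n

  structure(
    list(low1 = low1, low2 = low2, highs = highs,
         shape = dim(image), provenance = provenance),
    class = "nsst_coeffs")
}

#' Inverse non-subsampled shearlet transform
#'
#' Exact inverse of [nsst_decompose()] up to floating point: the analysis
#' filters at every split sum to one (pyramid: low + high = 1; directions:
#' the shear windows tile the plane), so synthesis is the plain sum of
#' `low1`, `low2` and every directional band.
#'
#' @param coeffs an `nsst_coeffs` object (bands may have been modified).
#' @param fb the filter bank the coefficients were produced with.
#' @return a numeric matrix of shape `coeffs$shape`.
#' @export
nsst_reconstruct <- function(coeffs, fb) {
  stopifnot(inherits(coeffs, "nsst_coeffs"), inherits(fb, "nsst_filter_bank"))
  if (length(coeffs$highs) != fb$levels) {
    stop("coefficient levels (", length(coeffs$highs),
         ") do not match the filter bank (", fb$levels, ")")
  }
  for (l in seq_len(fb$levels)) {
    if (length(coeffs$highs[[l]]) != fb$directions_per_level[l]) {
      stop("level ", l, " has ", length(coeffs$highs[[l]]),
           " bands but the filter bank expects ",
           fb$directions_per_level[l])
    }
  }
  out <- coeffs$low1 + coeffs$low2
  for (l in seq_len(fb$levels)) {
    for (k in seq_len(fb$directions_per_level[l])) {
      out <- out + coeffs$highs[[l]][[k]]
    }
  }
  out
}

#' @export
print.nsst_coeffs <- function(x, ...) {
  cat("NSST coefficients (", paste(x$shape, collapse = "x"), ")\n", sep = "")
  if (!is.null(x$provenance)) cat("  source: ", x$provenance, "\n", sep = "")
  cat("  levels (coarse to fine): ",
      paste(vapply(x$highs, length, 1L), collapse = ", "),
      " directional bands\n", sep = "")
  invisible(x)
}
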