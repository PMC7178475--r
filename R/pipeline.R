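#' End-to-end fusion pipeline
#'
#' Runs the five-step scheme on a registered pair: (1) decompose both
#' sources with the shearlet transform; (2) compute the network weight map
#' and decompose it too; (3) fuse the coarsest approximation by
#' activity-maximum selection and the second approximation component by
#' the spatial-frequency scalar blend; (4) fuse every directional detail
#' band with the matching weight band; (5) invert the transform. Pixel
#' values stay floating point in \[0, 255\] throughout; quantisation
#' happens only on write.
#'
#' @param image_a,image_b registered same-shape grayscale matrices on the
#'   0..255 scale (conventionally A = CT-like, B = MRI-like).
#' @param net trained [train_network()] model.
#' @param fb optional prebuilt filter bank matching the image size; built
#'   on the fly when `NULL`.
#' @param config a [fusion_config()].
#' @param levels,directions_per_level transform geometry used when `fb`
#'   is `NULL`.
#' @param stride weight-map window stride.
#' @return list of class `nsst_fusion`: `fused` (float matrix, clipped to
#'   \[0, 255\]), `weight_map`, `sf_weight` (the scalar blend weight used
#'   for the second approximation component), `config`.
#' @examples
#' \donttest{
#' pair <- make_pair(phantom_spec(c(64, 64), seed = 3),
#'                   phantom_spec(c(64, 64), seed = 3, modality = "mri_like"))
#' corpus <- make_blur_corpus(4, seed = 1, shape = c(64, 64))
#' ds <- make_patch_dataset(corpus$sharp, patch_size = 16, n_pairs = 200)
#' net <- train_network(ds, epochs = 2)
#' fus <- fuse_pipeline(pair$ct, pair$mri, net,
#'                      levels = 2, directions_per_level = c(4, 8))
#' }
#' @export
fuse_pipeline <- function(image_a, image_b, net, fb = NULL,
                          config = fusion_config(), levels = 4L,
                          directions_per_level = c(8L, 8L, 16L, 16L),
                          stride = 2L) {
  image_a <- as.matrix(image_a); image_b <- as.matrix(image_b)
  if (!all(dim(image_a) == dim(image_b))) {
    stop("source images differ in shape: ",
         paste(dim(image_a), collapse = "x"), " vs ",
         paste(dim(image_b), collapse = "x"))
  }
  if (is.null(fb)) {
    fb <- build_filter_bank(levels, directions_per_level, dim(image_a))
  }
  stopifnot(inherits(config, "fusion_config"))

  co_a <- nsst_decompose(image_a, fb, provenance = "A")
  co_b <- nsst_decompose(image_b, fb, provenance = "B")

  W_S <- weight_map(image_a, image_b, net, stride = stride)
  wmaps <- decompose_weight(W_S, fb)

  low1 <- fuse_low1(co_a$low1, co_b$low1, R = config$radius)
  sf_w <- spatial_frequency(wmaps$low)
  if (config$clamp_sf) sf_w <- min(sf_w, 1)
  low2 <- co_a$low2 * sf_w + co_b$low2 * (1 - sf_w)

  highs <- vector("list", fb$levels)
  for (l in seq_len(fb$levels)) {
    highs[[l]] <- vector("list", fb$directions_per_level[l])
    for (k in seq_len(fb$directions_per_level[l])) {
      highs[[l]][[k]] <- fuse_high(co_a$highs[[l]][[k]],
                                   co_b$highs[[l]][[k]],
                                   wmaps$highs[[l]][[k]],
                                   mode = config$weight_band_mode)
    }
  }
  fused_co <- structure(list(low1 = low1, low2 = low2, highs = highs,
                             shape = dim(image_a), provenance = "fused"),
                        class = "nsst_coeffs")
  fused <- nsst_reconstruct(fused_co, fb)
  fused[fused < 0] <- 0
  fused[fused > 255] <- 255
  structure(list(fused = fused, weight_map = W_S, sf_weight = sf_w,
                 config = config),
            class = "nsst_fusion")
}

#' @export
print.nsst_fusion <- function(x, ...) {
  cat("Fused image (", paste(dim(x$fused), collapse = "x"), ")\n", sep = "")
  cat("  weight map mean: ", signif(mean(x$weight_map), 4), "\n", sep = "")
  cat("  spatial-frequency blend weight: ", signif(x$sf_weight, 4), "\n",
      sep = "")
  invisible(x)
}

#' Read a grayscale image
#'
#' Reads PNG or TIFF; multi-channel input is collapsed to luminance
#' (0.299 R + 0.587 G + 0.114 B) with a warning; sub-unit sample values
#' (the png/tiff packages' native scale) are mapped to 0..255.
#'
#' @param path image file (.png, .tif/.tiff).
#' @return numeric matrix on the 0..255 scale.
#' @export
read_gray <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)"))
  if (length(dim(img)) == 3L) {
    ch <- dim(img)[3]
    if (ch >= 3L) {
      warning("multi-channel image collapsed to luminance: ", path)
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      img <- img[, , 1]
    }
  }
  img * 255
}

#' Write a grayscale image
#'
#' Clips to \[0, 255\] and quantises to 8 bits on write.
#'
#' @param img numeric matrix on the 0..255 scale.
#' @param path output file (.png, .tif/.tiff).
#' @export
write_gray <- function(img, path) {
  img <- as.matrix(img)
  x <- round(img)
  x[x < 0] <- 0
  x[x > 255] <- 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(x / 255, path),
    tif = ,
    tiff = tiff::writeTIFF(x / 255, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)"))
  invisible(path)
}
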