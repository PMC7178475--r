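#' Phantom specification
#'
#' Describes one synthetic brain-slice phantom. Two modalities are
#' emulated: `ct_like` (bright skull-like outer ring, low-texture
#' interior) and `mri_like` (dim rim, textured soft-tissue interior).
#' Identical specs produce identical phantoms; phantoms sharing a `seed`
#' share their geometry, so a ct/mri pair is co-registered by
#' construction.
#'
#' @param shape image dimensions (rows, cols), default 256 x 256.
#' @param seed geometry/noise seed.
#' @param modality `"ct_like"` or `"mri_like"`.
#' @param noise_sigma standard deviation of additive Gaussian noise, in
#'   gray levels.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(256L, 256L), seed = 1L,
                         modality = c("ct_like", "mri_like"),
                         noise_sigma = 2) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 32L)) {
    stop("phantom shape must be two dimensions, each >= 32")
  }
  structure(list(shape = shape, seed = as.integer(seed),
                 modality = match.arg(modality),
                 noise_sigma = noise_sigma),
            class = "phantom_spec")
}

#' Render one phantom
#'
#' @param spec a [phantom_spec()].
#' @return numeric matrix with integer values in \[0, 255\].
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- phantom_geometry(spec$shape, spec$seed)
  img <- if (spec$modality == "ct_like") {
    render_ct(geo)
  } else {
    render_mri(geo)
  }
  rng <- seeded_rng(spec$seed + 104729L)   # noise stream separate from geometry
  noise <- matrix(rng$rnorm(length(img), sd = spec$noise_sigma),
                  nrow(img), ncol(img))
  clip8(img + noise)
}

#' Co-registered CT-like / MRI-like phantom pair
#'
#' Both phantoms are rendered on the geometry of the shared seed, so their
#' anatomy is aligned pixel-for-pixel.
#'
#' @param spec_ct,spec_mri specs for the two modalities; shapes and seeds
#'   must match.
#' @return list with elements `ct` and `mri`, each an 8-bit-valued matrix.
#' @export
make_pair <- function(spec_ct = phantom_spec(modality = "ct_like"),
                      spec_mri = phantom_spec(modality = "mri_like")) {
  stopifnot(inherits(spec_ct, "phantom_spec"),
            inherits(spec_mri, "phantom_spec"))
  if (!all(spec_ct$shape == spec_mri$shape)) {
    stop("phantom pair shapes differ: ",
         paste(spec_ct$shape, collapse = "x"), " vs ",
         paste(spec_mri$shape, collapse = "x"))
  }
  if (spec_ct$seed != spec_mri$seed) {
    stop("phantom pair must share the geometry seed to be co-registered")
  }
  list(ct = make_phantom(spec_ct), mri = make_phantom(spec_mri))
}

#' Sharp/blurred training corpus
#'
#' Generates `n_images` phantoms (alternating modalities, varied seeds)
#' and pairs each with a Gaussian-blurred copy, blur sigma drawn uniformly
#' from `blur_sigma_range`. Feeds [make_patch_dataset()].
#'
#' @param n_images number of sharp images, >= 1.
#' @param blur_sigma_range length-2 positive range of blur standard
#'   deviations (pixels).
#' @param seed corpus seed.
#' @param shape phantom dimensions.
#' @return list with `sharp`, `blurred` (lists of matrices) and `sigma`
#'   (the per-image blur used).
#' @export
make_blur_corpus <- function(n_images, blur_sigma_range = c(1, 3), seed = 1L,
                             shape = c(128L, 128L)) {
  if (n_images < 1) stop("n_images must be >= 1")
  if (length(blur_sigma_range) != 2L || any(blur_sigma_range <= 0)) {
    stop("blur_sigma_range must be two positive values")
  }
  rng <- seeded_rng(seed)
  sharp <- vector("list", n_images)
  blurred <- vector("list", n_images)
  sigma <- numeric(n_images)
  for (i in seq_len(n_images)) {
    modality <- if (i %% 2L == 1L) "ct_like" else "mri_like"
    sp <- phantom_spec(shape = shape, seed = seed * 1000L + i,
                       modality = modality, noise_sigma = 1)
    sharp[[i]] <- make_phantom(sp)
    sigma[i] <- rng$runif(1, blur_sigma_range[1], blur_sigma_range[2])
    blurred[[i]] <- gaussian_blur(sharp[[i]], sigma[i])
  }
  list(sharp = sharp, blurred = blurred, sigma = sigma)
}

#' Gaussian blur of an image (separable, symmetric boundaries)
#' @param img numeric matrix.
#' @param sigma blur standard deviation in pixels, > 0.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  img <- as.matrix(img)
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-(-r:r)^2 / (2 * sigma^2))
  g <- g / sum(g)
  kernel_correlate(kernel_correlate(img, matrix(g, ncol = 1)),
                   matrix(g, nrow = 1))
}

# --- internal rendering ----------------------------------------------------

# Shared anatomy: head ellipse, skull ring, ventricles, a few tissue blobs
# and texture-band parameters, all drawn from the geometry seed.
phantom_geometry <- function(shape, seed) {
  rng <- seeded_rng(seed)
  m <- shape[1]; n <- shape[2]
  y <- matrix(seq(-1, 1, length.out = m), m, n)
  x <- matrix(seq(-1, 1, length.out = n), m, n, byrow = TRUE)
  a <- 0.78 + rng$runif(1, -0.05, 0.05)    # head semi-axes
  b <- 0.88 + rng$runif(1, -0.05, 0.05)
  d <- sqrt((x / a)^2 + (y / b)^2)
  n_blobs <- 3L
  blobs <- lapply(seq_len(n_blobs), function(i) {
    list(cx = rng$runif(1, -0.35, 0.35), cy = rng$runif(1, -0.35, 0.35),
         rx = rng$runif(1, 0.08, 0.2), ry = rng$runif(1, 0.08, 0.2),
         amp = rng$runif(1, 20, 60))
  })
  list(x = x, y = y, d = d,
       head = d < 1, skull = d >= 0.86 & d < 1, brain = d < 0.86,
       vent = sqrt(((x - 0.12) / 0.1)^2 + (y / 0.28)^2) < 1 |
              sqrt(((x + 0.12) / 0.1)^2 + (y / 0.28)^2) < 1,
       blobs = blobs,
       band_freq = rng$runif(1, 9, 13),
       band_phase = rng$runif(1, 0, 2 * pi),
       band_angle = rng$runif(1, 0, pi))
}

render_ct <- function(geo) {
  img <- matrix(12, nrow(geo$x), ncol(geo$x))        # air background
  img[geo$brain] <- 70 + 25 * (1 - geo$d[geo$brain]) # gently domed soft tissue
  img[geo$vent & geo$brain] <- 30                    # CSF: dark
  img[geo$skull] <- 235                              # bone: bright ring
  img
}

render_mri <- function(geo) {
  img <- matrix(8, nrow(geo$x), ncol(geo$x))
  t <- geo$band_freq * 2 * pi *
    (cos(geo$band_angle) * geo$x + sin(geo$band_angle) * geo$y) +
    geo$band_phase
  tissue <- 120 + 45 * sin(t) * cos(0.6 * t + 1) + 40 * (1 - geo$d)
  img[geo$brain] <- tissue[geo$brain]
  for (bl in geo$blobs) {
    mask <- sqrt(((geo$x - bl$cx) / bl$rx)^2 +
                 ((geo$y - bl$cy) / bl$ry)^2) < 1 & geo$brain
    img[mask] <- img[mask] + bl$amp
  }
  img[geo$vent & geo$brain] <- 215                   # CSF bright on T2
  img[geo$skull] <- 35                               # bone: dim rim
  img
}

clip8 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

# Local RNG stream that leaves the global .Random.seed untouched.
seeded_rng <- function(seed) {
  env <- new.env()
  local_seed <- function(expr_fun) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    if (is.null(env$state)) {
      set.seed(seed)
    } else {
      assign(".Random.seed", env$state, envir = globalenv())
    }
    res <- expr_fun()
    env$state <- get(".Random.seed", globalenv())
    res
  }
  list(
    runif = function(n, min = 0, max = 1) {
      local_seed(function() stats::runif(n, min, max))
    },
    rnorm = function(n, mean = 0, sd = 1) {
      local_seed(function() stats::rnorm(n, mean, sd))
    },
    sample_int = function(n, size, replace = FALSE) {
      local_seed(function() sample.int(n, size, replace = replace))
    }
  )
}
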