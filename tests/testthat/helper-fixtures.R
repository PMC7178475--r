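# Shared fixtures, built once per test run. The "small" network is sized
# for module-level behaviour checks; the "full" network uses the default
# training recipe (patch 16, 5000 pairs, 20 epochs) and backs the
# end-to-end checks.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

small_corpus <- function() {
  cached("small_corpus", function() {
    make_blur_corpus(6, c(1, 3), seed = 11, shape = c(96L, 96L))
  })
}

small_net <- function() {
  cached("small_net", function() {
    ds <- make_patch_dataset(small_corpus()$sharp, blur_sigma = c(1, 3),
                             patch_size = 16L, n_pairs = 800L, seed = 5L)
    train_network(ds, epochs = 5L, learning_rate = 1e-3, seed = 7L)
  })
}

full_net <- function() {
  cached("full_net", function() {
    corpus <- make_blur_corpus(10, c(1, 3), seed = 21, shape = c(128L, 128L))
    ds <- make_patch_dataset(corpus$sharp, blur_sigma = c(1, 3),
                             patch_size = 16L, n_pairs = 5000L, seed = 5L)
    train_network(ds, epochs = 20L, learning_rate = 1e-3, seed = 7L)
  })
}

holdout_dataset <- function(n_pairs = 500L) {
  # Phantom seeds disjoint from both training corpora.
  cached(paste0("holdout_", n_pairs), function() {
    corpus <- make_blur_corpus(6, c(1, 3), seed = 303, shape = c(128L, 128L))
    make_patch_dataset(corpus$sharp, blur_sigma = c(1, 3), patch_size = 16L,
                       n_pairs = n_pairs, seed = 99L)
  })
}

default_bank_256 <- function() {
  cached("fb256", function() {
    build_filter_bank(4L, c(8L, 8L, 16L, 16L), c(256L, 256L))
  })
}

default_bank_128 <- function() {
  cached("fb128", function() {
    build_filter_bank(4L, c(8L, 8L, 16L, 16L), c(128L, 128L))
  })
}
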