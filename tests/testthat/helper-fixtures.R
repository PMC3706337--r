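# Shared fixtures and lazily trained models, cached for the whole test run.

.rpl_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .rpl_cache)) assign(key, expr, envir = .rpl_cache)
  get(key, envir = .rpl_cache)
}

# small, fast spec used by most unit tests
small_spec <- function(seed = 11L, ...) {
  fixture_spec(image_size = c(160L, 160L), n_nuclei = 8L,
               n_bright_blobs = 1L, seed = seed, ...)
}

test_models <- function() {
  cached("models", {
    tr <- generate_suite(4L, fixture_spec(), seed = 99L)
    train_models(lapply(tr, `[[`, "image"), lapply(tr, `[[`, "truth"),
                 seed = 1L)
  })
}

# a synthetic image: one bright disk on dark background
disk_image <- function(n = 64L, r = 15L, fg = 200L, bg = 20L) {
  img <- matrix(bg, n, n)
  ctr <- (n + 1) / 2
  for (cc in 1:n) for (rr in 1:n)
    if ((rr - ctr)^2 + (cc - ctr)^2 <= r^2) img[rr, cc] <- fg
  img
}

# filled square as a pixel-index set
square_pixels <- function(dim, r0, c0, side) {
  as.vector(outer(r0:(r0 + side - 1L), (c0:(c0 + side - 1L) - 1L) * dim[1], "+"))
}

# uniform-mass appearance histogram concentrated at one intensity bin
point_hist <- function(bin, word = 1L) {
  ih <- numeric(64); ih[bin] <- 1
  wh <- numeric(12); wh[word] <- 1
  structure(list(intensity_hist = ih, word_hist = wh, normalizer = 1L),
            class = "rpl_appearance")
}
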