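# Bag-of-features appearance model. The image is divided into a grid of
# non-overlapping patch_size x patch_size patches; each patch is described by
# [min, max, mean, sd, 64-bin histogram of absolute pairwise pixel intensity
# differences] and assigned the nearest of 12 codebook words (Euclidean, after
# per-dimension standardization). A region's appearance is the pair of
# size-normalized histograms: 64 intensity bins over [0,255] and 12 word
# occurrence bins.

N_INTENSITY_BINS <- 64L
N_WORDS <- 12L

# 68-dim feature of one patch (vector of pixel values)
patch_feature <- function(vals) {
  d <- abs(outer(vals, vals, "-"))
  d <- d[upper.tri(d)]
  hist_d <- tabulate(pmin(d %/% 4L, 63L) + 1L, N_INTENSITY_BINS)
  c(min(vals), max(vals), mean(vals), stats::sd(vals),
    hist_d / max(1L, length(d)))
}

# grid decomposition: returns per-patch pixel indices and features
patch_grid_features <- function(image, patch_size) {
  h <- nrow(image); w <- ncol(image)
  pr <- (seq_len(h) - 1L) %/% patch_size
  pc <- (seq_len(w) - 1L) %/% patch_size
  pid <- outer(pr, pc * (max(pr) + 1L), "+") + 1L   # patch id per pixel
  split_idx <- split(seq_len(h * w), as.vector(pid))
  feats <- t(vapply(split_idx, function(ix) patch_feature(as.numeric(image[ix])),
                    numeric(4L + N_INTENSITY_BINS)))
  list(pixel_patch = as.vector(pid), patch_pixels = split_idx, features = feats,
       ids = as.integer(names(split_idx)))
}

assign_words <- function(features, codebook) {
  Z <- sweep(sweep(features, 2, codebook$center), 2, codebook$scale, "/")
  d2 <- outer(rowSums(Z^2), rowSums(codebook$centers^2), "+") -
    2 * Z %*% t(codebook$centers)
  max.col(-d2, ties.method = "first")
}

#' Appearance histogram of a region
#'
#' @param region integer vector of linear pixel indices
#' @param image integer intensity matrix (the enhanced working image)
#' @param codebook trained 12-word codebook from \code{build_codebook}
#' @param patch_size patch edge in px (8 by default)
#' @param grid optional precomputed result of an internal grid decomposition,
#'   reused across regions of the same image
#' @return list of class \code{rpl_appearance}: \code{intensity_hist} (64),
#'   \code{word_hist} (12), \code{normalizer} (region size in px)
#' @export
appearance_histogram <- function(region, image, codebook, patch_size = 8L,
                                 grid = NULL) {
  stopifnot(length(region) > 0, nrow(codebook$centers) == N_WORDS)
  if (is.null(grid)) {
    grid <- patch_grid_features(image, patch_size)
    grid$words <- assign_words(grid$features, codebook)
  }
  n <- length(region)
  ih <- tabulate(pmin(as.integer(image[region]) %/% 4L, 63L) + 1L,
                 N_INTENSITY_BINS)
  patches <- unique(grid$pixel_patch[region])
  wh <- tabulate(grid$words[match(patches, grid$ids)], N_WORDS)
  # both blocks are percentages of the region: intensities per pixel, words
  # per patch, so the two blocks carry comparable mass in the distance
  structure(list(intensity_hist = ih / n, word_hist = wh / length(patches),
                 normalizer = n),
            class = "rpl_appearance")
}

# one smoothing + downsampling step of the diffusion pyramid
diffuse_level <- function(d) {
  n <- length(d)
  sm <- 0.25 * c(d[1], d[-n]) + 0.5 * d + 0.25 * c(d[-1], d[n])
  sm[seq(1L, n, by = 2L)]
}

diffusion_distance_1d <- function(h1, h2) {
  d <- h1 - h2
  total <- sum(abs(d))
  while (length(d) > 1L) {
    d <- diffuse_level(d)
    total <- total + sum(abs(d))
  }
  total
}

#' Diffusion distance between appearance histograms
#'
#' Linear-time cross-bin histogram dissimilarity: the L1 norms of the
#' difference histogram are summed over a Gaussian pyramid (smooth with a
#' [1 2 1]/4 kernel, downsample by 2, repeat). Computed separately on the
#' intensity-histogram block and the word-histogram block, then summed, so
#' unrelated axes never mix. Symmetric; zero iff the histograms are equal.
#'
#' @param f1,f2 \code{rpl_appearance} objects with identical layout
#' @return nonnegative distance
#' @export
diffusion_distance <- function(f1, f2) {
  if (length(f1$intensity_hist) != length(f2$intensity_hist) ||
      length(f1$word_hist) != length(f2$word_hist))
    stop("appearance histogram layouts differ")
  diffusion_distance_1d(f1$intensity_hist, f2$intensity_hist) +
    diffusion_distance_1d(f1$word_hist, f2$word_hist)
}
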