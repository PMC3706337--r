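# Dense upright SIFT-style descriptors, vectorized over many pixels at once.
# 4x4 spatial cells of cell_px x cell_px pixels, 8 gradient-orientation bins,
# hard binning, L2 normalization with the standard 0.2 clipping. Upright and
# fixed-scale on purpose: rotation/scale invariance buys nothing for
# texture-vs-background discrimination and costs reproducibility.

# reflective padding keeps border descriptors defined; reflection wraps as
# often as needed so pads larger than the image are valid
pad_reflect <- function(img, m) {
  reflect <- function(x, n) {
    if (n == 1L) return(rep(1L, length(x)))
    r <- (x - 1L) %% (2L * n - 2L)
    ifelse(r >= n, 2L * n - 1L - r, r + 1L)
  }
  h <- nrow(img); w <- ncol(img)
  img[reflect((1L - m):(h + m), h), reflect((1L - m):(w + m), w)]
}

# per-orientation integral images of gradient magnitude
sift_integrals <- function(image, n_ori = 8L, pad = 16L) {
  p <- pad_reflect(image, pad)
  h <- nrow(p); w <- ncol(p)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (p[, 3:w] - p[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (p[3:h, ] - p[1:(h - 2), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ori <- atan2(gy, gx)                       # (-pi, pi]
  bin <- 1L + (floor((ori + pi) / (2 * pi / n_ori)) %% n_ori)
  ints <- lapply(seq_len(n_ori), function(k) {
    m <- mag * (bin == k)
    cs <- apply(m, 2, cumsum)
    cs <- t(apply(cs, 1, cumsum))
    rbind(0, cbind(0, cs))
  })
  list(ints = ints, pad = pad, dim = dim(image))
}

box_sum <- function(ii, r1, c1, r2, c2) {
  ii[cbind(r2 + 1L, c2 + 1L)] - ii[cbind(r1, c2 + 1L)] -
    ii[cbind(r2 + 1L, c1)] + ii[cbind(r1, c1)]
}

#' Dense SIFT descriptors at given pixels
#'
#' @param image integer intensity matrix
#' @param idx linear (column-major) pixel indices
#' @param cell_px size of one of the 4x4 descriptor cells (descriptor window
#'   is 4*cell_px square)
#' @return numeric matrix, one 128-dim row per pixel in \code{idx}
#' @export
dense_sift <- function(image, idx, cell_px = 4L) {
  si <- sift_integrals(image)
  rc <- arrayInd(idx, dim(image))
  # window top-left in padded coordinates, centered on the pixel
  half <- 2L * cell_px
  r0 <- rc[, 1] + si$pad - half; c0 <- rc[, 2] + si$pad - half
  n <- length(idx)
  desc <- matrix(0, n, 128L)
  col <- 0L
  for (cy in 0:3) for (cx in 0:3) {
    rr1 <- r0 + cy * cell_px; cc1 <- c0 + cx * cell_px
    for (k in 1:8) {
      col <- col + 1L
      desc[, col] <- box_sum(si$ints[[k]], rr1, cc1,
                             rr1 + cell_px - 1L, cc1 + cell_px - 1L)
    }
  }
  desc[desc < 0] <- 0   # integral-image round-off can leave tiny negatives
  nrm <- sqrt(rowSums(desc^2))
  nz <- nrm > 1e-12
  desc[nz, ] <- desc[nz, , drop = FALSE] / nrm[nz]
  desc[desc > 0.2] <- 0.2
  nrm2 <- sqrt(rowSums(desc^2))
  nz <- nrm2 > 1e-12
  desc[nz, ] <- desc[nz, , drop = FALSE] / nrm2[nz]
  desc
}

#' SIFT descriptor of a single pixel
#'
#' @param image integer intensity matrix
#' @param pixel c(row, col)
#' @param cell_px cell size in px
#' @return 128-dim numeric vector
#' @export
dense_descriptor <- function(image, pixel, cell_px = 4L) {
  stopifnot(pixel[1] >= 1, pixel[1] <= nrow(image),
            pixel[2] >= 1, pixel[2] <= ncol(image))
  as.vector(dense_sift(image, (pixel[2] - 1L) * nrow(image) + pixel[1],
                       cell_px = cell_px))
}
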