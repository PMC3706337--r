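# Minimum-volume enclosing ellipse (Loewner-John) by Khachiyan's barycentric
# coordinate ascent, used to complete under-segmented pixel-classification
# candidates to full elliptical extents.

#' Minimum-volume enclosing ellipse of a 2-D point set
#'
#' @param pts n x 2 matrix of (row, col) points
#' @param tol convergence tolerance on the barycentric update
#' @param max_iter iteration cap
#' @return list(center, A) describing \{x : (x-c)' A (x-c) <= 1\}, or NULL for
#'   degenerate inputs (< 3 non-collinear points)
#' @export
mvee <- function(pts, tol = 1e-4, max_iter = 500L) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n < 3L) return(NULL)
  if (abs(det(stats::cov(pts))) < 1e-12 &&
      qr(sweep(pts, 2, colMeans(pts)))$rank < 2L) return(NULL)
  Q <- t(cbind(pts, 1))            # 3 x n lifted points
  u <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    Xm <- Q %*% (u * t(Q))
    Minv <- tryCatch(solve(Xm), error = function(e) NULL)
    if (is.null(Minv)) return(NULL)
    m <- colSums(Q * (Minv %*% Q))   # Mahalanobis distances of lifted points
    j <- which.max(m)
    step <- (m[j] - 3) / (3 * (m[j] - 1))
    if (step < tol) break
    u <- (1 - step) * u
    u[j] <- u[j] + step
  }
  c0 <- as.vector(t(pts) %*% u)
  S <- t(pts) %*% (u * pts) - c0 %o% c0
  A <- solve(S) / 2
  list(center = c0, A = A)
}

rasterize_ellipse <- function(e, dim, slack = 1.05) {
  h <- dim[1]; w <- dim[2]
  ev <- eigen(e$A, symmetric = TRUE)
  rmax <- 1 / sqrt(min(ev$values)) * slack + 1
  rows <- max(1L, floor(e$center[1] - rmax)):min(h, ceiling(e$center[1] + rmax))
  cols <- max(1L, floor(e$center[2] - rmax)):min(w, ceiling(e$center[2] + rmax))
  dy <- outer(rows - e$center[1], rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - e$center[2])
  q <- e$A[1, 1] * dy^2 + 2 * e$A[1, 2] * dy * dx + e$A[2, 2] * dx^2
  ix <- which(q <= slack, arr.ind = TRUE)
  sort((cols[ix[, 2]] - 1L) * h + rows[ix[, 1]])
}

#' Complete a pixel-classification candidate to its elliptical extent
#'
#' Rasterizes the minimum-volume enclosing ellipse of the candidate's pixels
#' and intersects it with the cluster (so no pixels outside the cluster are
#' pulled in). Degenerate candidates are returned unchanged.
#'
#' @param pixels candidate pixel indices
#' @param cluster_pixels pixel indices of the enclosing cluster
#' @param dim image dimensions
#' @return list(pixels, ellipse_completed)
#' @export
complete_ellipse <- function(pixels, cluster_pixels, dim) {
  pts <- arrayInd(pixels, dim)
  e <- mvee(pts)
  if (is.null(e)) return(list(pixels = pixels, ellipse_completed = FALSE))
  filled <- rasterize_ellipse(e, dim)
  out <- intersect(union(filled, pixels), cluster_pixels)
  list(pixels = sort(out), ellipse_completed = TRUE)
}
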