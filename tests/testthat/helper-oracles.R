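# Independent oracles shared by the unit and acceptance tests. These
# re-implement the quantities from scratch (enumeration, brute force, direct
# sums) and never call the code paths they check.

# exhaustive minimum of the CRF energy over all 2^(n+1) labelings,
# vectorized over labelings
enumerate_energy <- function(crf) {
  n <- length(crf$unary_F)
  stopifnot(n <= 16L)
  codes <- 0:(2^n - 1)
  lab <- vapply(seq_len(n), function(b) bitwAnd(codes, 2^(b - 1)) > 0,
                logical(length(codes)))   # labelings x pixels
  unary <- lab %*% crf$unary_F + (!lab) %*% crf$unary_B
  spatial <- if (nrow(crf$pairs) > 0)
    (lab[, crf$pairs[, 1], drop = FALSE] !=
       lab[, crf$pairs[, 2], drop = FALSE]) %*% crf$psi
  else 0
  best <- Inf
  for (aux in c(TRUE, FALSE)) {
    det <- (lab != aux) %*% crf$phi
    e <- unary + (if (aux) 0 else crf$aux_unary[["B"]]) +
      0.5 * (det + spatial)
    best <- min(best, min(e))
  }
  best
}

random_crf_problem <- function(h, w, max_px = 16L) {
  repeat {
    img <- matrix(as.integer(sample(0:255, h * w, TRUE)), h, w)
    G <- sort(sample(h * w, sample(3:6, 1)))
    er <- expand_region(G, c(h, w))
    if (length(er$G_bar) <= max_px)
      return(rplseg:::build_crf(er, img, contrast_params()))
  }
}

# direct-sum Gaussian KDE (no shared code with the package's kde_density)
kde_oracle <- function(x, samples, h)
  sum(exp(-0.5 * ((x - samples) / h)^2)) / (length(samples) * h * sqrt(2 * pi))

# brute-force distances to the 8-connected inner boundary of M
oracle_dist_to_boundary <- function(px, M, dims) {
  inm <- logical(prod(dims)); inm[M] <- TRUE
  rc <- arrayInd(M, dims)
  bnd <- M[vapply(seq_along(M), function(i) {
    r <- rc[i, 1]; c <- rc[i, 2]
    r == 1 || r == dims[1] || c == 1 || c == dims[2] ||
      !inm[(c - 1) * dims[1] + r - 1] || !inm[(c - 1) * dims[1] + r + 1] ||
      !inm[(c - 2) * dims[1] + r] || !inm[c * dims[1] + r]
  }, logical(1))]
  brc <- arrayInd(bnd, dims)
  prc <- arrayInd(px, dims)
  vapply(seq_along(px), function(i)
    sqrt(min((prc[i, 1] - brc[, 1])^2 + (prc[i, 2] - brc[, 2])^2)), numeric(1))
}

oracle_nsd <- function(F, M, dims) {
  uni <- union(F, M)
  sym <- setdiff(uni, intersect(F, M))
  if (!length(sym)) return(0)
  sum(oracle_dist_to_boundary(sym, M, dims)) /
    sum(oracle_dist_to_boundary(uni, M, dims))
}

oracle_hd <- function(F, M, dims) {
  inm <- logical(prod(dims)); inm[F] <- TRUE
  rc <- arrayInd(F, dims)
  bnd <- F[vapply(seq_along(F), function(i) {
    r <- rc[i, 1]; c <- rc[i, 2]
    r == 1 || r == dims[1] || c == 1 || c == dims[2] ||
      !inm[(c - 1) * dims[1] + r - 1] || !inm[(c - 1) * dims[1] + r + 1] ||
      !inm[(c - 2) * dims[1] + r] || !inm[c * dims[1] + r]
  }, logical(1))]
  max(oracle_dist_to_boundary(bnd, M, dims))
}

random_blob <- function(dims, n_seeds = 2L) {
  m <- matrix(FALSE, dims[1], dims[2])
  for (s in seq_len(n_seeds)) {
    r <- sample(5:(dims[1] - 5), 1); c <- sample(5:(dims[2] - 5), 1)
    rad <- sample(2:5, 1)
    m[abs(row(m) - r) <= rad & abs(col(m) - c) <= rad] <- TRUE
  }
  which(m)
}
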