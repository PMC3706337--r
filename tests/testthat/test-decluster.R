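# --- dense descriptors ------------------------------------------------------

test_that("dense SIFT behaves like an upright descriptor", {
  flat <- matrix(100L, 40, 40)
  expect_equal(dense_descriptor(flat, c(20, 20)), rep(0, 128))
  # translation covariance away from borders
  set.seed(42)
  tex <- matrix(as.integer(sample(0:255, 60 * 60, TRUE)), 60, 60)
  shifted <- matrix(0L, 60, 60)
  shifted[6:60, 6:60] <- tex[1:55, 1:55]
  d1 <- dense_descriptor(tex, c(25, 25))
  d2 <- dense_descriptor(shifted, c(30, 30))
  expect_equal(d1, d2, tolerance = 1e-12)
  # clipping contract: entries capped at 0.2 before the final renormalization
  # (so post-norm entries stay below 0.2 / ||clipped|| < ~0.3), unit norm
  idx <- sample(which(matrix(TRUE, 60, 60)), 10)
  idx <- idx[arrayInd(idx, c(60, 60))[, 1] > 16 & arrayInd(idx, c(60, 60))[, 1] < 44 &
               arrayInd(idx, c(60, 60))[, 2] > 16 & arrayInd(idx, c(60, 60))[, 2] < 44]
  D <- dense_sift(tex, idx)
  expect_true(all(D >= 0 & D <= 1))
  expect_true(all(abs(sqrt(rowSums(D^2)) - 1) < 1e-9))
})

# --- appearance histograms --------------------------------------------------

test_that("appearance histograms are size-normalized percentages", {
  models <- test_models()
  img <- matrix(64L, 64, 64)
  region <- square_pixels(c(64L, 64L), 9L, 9L, 16L)
  f <- appearance_histogram(region, img, models$codebook, patch_size = 8L)
  # constant region: one intensity bin, one word
  expect_equal(sum(f$intensity_hist > 0), 1L)
  expect_equal(sum(f$intensity_hist), 1)          # mass / region size
  expect_equal(sum(f$word_hist > 0), 1L)
  expect_equal(f$normalizer, 256L)
  # translation by a multiple of the patch size leaves the histogram unchanged
  region2 <- square_pixels(c(64L, 64L), 17L, 25L, 16L)
  f2 <- appearance_histogram(region2, img, models$codebook, patch_size = 8L)
  expect_equal(f$intensity_hist, f2$intensity_hist)
  expect_equal(f$word_hist, f2$word_hist)
})

test_that("duplicating a region's patches leaves the histogram unchanged", {
  models <- test_models()
  set.seed(1)
  img <- matrix(as.integer(sample(0:255, 64 * 64, TRUE)), 64, 64)
  base <- square_pixels(c(64L, 64L), 1L, 1L, 8L)
  img[base + 16L] <- img[base]  # copy the patch 16 rows down (patch-aligned)
  f1 <- appearance_histogram(base, img, models$codebook, patch_size = 8L)
  f2 <- appearance_histogram(c(base, base + 16L), img, models$codebook,
                             patch_size = 8L)
  expect_equal(f1$intensity_hist, f2$intensity_hist, tolerance = 1e-12)
  expect_equal(f1$word_hist, f2$word_hist, tolerance = 1e-12)
})

# --- diffusion distance -----------------------------------------------------

test_that("diffusion distance is a symmetric premetric with cross-bin order", {
  models <- test_models()
  set.seed(3)
  img <- matrix(as.integer(sample(0:255, 64 * 64, TRUE)), 64, 64)
  r1 <- square_pixels(c(64L, 64L), 5L, 5L, 12L)
  r2 <- square_pixels(c(64L, 64L), 30L, 30L, 12L)
  f1 <- appearance_histogram(r1, img, models$codebook)
  f2 <- appearance_histogram(r2, img, models$codebook)
  expect_equal(diffusion_distance(f1, f1), 0)
  expect_equal(diffusion_distance(f1, f2), diffusion_distance(f2, f1))
  expect_gte(diffusion_distance(f1, f2), 0)
  # unit-mass histograms at bins i and j: distance non-decreasing in |i - j|
  # (EMD ordering) up to a sub-1% ripple from the dyadic pyramid boundaries
  d <- vapply(2:40, function(j)
    diffusion_distance(point_hist(1L), point_hist(j)), numeric(1))
  expect_true(all(diff(d) >= -0.01))
  expect_gt(d[30] , d[1])
  bad <- point_hist(1L); bad$intensity_hist <- numeric(32)
  expect_error(diffusion_distance(point_hist(1L), bad), "layout")
})

# --- KDE probability --------------------------------------------------------

test_that("reference_probability matches a dense numerical KDE oracle", {
  # oracle: independent direct-sum KDE implementation
  kde_oracle <- function(x, samples, h)
    sum(exp(-0.5 * ((x - samples) / h)^2)) / (length(samples) * h * sqrt(2 * pi))
  set.seed(7)
  for (trial in 1:100) {
    K <- sample(3:12, 1)
    dists <- runif(K - 1, 0, 10)
    prof <- distance_profile(1L, dists)
    dkx <- runif(1, 0, 12)
    p0 <- kde_oracle(dkx, dists, prof$bandwidth)
    pmax_ref <- max(vapply(dists, kde_oracle, numeric(1),
                           samples = dists, h = prof$bandwidth))
    expect_equal(reference_probability(dkx, prof),
                 min(max(p0 / pmax_ref, 0), 1), tolerance = 1e-9)
  }
})

test_that("reference_probability respects its fixed-point and tail limits", {
  prof <- distance_profile(1L, c(2, 2, 2))
  expect_equal(reference_probability(2, prof), 1)      # density peak
  expect_lt(reference_probability(1e6, prof), 1e-12)   # Gaussian tail
  prof2 <- distance_profile(1L, c(1, 2, 3))
  expect_equal(prof2$bandwidth, 1.06 * sd(c(1, 2, 3)) * 3^(-1 / 5))
  p <- reference_probability(2, prof2)
  expect_true(p >= 0 && p <= 1)
})

test_that("validation thresholding follows the two-branch rule", {
  prm <- validation_params()
  expect_equal(prm$alpha1, 0.6)
  expect_equal(prm$alpha2, 0.4)
  expect_equal(validate_candidate(0.9, c(1.0, 0.2), prm), "F")  # 0.9 > 0.6
  expect_equal(validate_candidate(0.5, c(1.0), prm), "B")       # 0.5 < 0.6
  expect_equal(validate_candidate(0.3, numeric(0), prm), "B")   # 0.3 < 0.4
  expect_equal(validate_candidate(0.41, numeric(0), prm), "F")
})

test_that("candidate probability lies in [0,1] and ignores reference order", {
  models <- test_models()
  set.seed(11)
  img <- matrix(as.integer(sample(0:255, 96 * 96, TRUE)), 96, 96)
  regions <- lapply(seq(1, 70, by = 14), function(r)
    square_pixels(c(96L, 96L), r, r, 10L))
  hists <- lapply(regions, appearance_histogram, image = img,
                  codebook = models$codebook)
  cand <- appearance_histogram(square_pixels(c(96L, 96L), 40L, 8L, 10L),
                               img, models$codebook)
  Q1 <- rplseg:::candidate_probability(cand, hists)
  expect_true(Q1 >= 0 && Q1 <= 1)
  set.seed(2)
  for (i in 1:5) {
    Qp <- rplseg:::candidate_probability(cand, sample(hists))
    expect_equal(Qp, Q1, tolerance = 1e-12)
  }
})

# --- minimum-volume enclosing ellipse --------------------------------------

test_that("complete_ellipse covers candidates and respects the cluster", {
  dims <- c(40L, 40L)
  sq <- square_pixels(dims, 10L, 10L, 4L)
  cluster <- square_pixels(dims, 1L, 1L, 40L)
  cc <- complete_ellipse(sq, cluster, dims)
  expect_true(cc$ellipse_completed)
  expect_true(all(sq %in% cc$pixels))
  # Loewner-John oracle on the square's corner points: area pi * a * b with
  # a = b = half-diagonal of the 3x3 extent -> area pi * (3/sqrt(2))^2 * 1.0
  corners <- rbind(c(10, 10), c(10, 13), c(13, 10), c(13, 13))
  eo <- mvee(corners, tol = 1e-9, max_iter = 5000L)
  oracle_area <- pi / sqrt(det(eo$A))
  expect_lte(length(cc$pixels), oracle_area * 1.35 + 8)  # rasterization slack
  # intersection contract: half-moon near cluster edge stays inside cluster
  small_cluster <- square_pixels(dims, 8L, 8L, 8L)
  cc2 <- complete_ellipse(sq, small_cluster, dims)
  expect_true(all(cc2$pixels %in% small_cluster))
  # degenerate: collinear pixels are returned unchanged
  line <- square_pixels(dims, 5L, 5L, 1L)
  line <- c(line, line + 1L, line + 2L)
  cc3 <- complete_ellipse(line, cluster, dims)
  expect_false(cc3$ellipse_completed)
  expect_equal(cc3$pixels, line)
})

test_that("mvee encloses random point sets tightly", {
  set.seed(5)
  for (i in 1:20) {
    pts <- matrix(runif(40, 0, 30), ncol = 2)
    e <- mvee(pts, tol = 1e-7, max_iter = 2000L)
    q <- apply(pts, 1, function(p) {
      d <- p - e$center
      as.numeric(t(d) %*% e$A %*% d)
    })
    # Khachiyan converges sublinearly; at this iteration budget points sit
    # within a ~0.5% inflation of the unit ellipse
    expect_true(all(q <= 1 + 5e-3))
  }
})
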