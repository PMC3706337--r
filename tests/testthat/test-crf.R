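# --- closed-form term checks ------------------------------------------------

test_that("intensity term is the two-sided sigmoid with unit cost mass", {
  it <- intensity_term(1, 1)
  expect_equal(it$cost_F, 0.5)
  expect_equal(it$cost_B, 0.5)
  it2 <- intensity_term(2, 1)               # f_i - lambda_G = 1
  expect_equal(1 - it2$cost_F, 1 / (1 + exp(-2)))
  f <- runif(20, 0, 2)
  it3 <- intensity_term(f, 0.9)
  expect_equal(it3$cost_F + it3$cost_B, rep(1, 20))
})

test_that("detection weight follows the contrast branch rule", {
  expect_equal(detection_weight(150, 100, 500), 1)        # brighter than I_G
  expect_equal(detection_weight(100, 100, 500), 1)        # exp(0)
  expect_equal(detection_weight(90, 100, 100), exp(-0.5)) # at the average
  expect_true(all(diff(detection_weight(seq(100, 0, -10), 100, 900)) <= 0))
})

test_that("spatial weight is maximal for equal intensities and decays", {
  expect_equal(spatial_weight(80, 80, 200), 1)
  w <- spatial_weight(80, 80 + (0:10) * 5, 200)
  expect_true(all(diff(w) <= 0))
})

test_that("lambda search picks the smallest gamma keeping foreground alive", {
  img <- matrix(0L, 3, 3)
  img[1, 1:3] <- c(80L, 100L, 120L)   # f = 0.8, 1.0, 1.2
  res <- compute_lambda(c(1L, 4L, 7L), img, contrast_params())
  expect_equal(res$gamma_G, 0.25)
  expect_equal(res$lambda_G, 1 - 0.25 * (1 - 0.8))
  expect_false(res$fell_back)
  # constant region: all f equal, no pixel exceeds lambda at any gamma
  img2 <- matrix(100L, 3, 3)
  res2 <- compute_lambda(1:9, img2, contrast_params())
  expect_equal(res2$gamma_G, 1)
  expect_true(res2$fell_back)
  # lambda non-increasing along the gamma grid
  lam <- vapply(seq(0.25, 1, 0.25), function(g)
    1 - g * (1 - 0.8), numeric(1))
  expect_true(all(diff(lam) <= 0))
})

# --- expansion --------------------------------------------------------------

test_that("expand_region margin is half the short axis, clipped and strict", {
  img_shape <- c(60L, 60L)
  disk <- which(matrix(outer((1:60 - 30)^2, (1:60 - 30)^2, "+") <= 100,
                       60, 60))
  er <- expand_region(disk, img_shape)
  expect_equal(er$margin, 10)   # radius-10 disk: short axis 20
  expect_true(all(disk %in% er$G_bar))
  expect_gt(length(er$G_bar), length(disk))
  # touching the border: clipped but still a superset
  edge <- which(matrix(outer((1:60 - 3)^2, (1:60 - 30)^2, "+") <= 64, 60, 60))
  er2 <- expand_region(edge, img_shape)
  expect_true(all(edge %in% er2$G_bar))
  expect_true(all(arrayInd(er2$G_bar, img_shape)[, 1] >= 1))
})

# --- exact inference vs exhaustive enumeration ------------------------------
# (enumerate_energy / random_crf_problem live in helper-oracles.R)

test_that("graph-cut inference attains the enumeration optimum (50 cases)", {
  set.seed(17)
  for (trial in 1:50) {
    crf <- random_crf_problem(4L, 4L)
    res <- rplseg:::crf_mincut(crf)
    e_cut <- rplseg:::crf_energy(crf, res$pixel_labels, res$aux_label)
    e_opt <- enumerate_energy(crf)
    expect_equal(e_cut, e_opt, tolerance = 1e-9)
    expect_true(res$aux_label)   # B cost of the auxiliary node is prohibitive
  }
})

test_that("all pairwise weights are nonnegative (submodularity)", {
  set.seed(23)
  for (trial in 1:10) {
    crf <- random_crf_problem(5L, 5L)
    expect_true(all(crf$phi >= 0))
    expect_true(all(crf$psi >= 0))
    expect_equal(crf$pairwise_scale, 0.5)
    expect_equal(unname(crf$aux_unary), c(0, length(crf$unary_F)))
  }
})

test_that("refinement recovers a dim rim and never beats the oracle energy", {
  # nucleus with bright core and dim rim; G misses the rim
  img <- matrix(30L, 50, 50)
  for (cc in 1:50) for (rr in 1:50) {
    d <- sqrt((rr - 25)^2 + (cc - 25)^2)
    if (d <= 10) img[rr, cc] <- as.integer(160 - 6 * d)
  }
  core <- which(matrix(outer((1:50 - 25)^2, (1:50 - 25)^2, "+") <= 36, 50, 50))
  truth <- which(matrix(outer((1:50 - 25)^2, (1:50 - 25)^2, "+") <= 100, 50, 50))
  ref <- refine_contour(core, img, contrast_params())
  expect_gt(dice(ref$pixels, truth), dice(core, truth))
  expect_gte(dice(ref$pixels, truth), 0.9)
  # energy of the refined labeling <= energy of reproducing G exactly
  er <- expand_region(core, dim(img))
  crf <- rplseg:::build_crf(er, img, contrast_params())
  res <- rplseg:::crf_mincut(crf)
  e_ref <- rplseg:::crf_energy(crf, res$pixel_labels, res$aux_label)
  e_g <- rplseg:::crf_energy(crf, er$G_bar %in% core, TRUE)
  expect_lte(e_ref, e_g + 1e-9)
})

test_that("refinement is covariant under intensity scaling (no clipping)", {
  img <- matrix(20L, 40, 40)
  for (cc in 1:40) for (rr in 1:40)
    if ((rr - 20)^2 + (cc - 20)^2 <= 64) img[rr, cc] <- 80L
  G <- which(matrix(outer((1:40 - 20)^2, (1:40 - 20)^2, "+") <= 36, 40, 40))
  r1 <- refine_contour(G, img, contrast_params())
  r2 <- refine_contour(G, img * 2L, contrast_params())  # max 160, no clipping
  expect_equal(sort(r1$pixels), sort(r2$pixels))
  # determinism
  r3 <- refine_contour(G, img, contrast_params())
  expect_identical(r1$pixels, r3$pixels)
})

# --- post-processing and assembly ------------------------------------------

test_that("postprocess_segments removes sub-1/10-average components", {
  m <- matrix(FALSE, 40, 60)
  m[2:11, 2:11] <- TRUE       # 100
  m[2:11, 20:29] <- TRUE      # 100
  m[30:30, 50:54] <- TRUE     # 5 < (205/3)/10 = 6.83 -> removed
  out <- postprocess_segments(m)
  expect_equal(sum(out), 200L)
  expect_false(any(out[30, 50:54]))
  # single component untouched; empty mask passes through
  single <- matrix(FALSE, 10, 10); single[2:4, 2:4] <- TRUE
  expect_identical(postprocess_segments(single), single)
  empty <- matrix(FALSE, 5, 5)
  expect_identical(postprocess_segments(empty), empty)
})

test_that("assemble_result resolves overlaps by contrast, deterministically", {
  img <- matrix(10L, 30, 30)
  a <- square_pixels(c(30L, 30L), 3L, 3L, 8L)      # mean intensity 120
  b <- square_pixels(c(30L, 30L), 8L, 8L, 8L)      # mean intensity 200, overlaps a
  img[a] <- 120L; img[b] <- 200L
  out <- assemble_result(list(a, b), img, c(30L, 30L))
  expect_equal(dim(out), c(30L, 30L))
  contested <- intersect(a, b)
  lab_b <- unique(out[setdiff(b, a)])
  expect_length(lab_b, 1L)
  expect_true(all(out[contested] == lab_b))        # brighter region wins
  # deterministic labeling order for disjoint regions (top-left centroid first)
  c1 <- square_pixels(c(30L, 30L), 20L, 20L, 5L)
  c2 <- square_pixels(c(30L, 30L), 2L, 2L, 5L)
  out2 <- assemble_result(list(c1, c2), img, c(30L, 30L))
  expect_equal(unique(out2[c2]), 1L)
  expect_equal(unique(out2[c1]), 2L)
})
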