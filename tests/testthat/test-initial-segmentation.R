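test_that("detect_mser finds nothing in a uniform image", {
  expect_equal(n_regions(detect_mser(matrix(50L, 40, 40), 0.7)), 0L)
})

test_that("detect_mser recovers a bright disk against a thresholding oracle", {
  img <- disk_image(64L, r = 15L)
  h <- detect_mser(img, 0.7)
  expect_equal(n_regions(h), 1L)
  expect_equal(h$regions[[1]]$level, "single")
  # oracle: any threshold in (20, 200) yields exactly the disk pixels
  oracle <- which(img > 100L)
  found <- h$regions[[1]]$pixels
  # agreement within a 2-px boundary band
  orc <- arrayInd(oracle, dim(img)); frc <- arrayInd(found, dim(img))
  extra <- setdiff(found, oracle); miss <- setdiff(oracle, found)
  band_ok <- function(px) {
    if (length(px) == 0L) return(TRUE)
    rc <- arrayInd(px, dim(img))
    d2 <- outer(rc[, 1], orc[, 1], "-")^2 + outer(rc[, 2], orc[, 2], "-")^2
    all(sqrt(apply(d2, 1, min)) <= 2)
  }
  expect_true(band_ok(extra))
  expect_lte(length(miss) + length(extra), 0.1 * length(oracle))
})

test_that("two bright disks inside a plateau nest as lower + two uppers", {
  img <- matrix(20L, 120, 120)
  for (cc in 1:120) for (rr in 1:120) {
    if ((rr - 60)^2 / 900 + (cc - 60)^2 / 400 <= 1) img[rr, cc] <- 90L
    if ((rr - 60)^2 + (cc - 48)^2 <= 64) img[rr, cc] <- 200L
    if ((rr - 60)^2 + (cc - 72)^2 <= 64) img[rr, cc] <- 200L
  }
  h <- detect_mser(img, 0.7)
  lev <- sort(sapply(h$regions, `[[`, "level"))
  expect_identical(lev, c("lower", "upper", "upper"))
  validate_hierarchy <- rplseg:::validate_hierarchy
  expect_true(validate_hierarchy(h))
  low <- which(sapply(h$regions, `[[`, "level") == "lower")
  for (r in h$regions) if (r$level == "upper") {
    expect_equal(r$parent_id, h$regions[[low]]$id)
    expect_true(all(r$pixels %in% h$regions[[low]]$pixels))
  }
})

test_that("adaptive_mser stops at v1 when a nest already exists, else walks to v2", {
  img <- matrix(20L, 120, 120)
  for (cc in 1:120) for (rr in 1:120) {
    if ((rr - 60)^2 / 900 + (cc - 60)^2 / 400 <= 1) img[rr, cc] <- 90L
    if ((rr - 60)^2 + (cc - 48)^2 <= 64) img[rr, cc] <- 200L
    if ((rr - 60)^2 + (cc - 72)^2 <= 64) img[rr, cc] <- 200L
  }
  res <- adaptive_mser(img, mser_params())
  expect_equal(res$used_max_variation, 0.7)
  # single disk: no nest at any step; schedule must end at v2 = 0.4
  res2 <- adaptive_mser(disk_image(), mser_params())
  expect_equal(res2$used_max_variation, 0.4)
})

test_that("enhance_contrast implements the normalization exactly", {
  # craft image whose detected region has {R}0 = 40, {R}2 = 120:
  # region = two pixels of 40 and 200 -> min 40, mean 120, factor 128/80 = 1.6
  img <- matrix(c(40L, 200L, 100L, 10L), 2, 2)
  h <- rplseg:::new_hierarchy(list(list(id = 1L, pixels = c(1L, 2L),
                                        level = "single", parent_id = NA)),
                              c(2L, 2L))
  out <- enhance_contrast(img, h, C = 128)
  expect_equal(out[1, 1], 64L)          # 40 * 1.6
  expect_equal(out[2, 1], 255L)         # 200 * 1.6 = 320, clipped
  expect_equal(out[1, 2], 160L)         # 100 * 1.6
  expect_equal(out[2, 2], 16L)
  expect_true(all(out >= 0L & out <= 255L))
  # {R}0 + {R}2 = 2C leaves the image unchanged: min 100, mean 156
  img2 <- matrix(c(100L, 212L, 77L, 3L), 2, 2)
  h2 <- rplseg:::new_hierarchy(list(list(id = 1L, pixels = c(1L, 2L),
                                         level = "single", parent_id = NA)),
                               c(2L, 2L))
  expect_identical(enhance_contrast(img2, h2, C = 128), img2)
  expect_error(enhance_contrast(img, rplseg:::new_hierarchy(list(), c(2L, 2L))),
               "no detected regions")
})

test_that("enhancement preserves intensity order away from clipping", {
  fx <- generate_fixture(small_spec())
  h <- detect_mser(fx$image, 0.7)
  out <- enhance_contrast(fx$image, h, C = 128)
  unclipped <- out > 0L & out < 255L
  ord_in <- order(fx$image[unclipped])
  vals_out <- out[unclipped][ord_in]
  expect_true(all(diff(vals_out) >= -1L))  # integer rounding can swap ties only
})

test_that("classify_hierarchy partitions regions and conserves counts", {
  mk <- function(id, level, parent = NA)
    list(id = id, pixels = id, level = level, parent_id = parent)
  h <- rplseg:::new_hierarchy(list(mk(1L, "single"), mk(2L, "single"),
                                   mk(3L, "lower"), mk(4L, "upper", 3L),
                                   mk(5L, "upper", 3L)), c(10L, 10L))
  ch <- classify_hierarchy(h)
  expect_length(ch$nuclei, 2L)
  expect_length(ch$clusters, 1L)
  expect_length(ch$clusters[[1]]$uppers, 2L)
  # only singles
  h2 <- rplseg:::new_hierarchy(list(mk(1L, "single"), mk(2L, "single"),
                                    mk(3L, "single")), c(10L, 10L))
  ch2 <- classify_hierarchy(h2)
  expect_length(ch2$nuclei, 3L)
  expect_length(ch2$clusters, 0L)
})

test_that("run_initial_segmentation terminates and finds low-contrast nuclei", {
  # one low-contrast nucleus (mean 60 on background 40) plus a bright anchor
  img <- matrix(40L, 140, 140)
  for (cc in 1:140) for (rr in 1:140) {
    if ((rr - 40)^2 + (cc - 40)^2 <= 100) img[rr, cc] <- 60L
    if ((rr - 100)^2 + (cc - 100)^2 <= 100) img[rr, cc] <- 180L
  }
  s1 <- run_initial_segmentation(img, mser_params(), merge_model = NULL)
  expect_lte(length(s1$region_counts), 10L)
  dim_px <- which(matrix(
    outer((1:140 - 40)^2, rep(1, 140)) +
      outer(rep(1, 140), (1:140 - 40)^2) <= 100, 140, 140))
  hit <- any(vapply(s1$hierarchy$regions, function(r)
    overlap_ratio(r$pixels, dim_px) > 0.5, logical(1)))
  expect_true(hit)
  expect_error(run_initial_segmentation(matrix(7L, 64, 64)), "no interest regions")
})

test_that("merge_nested_regions collapses elliptical pairs, keeps clusters", {
  models <- test_models()
  # elliptical nested pair: disk with a brighter core
  img <- matrix(20L, 100, 100)
  for (cc in 1:100) for (rr in 1:100) {
    if ((rr - 50)^2 + (cc - 50)^2 <= 144) img[rr, cc] <- 120L
    if ((rr - 50)^2 + (cc - 50)^2 <= 36) img[rr, cc] <- 190L
  }
  h <- detect_mser(img, 0.7)
  expect_setequal(sapply(h$regions, `[[`, "level"), c("lower", "upper"))
  merged <- merge_nested_regions(h, img, models$merge_model)
  expect_true(all(sapply(merged$regions, `[[`, "level") == "single"))
  expect_equal(n_regions(merged), 1L)
  # two-nuclei cluster must remain nested
  img2 <- matrix(20L, 120, 120)
  for (cc in 1:120) for (rr in 1:120) {
    if ((rr - 60)^2 / 900 + (cc - 60)^2 / 400 <= 1) img2[rr, cc] <- 90L
    if ((rr - 60)^2 + (cc - 48)^2 <= 64) img2[rr, cc] <- 200L
    if ((rr - 60)^2 + (cc - 72)^2 <= 64) img2[rr, cc] <- 200L
  }
  h2 <- detect_mser(img2, 0.7)
  merged2 <- merge_nested_regions(h2, img2, models$merge_model)
  expect_equal(sort(sapply(merged2$regions, `[[`, "level")),
               c("lower", "upper", "upper"))
  # no pairs: unchanged
  h3 <- detect_mser(disk_image(), 0.7)
  expect_equal(n_regions(merge_nested_regions(h3, disk_image(),
                                              models$merge_model)), 1L)
})
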