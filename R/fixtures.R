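#' Synthetic fluorescence-nuclei fixture specification
#'
#' Describes a synthetic single-channel image of fluorescently labelled nuclei
#' with the artifacts that make real micrographs hard: per-nucleus intensity
#' differences (some nuclei much dimmer than others), intensity falloff within
#' a nucleus, an inhomogeneous background, bright nucleus-like distractor
#' blobs, and touching nuclei. Defaults describe a moderately hard image:
#' 20 nuclei of 6-12 px semi-axes on a 256 x 256 frame, mean intensities
#' spanning 130-200 over a base-30 background, 30% intra-nucleus falloff with
#' correlated chromatin-like speckle, 3 very bright distractors on elevated
#' plateaus, and additive Gaussian noise (sd 5).
#'
#' @param image_size c(height, width) in pixels
#' @param n_nuclei number of nuclei (>= 1)
#' @param nucleus_axes_range c(min, max) semi-axis in px
#' @param nucleus_mean_intensity_range c(low, high), integer means drawn
#'   uniformly from this range
#' @param intra_nucleus_gradient maximal fractional radial intensity falloff
#'   within one nucleus, in [0, 1]
#' @param background_base background intensity
#' @param n_bright_blobs number of bright background distractor blobs
#' @param blob_intensity_range c(low, high) distractor intensity
#' @param touching_fraction fraction of nuclei placed adjacent to another
#' @param noise_sd additive Gaussian noise standard deviation
#' @param seed integer RNG seed
#' @return object of class \code{rpl_fixture_spec}
#' @export
fixture_spec <- function(image_size = c(256L, 256L), n_nuclei = 20L,
                         nucleus_axes_range = c(6, 12),
                         nucleus_mean_intensity_range = c(130, 200),
                         intra_nucleus_gradient = 0.3,
                         background_base = 30,
                         n_bright_blobs = 3L,
                         blob_intensity_range = c(210, 250),
                         touching_fraction = 0.2,
                         noise_sd = 5,
                         seed = 1L) {
  spec <- list(image_size = as.integer(image_size), n_nuclei = as.integer(n_nuclei),
               nucleus_axes_range = nucleus_axes_range,
               nucleus_mean_intensity_range = nucleus_mean_intensity_range,
               intra_nucleus_gradient = intra_nucleus_gradient,
               background_base = background_base,
               n_bright_blobs = as.integer(n_bright_blobs),
               blob_intensity_range = blob_intensity_range,
               touching_fraction = touching_fraction,
               noise_sd = noise_sd, seed = as.integer(seed))
  class(spec) <- "rpl_fixture_spec"
  validate_fixture_spec(spec)
  spec
}

validate_fixture_spec <- function(spec) {
  stopifnot(length(spec$image_size) == 2L, all(spec$image_size >= 32L))
  if (spec$n_nuclei < 1L) stop("n_nuclei must be >= 1")
  ints <- c(spec$nucleus_mean_intensity_range, spec$background_base,
            spec$blob_intensity_range)
  if (any(ints < 0) || any(ints > 255)) stop("intensity parameters must lie in [0, 255]")
  if (spec$intra_nucleus_gradient < 0 || spec$intra_nucleus_gradient > 1)
    stop("intra_nucleus_gradient must lie in [0, 1]")
  if (spec$touching_fraction < 0 || spec$touching_fraction > 1)
    stop("touching_fraction must lie in [0, 1]")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  if (diff(spec$nucleus_axes_range) < 0 || spec$nucleus_axes_range[1] < 2)
    stop("nucleus_axes_range must be increasing with min >= 2")
  invisible(spec)
}

# run code under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# pixels of an ellipse (center cy,cx; semi-axes a >= b; angle theta), plus the
# normalized elliptical radius of each pixel, as a logical matrix + rho matrix
ellipse_mask <- function(h, w, cy, cx, a, b, theta) {
  rmax <- ceiling(max(a, b)) + 1L
  rows <- max(1L, floor(cy - rmax)):min(h, ceiling(cy + rmax))
  cols <- max(1L, floor(cx - rmax)):min(w, ceiling(cx + rmax))
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  rho <- sqrt((u / a)^2 + (v / b)^2)
  idx <- which(rho <= 1, arr.ind = TRUE)
  list(rows = rows[idx[, 1]], cols = cols[idx[, 2]], rho = rho[rho <= 1])
}

#' Generate one synthetic fixture image
#'
#' Renders elliptical nuclei (randomized orientation, integer per-nucleus mean
#' intensity, linear radial falloff), distractor blobs sitting on dim halos
#' (so that salient-region detection nests them like real bright background),
#' a smoothly varying background, and additive Gaussian noise, clipped and
#' rounded to 8-bit. Identical \code{spec} (including its seed) gives a
#' bitwise-identical fixture.
#'
#' @param spec an \code{rpl_fixture_spec}
#' @return list with \code{image} (integer matrix), \code{truth} (instance
#'   label matrix, 0 = background), \code{distractor_mask} (logical matrix)
#' @export
generate_fixture <- function(spec) {
  validate_fixture_spec(spec)
  with_seed(spec$seed, {
    h <- spec$image_size[1]; w <- spec$image_size[2]
    img <- matrix(spec$background_base, h, w)
    # smooth background inhomogeneity: a few broad low-amplitude bumps
    n_bumps <- 3L
    for (i in seq_len(n_bumps)) {
      cy <- runif(1, 1, h); cx <- runif(1, 1, w)
      amp <- runif(1, 4, 12); sig <- runif(1, 0.2, 0.4) * min(h, w)
      dy <- (seq_len(h) - cy) / sig; dx <- (seq_len(w) - cx) / sig
      img <- img + amp * outer(exp(-dy^2 / 2), exp(-dx^2 / 2))
    }
    truth <- matrix(0L, h, w)
    g <- spec$intra_nucleus_gradient
    axr <- spec$nucleus_axes_range
    mir <- spec$nucleus_mean_intensity_range
    centers <- matrix(NA_real_, spec$n_nuclei, 2)
    binors <- numeric(spec$n_nuclei)
    n_touch <- floor(spec$touching_fraction * spec$n_nuclei)
    for (k in seq_len(spec$n_nuclei)) {
      placed <- FALSE
      for (attempt in seq_len(300L)) {
        a <- runif(1, axr[1], axr[2]); b <- runif(1, axr[1], a)
        theta <- runif(1, 0, pi)
        touching <- (k > 1L && k <= n_touch + 1L)
        if (touching) {
          j <- sample.int(k - 1L, 1L)
          dir <- runif(1, 0, 2 * pi)
          d <- binors[j] + b + 1     # centers ~ sum of semi-minor axes
          cy <- centers[j, 1] + d * sin(dir); cx <- centers[j, 2] + d * cos(dir)
        } else {
          cy <- runif(1, axr[2] + 2, h - axr[2] - 2)
          cx <- runif(1, axr[2] + 2, w - axr[2] - 2)
        }
        if (cy < a + 2 || cy > h - a - 2 || cx < a + 2 || cx > w - a - 2) next
        em <- ellipse_mask(h, w, cy, cx, a, b, theta)
        lin <- cbind(em$rows, em$cols)
        free <- truth[lin] == 0L
        if (!touching && any(!free)) next
        # near-tangency: adjacency with a genuine intensity saddle between
        # the partners, the ambiguous case for watershed-style splitting
        if (touching && mean(!free) > 0.03) next
        if (sum(free) < 12L) next
        mean_int <- sample(seq(mir[1], mir[2]), 1L)
        peak <- mean_int / (1 - 2 * g / 3)  # E[rho] = 2/3 over an ellipse
        vals <- peak * (1 - g * em$rho)
        if (g > 0) {
          # chromatin-like multiplicative speckle (spatially correlated),
          # zero-mean so the drawn mean intensity is preserved in expectation;
          # disabled in the exact-contrast regime (gradient 0)
          nr <- length(unique(em$rows)); nc <- length(unique(em$cols))
          field <- matrix(rnorm((nr + 2) * (nc + 2)), nr + 2, nc + 2)
          sm <- (field[1:nr, 1:nc] + field[2:(nr + 1), 1:nc] +
                   field[3:(nr + 2), 1:nc] + field[2:(nr + 1), 2:(nc + 1)] +
                   field[2:(nr + 1), 3:(nc + 2)]) / sqrt(5)
          rix <- match(em$rows, sort(unique(em$rows)))
          cix <- match(em$cols, sort(unique(em$cols)))
          vals <- vals * pmax(0.3, 1 + 0.12 * sm[cbind(rix, cix)])
        }
        img[lin[free, , drop = FALSE]] <- vals[free]
        truth[lin[free, , drop = FALSE]] <- k
        centers[k, ] <- c(cy, cx); binors[k] <- b
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place nucleus ", k,
                        " within image bounds after 300 attempts")
    }
    # bright distractor blobs sitting on broad elevated background areas
    # (homogeneous texture, off-nuclei): the bright-background artifact that
    # salient-region detection nests as upper regions inside large lowers
    distractor <- matrix(FALSE, h, w)
    bir <- spec$blob_intensity_range
    for (k in seq_len(spec$n_bright_blobs)) {
      for (attempt in seq_len(300L)) {
        a <- runif(1, axr[1], axr[2]) * 0.8; b <- runif(1, 0.7 * a, a)
        theta <- runif(1, 0, pi)
        halo <- 3.2
        cy <- runif(1, halo * a + 2, h - halo * a - 2)
        cx <- runif(1, halo * a + 2, w - halo * a - 2)
        # broad flat lobed plateau (union of jittered ellipses): steep edge
        # makes it a stable (lower) salient region, and its irregular,
        # non-elliptical footprint keeps the merge classifier from ever
        # collapsing the nested blob into a single-level detection
        offs <- matrix(runif(6, -0.9, 0.9) * a, 3, 2)
        lobes <- lapply(1:3, function(li)
          ellipse_mask(h, w, cy + offs[li, 1], cx + offs[li, 2],
                       halo * a * runif(1, 0.7, 1), halo * b * runif(1, 0.7, 1),
                       runif(1, 0, pi)))
        linh <- unique(do.call(rbind, lapply(lobes, function(e)
          cbind(e$rows, e$cols))))
        if (any(truth[linh] != 0L) || any(distractor[linh]) ||
            any(linh[, 1] %in% c(1L, h)) || any(linh[, 2] %in% c(1L, w))) next
        eb <- ellipse_mask(h, w, cy, cx, a, b, theta)
        linb <- cbind(eb$rows, eb$cols)
        img[linh] <- pmax(img[linh], spec$background_base + 22)
        img[linb] <- sample(seq(bir[1], bir[2]), 1L)
        distractor[linb] <- TRUE
        break
      }
    }
    if (spec$noise_sd > 0) img <- img + rnorm(h * w, 0, spec$noise_sd)
    img <- matrix(as.integer(round(pmin(pmax(img, 0), 255))), h, w)
    structure(list(image = img, truth = truth, distractor_mask = distractor,
                   spec = spec), class = "rpl_fixture")
  })
}

#' Generate a reproducible suite of fixtures
#'
#' Per-image seeds are derived from \code{seed}, so the whole suite is
#' reproducible from \code{(n_images, spec, seed)}.
#'
#' @param n_images number of images (>= 1)
#' @param spec an \code{rpl_fixture_spec}; its own seed field is overridden
#' @param seed suite-level seed
#' @return list of fixtures
#' @export
generate_suite <- function(n_images, spec = fixture_spec(), seed = 1L) {
  stopifnot(n_images >= 1)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max %/% 2L, n_images))
  lapply(seq_len(n_images), function(i) {
    s <- spec; s$seed <- seeds[i]
    generate_fixture(s)
  })
}

#' Write a fixture to disk
#'
#' Image as 8-bit grayscale (PNG or TIFF by extension), truth as 16-bit
#' instance-label TIFF, spec as JSON.
#'
#' @param fixture result of \code{generate_fixture}
#' @param dir output directory
#' @param stem file name stem
#' @export
write_fixture <- function(fixture, dir, stem = "fixture") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_image(fixture$image, file.path(dir, paste0(stem, ".tif")), bits = 8L)
  write_image(fixture$truth, file.path(dir, paste0(stem, "_truth.tif")), bits = 16L)
  spec <- fixture$spec; class(spec) <- NULL
  jsonlite::write_json(spec, file.path(dir, paste0(stem, "_spec.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
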