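# Interest-region hierarchy: a flat list of regions, each a list with
#   id        integer
#   pixels    sorted integer vector of linear (column-major) pixel indices
#   level     "single", "lower" or "upper"
#   parent_id integer or NA ("upper" regions point at their "lower" parent)
# Nesting depth is at most 2 by construction.

new_hierarchy <- function(regions, dim) {
  structure(list(regions = regions, dim = as.integer(dim)),
            class = "rpl_hierarchy")
}

#' Number of interest regions in a hierarchy
#' @param hierarchy an \code{rpl_hierarchy}
#' @return integer count (all levels)
#' @export
n_regions <- function(hierarchy) length(hierarchy$regions)

region_levels <- function(hierarchy)
  vapply(hierarchy$regions, `[[`, character(1), "level")

region_parents <- function(hierarchy)
  vapply(hierarchy$regions, function(r)
    if (is.null(r$parent_id) || is.na(r$parent_id)) NA_integer_
    else as.integer(r$parent_id), integer(1))

children_of <- function(hierarchy, id) {
  par <- region_parents(hierarchy)
  which(!is.na(par) & par == id)
}

# structural invariants; used by tests and defensive checks
validate_hierarchy <- function(hierarchy) {
  lev <- region_levels(hierarchy)
  par <- region_parents(hierarchy)
  stopifnot(all(lev %in% c("single", "lower", "upper")))
  stopifnot(all(is.na(par[lev != "upper"])))
  for (i in which(lev == "upper")) {
    p <- par[i]
    stopifnot(!is.na(p), lev[p] == "lower")
    stopifnot(all(hierarchy$regions[[i]]$pixels %in% hierarchy$regions[[p]]$pixels))
  }
  for (p in which(lev == "lower")) {
    kids <- children_of(hierarchy, p)
    if (length(kids) > 1L) {
      all_px <- unlist(lapply(hierarchy$regions[kids], `[[`, "pixels"))
      stopifnot(!anyDuplicated(all_px))  # sibling uppers pairwise disjoint
    }
  }
  invisible(TRUE)
}

region_centroid <- function(pixels, dim) {
  rc <- arrayInd(pixels, dim)
  c(mean(rc[, 1]), mean(rc[, 2]))
}

# second-moment best-fit ellipse of a pixel set: center, semi-axes (major a,
# minor b), orientation. Matches the usual regionprops convention where the
# ellipse has the same normalized second central moments as the region.
region_ellipse <- function(pixels, dim) {
  rc <- arrayInd(pixels, dim)
  mu <- colMeans(rc)
  y <- rc[, 1] - mu[1]; x <- rc[, 2] - mu[2]
  cyy <- mean(y^2); cxx <- mean(x^2); cxy <- mean(x * y)
  cyy <- max(cyy, 1 / 12); cxx <- max(cxx, 1 / 12)  # floor for 1-px-thin sets
  tr <- cxx + cyy; dt <- sqrt(max(0, (cxx - cyy)^2 + 4 * cxy^2))
  l1 <- (tr + dt) / 2; l2 <- max((tr - dt) / 2, 1e-9)
  a <- 2 * sqrt(l1); b <- 2 * sqrt(l2)
  theta <- 0.5 * atan2(2 * cxy, cxx - cyy)
  list(center = mu, a = a, b = b, theta = theta)
}

# shape/size features used by the nested-pair merge classifier:
# area, axis ratio, solidity, fraction of symmetric difference with the
# best-fit ellipse
region_shape_features <- function(pixels, dim) {
  n <- length(pixels)
  rc <- arrayInd(pixels, dim)
  el <- region_ellipse(pixels, dim)
  hull_area <- tryCatch({
    ch <- grDevices::chull(rc[, 2], rc[, 1])
    xs <- rc[ch, 2]; ys <- rc[ch, 1]
    abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2 + n / max(n, 2)
  }, error = function(e) n)
  solidity <- min(1, n / max(hull_area, 1))
  # rasterized best-fit ellipse vs region
  h <- dim[1]; w <- dim[2]
  em <- ellipse_mask(h, w, el$center[1], el$center[2], el$a, el$b, el$theta)
  epix <- sort((em$cols - 1L) * h + em$rows)
  inter <- length(intersect(pixels, epix))
  sym <- (n - inter) + (length(epix) - inter)
  c(area = n, axis_ratio = el$a / el$b, solidity = solidity,
    ellipse_residual = sym / n)
}

#' Detect maximally stable extremal regions (bright on dark)
#'
#' Builds the max-tree of upper level sets, scores component stability by
#' relative area variation across \code{delta} gray levels, keeps regions with
#' variation below \code{max_variation} and area within bounds, prunes
#' near-duplicates along branches (min diversity 0.2), and collapses the
#' result to a hierarchy of depth at most 2 (lower regions with disjoint
#' upper children, or single-level regions).
#'
#' @param image integer matrix of intensities in [0, 255]
#' @param max_variation stability threshold
#' @param params \code{mser_params()} (delta and area bounds are used here)
#' @return an \code{rpl_hierarchy}; possibly empty
#' @export
detect_mser <- function(image, max_variation, params = mser_params()) {
  stopifnot(length(image) > 0)
  max_area <- params$max_area
  if (max_area <= 1) max_area <- ceiling(max_area * length(image))
  res <- cpp_mser(matrix(as.integer(image), nrow(image)),
                  as.integer(params$delta), max_variation,
                  as.integer(params$min_area), as.integer(max_area),
                  params$min_diversity)
  regions <- lapply(seq_along(res$pixels), function(i) {
    list(id = i, pixels = res$pixels[[i]], level = res$level[i],
         parent_id = res$parent[i])
  })
  new_hierarchy(regions, dim(image))
}

#' MSER / stage-1 parameters
#'
#' \code{v1}, \code{v2}, \code{delta_v} drive the adaptive MaxVariation
#' schedule (start at v1, step down by delta_v until v2 or a two-level
#' hierarchy appears); \code{C} is the contrast-enhancement scaling constant.
#' Defaults are the published operating point for high-resolution
#' nuclear-marker images: v1 = 0.7, v2 = 0.4, delta_v = 0.1, C = 128.
#'
#' @param delta MSER intensity step for the stability test
#' @param min_area,max_area area bounds in px (max_area <= 1 is interpreted
#'   as a fraction of the image area)
#' @param v1,v2,delta_v MaxVariation schedule
#' @param C contrast scaling constant in [1, 255]
#' @param min_diversity branch diversity threshold
#' @return list of class \code{rpl_mser_params}
#' @export
mser_params <- function(delta = 5L, min_area = 30L, max_area = 0.25,
                        v1 = 0.7, v2 = 0.4, delta_v = 0.1, C = 128,
                        min_diversity = 0.2) {
  p <- list(delta = as.integer(delta), min_area = as.integer(min_area),
            max_area = max_area, v1 = v1, v2 = v2, delta_v = delta_v,
            C = C, min_diversity = min_diversity)
  stopifnot(p$delta_v > 0, p$v2 <= p$v1, p$min_area < max(p$max_area, 2) * 1e9)
  class(p) <- "rpl_mser_params"
  p
}
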