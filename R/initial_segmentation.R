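#' Adaptive MaxVariation schedule
#'
#' Runs \code{detect_mser} with MaxVariation = v1, then v1 - delta_v, ...,
#' stopping as soon as the hierarchy has more than one region level (i.e. a
#' lower/upper nest exists) or the schedule reaches v2. Returns the first
#' qualifying hierarchy and the MaxVariation value it used.
#'
#' @param image integer intensity matrix
#' @param params \code{mser_params()}
#' @return list(hierarchy, used_max_variation)
#' @export
adaptive_mser <- function(image, params = mser_params()) {
  vs <- seq(params$v1, params$v2, by = -params$delta_v)
  if (length(vs) == 0L || abs(vs[length(vs)] - params$v2) > 1e-9)
    vs <- c(vs, params$v2)
  hier <- NULL
  used <- params$v2
  for (v in vs) {
    hier <- detect_mser(image, v, params)
    used <- v
    if (any(region_levels(hier) != "single")) break
  }
  list(hierarchy = hier, used_max_variation = used)
}

#' Contrast enhancement from detected interest regions
#'
#' Scales the whole image by C / (0.5 ({R}0 + {R}2)) where {R}0 and {R}2 are
#' the minimum and mean intensity over the pooled pixels of all detected
#' interest regions, then clips to [0, 255]. The normalizer is usually below
#' C, so contrast between pixels grows proportionally while saturation caps
#' the brightest areas.
#'
#' @param image integer intensity matrix
#' @param regions \code{rpl_hierarchy} detected on \code{image}
#' @param C scaling constant
#' @return enhanced integer intensity matrix, same shape
#' @export
enhance_contrast <- function(image, regions, C = 128) {
  if (n_regions(regions) == 0L)
    stop("cannot enhance contrast: no detected regions (normalization undefined)")
  pooled <- unique(unlist(lapply(regions$regions, `[[`, "pixels")))
  vals <- image[pooled]
  scale <- C / (0.5 * (min(vals) + mean(vals)))
  matrix(as.integer(round(pmin(pmax(image * scale, 0), 255))), nrow(image))
}

#' Merge under-segmented nested pairs
#'
#' A single nucleus occasionally splits into a lower region with one upper
#' child (the upper being a bright core). For each lower region with exactly
#' one upper child, shape/size features of the combined (= lower) pixel set
#' are scored by the trained linear merge classifier; accepted pairs collapse
#' into one single-level region. Lowers with two or more children are genuine
#' clusters and are left untouched.
#'
#' @param hierarchy \code{rpl_hierarchy}
#' @param image intensity matrix (unused by the default features; kept for
#'   extended feature sets)
#' @param merge_model trained \code{rpl_svm} from
#'   \code{train_merge_classifier}
#' @return updated hierarchy
#' @export
merge_nested_regions <- function(hierarchy, image, merge_model) {
  if (is.null(merge_model) || !isTRUE(merge_model$trained))
    stop("merge_model must be trained")
  lev <- region_levels(hierarchy)
  if (!any(lev == "lower")) return(hierarchy)
  drop <- logical(length(lev))
  for (p in which(lev == "lower")) {
    kids <- children_of(hierarchy, p)
    if (length(kids) != 1L) next
    feats <- region_shape_features(hierarchy$regions[[p]]$pixels, hierarchy$dim)
    if (svm_predict(merge_model, matrix(feats, 1)) > 0) {
      hierarchy$regions[[p]]$level <- "single"
      drop[kids] <- TRUE
    }
  }
  keep <- which(!drop)
  remap <- match(seq_along(lev), keep)
  regions <- lapply(seq_along(keep), function(i) {
    r <- hierarchy$regions[[keep[i]]]
    r$id <- i
    if (!is.na(r$parent_id)) r$parent_id <- remap[r$parent_id]
    r
  })
  new_hierarchy(regions, hierarchy$dim)
}

#' Split a hierarchy into nuclei and clusters
#'
#' Single-level regions are taken as true nuclei; lower regions with at least
#' one upper child are clusters (their uppers travel with them).
#'
#' @param hierarchy \code{rpl_hierarchy}
#' @return list(nuclei = regions, clusters = list of list(region, uppers))
#' @export
classify_hierarchy <- function(hierarchy) {
  lev <- region_levels(hierarchy)
  nuclei <- hierarchy$regions[lev == "single"]
  clusters <- lapply(which(lev == "lower"), function(p) {
    kids <- children_of(hierarchy, p)
    if (length(kids) == 0L) return(NULL)
    list(region = hierarchy$regions[[p]], uppers = hierarchy$regions[kids])
  })
  clusters <- Filter(Negate(is.null), clusters)
  list(nuclei = nuclei, clusters = clusters)
}

#' Stage 1: contrast-enhanced salient region detection
#'
#' Alternates adaptive MSER detection and contrast enhancement on the working
#' image until the number of detected regions stops changing (or an iteration
#' cap of 10 is hit), then applies the nested-pair merge step. Enhancement
#' compounds: each pass rescales the current working image.
#'
#' @param image integer intensity matrix
#' @param params \code{mser_params()}
#' @param merge_model trained merge classifier (NULL skips merging, for
#'   diagnostics only)
#' @param max_iter iteration cap
#' @return list(hierarchy, image = final enhanced image,
#'   region_counts = per-iteration counts, used_max_variation)
#' @export
run_initial_segmentation <- function(image, params = mser_params(),
                                     merge_model = NULL, max_iter = 10L) {
  counts <- integer(0)
  cur <- image
  det_img <- image   # image the reported hierarchy was detected on
  hier <- NULL
  used_v <- NA_real_
  for (it in seq_len(max_iter)) {
    am <- adaptive_mser(cur, params)
    counts <- c(counts, n_regions(am$hierarchy))
    # a shrinking count means enhancement started saturating/merging regions
    # rather than revealing new ones: keep the previous iterate
    if (it > 1L && counts[it] < counts[it - 1L]) break
    hier <- am$hierarchy
    used_v <- am$used_max_variation
    det_img <- cur
    if (it > 1L && counts[it] == counts[it - 1L]) break
    if (n_regions(hier) == 0L) {
      if (it > 1L) break
      next
    }
    if (it < max_iter) cur <- enhance_contrast(cur, hier, params$C)
  }
  cur <- det_img
  if (is.null(hier) || n_regions(hier) == 0L)
    stop("no interest regions found after ", max_iter, " iterations")
  if (!is.null(merge_model))
    hier <- merge_nested_regions(hier, cur, merge_model)
  list(hierarchy = hier, image = cur, region_counts = counts,
       used_max_variation = used_v)
}
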