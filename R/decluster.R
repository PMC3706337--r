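# Stage 2: decompose clusters into candidate nuclei and validate them.
# References are the single- and upper-level regions from stage 1; candidates
# are the uppers themselves plus connected components of pixels classified as
# foreground by the dense-descriptor SVM.

#' Identify candidate regions inside one cluster
#'
#' Every enclosed upper region is a candidate. All cluster pixels are
#' classified foreground/background on their dense SIFT descriptors, and each
#' connected foreground component that does not touch an upper region (and is
#' at least \code{min_candidate_area} px) becomes an additional candidate.
#'
#' @param cluster list(region, uppers) from \code{classify_hierarchy}
#' @param image intensity matrix (enhanced working image)
#' @param pixel_model trained polynomial-kernel \code{rpl_svm}
#' @param dim image dimensions
#' @param min_candidate_area smallest admissible new candidate
#' @return list of candidates: list(pixels, source, ellipse_completed)
#' @export
identify_candidates <- function(cluster, image, pixel_model, dim = dim(image),
                                min_candidate_area = 30L) {
  if (is.null(pixel_model) || !isTRUE(pixel_model$trained))
    stop("pixel_model must be trained")
  cands <- lapply(cluster$uppers, function(u)
    list(pixels = u$pixels, source = "upper_region", ellipse_completed = FALSE,
         region_id = u$id))
  upx <- unlist(lapply(cluster$uppers, `[[`, "pixels"))
  cpx <- cluster$region$pixels
  desc <- dense_sift(image, cpx)
  fg <- svm_predict(pixel_model, desc) > 0
  if (any(fg)) {
    mask <- matrix(FALSE, dim[1], dim[2])
    mask[cpx[fg]] <- TRUE
    lab <- cpp_label_components(mask, 4L)
    for (l in seq_len(max(lab))) {
      comp <- which(lab == l)
      if (length(comp) < min_candidate_area) next
      if (length(intersect(comp, upx)) > 0L) next
      cc <- complete_ellipse(comp, cpx, dim)
      cands[[length(cands) + 1L]] <-
        list(pixels = cc$pixels, source = "pixel_classification",
             ellipse_completed = cc$ellipse_completed, region_id = NA_integer_)
    }
  }
  cands
}

# A Gaussian KDE over K-1 profile distances is meaningless for very small K:
# the normal-reference bandwidth and the max-normalization both degenerate,
# and a single false-positive reference dominates the pool. Below this many
# quadrant references, validation falls back to the image-wide pool.
MIN_QUADRANT_REFS <- 6L

# image quadrant (1..4) of a pixel-set centroid
quadrant_of <- function(pixels, dim) {
  ctr <- region_centroid(pixels, dim)
  1L + (ctr[1] > dim[1] / 2) + 2L * (ctr[2] > dim[2] / 2)
}

# Q for one candidate against a subset of references (by index), reusing the
# precomputed reference-reference distance matrix
q_from_profiles <- function(cand_hist, ref_hists, dmat, subset) {
  probs <- vapply(subset, function(k) {
    prof <- distance_profile(k, dmat[k, setdiff(subset, k)])
    reference_probability(diffusion_distance(ref_hists[[k]], cand_hist), prof)
  }, numeric(1))
  mean(probs)
}

#' Stage 2: decluster processing
#'
#' Keeps all single-level regions as detected nuclei and as references,
#' identifies candidates within every cluster, scores each candidate's
#' probability of being a nucleus from the distance profiles of references in
#' its image quadrant (falling back to all references when the quadrant holds
#' fewer than two), applies the thresholding rule, and resolves any overlaps
#' created by ellipse completion in favour of the higher-probability
#' candidate.
#'
#' @param image enhanced working image from stage 1
#' @param hierarchy stage-1 \code{rpl_hierarchy} (post merge)
#' @param models \code{rpl_models} bundle (pixel classifier + codebook)
#' @param params \code{validation_params()}
#' @param min_candidate_area smallest admissible new candidate in px
#' @return list of detected regions: list(pixels, provenance, Q)
#' @export
decluster_process <- function(image, hierarchy, models,
                              params = validation_params(),
                              min_candidate_area = 30L) {
  ch <- classify_hierarchy(hierarchy)
  dim <- hierarchy$dim
  grid <- patch_grid_features(image, params$patch_size)
  grid$words <- assign_words(grid$features, models$codebook)
  hist_of <- function(px) appearance_histogram(px, image, models$codebook,
                                               params$patch_size, grid = grid)
  detected <- lapply(ch$nuclei, function(r)
    list(pixels = r$pixels, provenance = "single", Q = NA_real_))
  if (length(ch$clusters) == 0L) return(detected)

  refs <- c(ch$nuclei, unlist(lapply(ch$clusters, `[[`, "uppers"),
                              recursive = FALSE))
  ref_hists <- lapply(refs, function(r) hist_of(r$pixels))
  ref_quad <- vapply(refs, function(r) quadrant_of(r$pixels, dim), integer(1))
  ref_ids <- vapply(refs, function(r) as.integer(r$id), integer(1))
  K <- length(refs)
  dmat <- matrix(0, K, K)
  if (K >= 2L) for (i in seq_len(K - 1L)) for (j in (i + 1L):K)
    dmat[i, j] <- dmat[j, i] <- diffusion_distance(ref_hists[[i]], ref_hists[[j]])

  for (cl in ch$clusters) {
    cands <- identify_candidates(cl, image, models$pixel_model, dim,
                                 min_candidate_area)
    if (length(cands) == 0L) next
    Qs <- vapply(seq_along(cands), function(ci) {
      cand <- cands[[ci]]
      self <- if (!is.na(cand$region_id)) which(ref_ids == cand$region_id)
              else integer(0)
      avail <- setdiff(seq_len(K), self)
      sub <- avail[ref_quad[avail] == quadrant_of(cand$pixels, dim)]
      if (length(sub) < MIN_QUADRANT_REFS) sub <- avail  # sparse-quadrant fallback
      if (length(sub) < 2L) return(NA_real_)      # validation impossible
      q_from_profiles(hist_of(cand$pixels), ref_hists, dmat, sub)
    }, numeric(1))
    labels <- vapply(seq_along(cands), function(ci) {
      if (is.na(Qs[ci]))  # too few references anywhere: keep uppers, drop rest
        return(if (cands[[ci]]$source == "upper_region") "F" else "B")
      validate_candidate(Qs[ci], Qs[-ci][!is.na(Qs[-ci])], params)
    }, character(1))
    acc <- which(labels == "F")
    if (length(acc) == 0L) next
    # overlap resolution: contested pixels to the higher-Q candidate
    ord <- acc[order(ifelse(is.na(Qs[acc]), -1, Qs[acc]),
                     vapply(cands[acc], function(x) length(x$pixels), numeric(1)),
                     decreasing = TRUE)]
    claimed <- integer(0)
    for (ci in ord) {
      px <- setdiff(cands[[ci]]$pixels, claimed)
      if (length(px) < max(3L, min_candidate_area %/% 3L)) next
      claimed <- c(claimed, px)
      detected[[length(detected) + 1L]] <-
        list(pixels = px, provenance = cands[[ci]]$source, Q = Qs[ci])
    }
  }
  detected
}
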