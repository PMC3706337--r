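# Instance-level detection and segmentation metrics. A detection is a true
# positive iff its Jaccard overlap with some truth object is at least 0.5
# (such pairs are necessarily one-to-one). Contour metrics use the exact
# Euclidean distance to the matched reference contour (8-connected inner
# boundary pixels).

#' Jaccard overlap ratio of two pixel sets
#' @param detected,truth integer vectors of linear pixel indices
#' @return value in [0, 1]; 0 if either (or both) is empty
#' @export
overlap_ratio <- function(detected, truth) {
  u <- length(union(detected, truth))
  if (u == 0L) return(0)
  length(intersect(detected, truth)) / u
}

#' Match detected instances against ground truth
#'
#' @param detected,truth integer instance label matrices of the same shape
#' @return list(TP, FN, FP, matches = data.frame(detected, truth, overlap))
#' @export
match_instances <- function(detected, truth) {
  if (!all(dim(detected) == dim(truth))) stop("mask shapes differ")
  dl <- sort(unique(detected[detected > 0]))
  tl <- sort(unique(truth[truth > 0]))
  matches <- NULL
  for (d in dl) {
    dpx <- which(detected == d)
    cover <- truth[dpx]; cover <- unique(cover[cover > 0])
    for (tt in cover) {
      ov <- overlap_ratio(dpx, which(truth == tt))
      if (ov >= 0.5) matches <- rbind(matches, c(d, tt, ov))
    }
  }
  if (is.null(matches))
    matches <- matrix(numeric(0), 0, 3)
  matches <- data.frame(detected = matches[, 1], truth = matches[, 2],
                        overlap = matches[, 3])
  list(TP = nrow(matches), FN = length(tl) - nrow(matches),
       FP = length(dl) - nrow(matches), matches = matches)
}

#' Dice coefficient of two pixel sets
#' @param F,M pixel-index vectors (segmented foreground, reference mask)
#' @return value in [0, 1]; 1 when both are empty
#' @export
dice <- function(F, M) {
  if (length(F) == 0L && length(M) == 0L) return(1)
  2 * length(intersect(F, M)) / (length(F) + length(M))
}

# exact Euclidean distance of query pixels to the nearest boundary pixel of M
dist_to_contour <- function(query, M, dim) {
  bnd <- boundary_pixels(M, dim)
  qrc <- arrayInd(query, dim); brc <- arrayInd(bnd, dim)
  d2 <- outer(qrc[, 1], brc[, 1], "-")^2 + outer(qrc[, 2], brc[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}

#' Normalized sum of distances
#'
#' Distance-weighted symmetric-difference error: the sum of distances to the
#' reference contour over F-triangle-M, divided by the same sum over the
#' union. 0 for a perfect match, 1 when F is empty.
#'
#' @param F segmented pixel set
#' @param M reference pixel set (nonempty)
#' @param dim image dimensions
#' @return value >= 0
#' @export
nsd <- function(F, M, dim) {
  if (length(M) == 0L) stop("reference mask is empty")
  uni <- union(F, M)
  symdiff <- setdiff(uni, intersect(F, M))
  if (length(symdiff) == 0L) return(0)
  d <- dist_to_contour(uni, M, dim)
  sum(d[match(symdiff, uni)]) / sum(d)
}

#' One-sided Hausdorff distance of a segmented contour to the reference
#'
#' Maximum over boundary pixels of F of the Euclidean distance to the
#' boundary of M. Deliberately one-sided.
#'
#' @param F,M nonempty pixel sets
#' @param dim image dimensions
#' @return value >= 0
#' @export
hausdorff <- function(F, M, dim) {
  if (length(F) == 0L || length(M) == 0L) stop("empty input")
  max(dist_to_contour(boundary_pixels(F, dim), M, dim))
}

#' Evaluate an instance segmentation against ground truth
#'
#' Detection metrics (R, P, A) from instance matching; pooled-foreground Dice
#' as the headline region measure; NSD and Hausdorff averaged over matched
#' objects against their reference nuclei (unmatched truth objects contribute
#' a per-object Dice of 0 and are excluded from the contour metrics).
#'
#' @param detected,truth integer instance label matrices
#' @return list of class \code{rpl_metrics}: R, P, A, dice, nsd, hd,
#'   TP/FN/FP, per_object data frame
#' @export
evaluate <- function(detected, truth) {
  m <- match_instances(detected, truth)
  R <- if (m$TP + m$FN > 0) m$TP / (m$TP + m$FN) else 1
  P <- if (m$TP + m$FP > 0) m$TP / (m$TP + m$FP) else 1
  A <- if (m$TP + m$FN + m$FP > 0) m$TP / (m$TP + m$FN + m$FP) else 1
  dsc <- dice(which(detected > 0), which(truth > 0))
  per <- NULL
  dims <- dim(truth)
  for (tt in sort(unique(truth[truth > 0]))) {
    M <- which(truth == tt)
    row <- m$matches[m$matches$truth == tt, ]
    if (nrow(row) == 1L) {
      F <- which(detected == row$detected)
      per <- rbind(per, data.frame(truth = tt, dice = dice(F, M),
                                   nsd = nsd(F, M, dims),
                                   hd = hausdorff(F, M, dims)))
    } else {
      per <- rbind(per, data.frame(truth = tt, dice = 0, nsd = NA_real_,
                                   hd = NA_real_))
    }
  }
  structure(list(R = R, P = P, A = A, dice = dsc,
                 nsd = if (m$TP > 0) mean(per$nsd, na.rm = TRUE) else NA_real_,
                 hd = if (m$TP > 0) mean(per$hd, na.rm = TRUE) else NA_real_,
                 TP = m$TP, FN = m$FN, FP = m$FP, per_object = per),
            class = "rpl_metrics")
}
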