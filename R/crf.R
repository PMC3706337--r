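# Stage 3: contour refinement. Each detected region G is expanded to a band
# G_bar, a binary CRF with intensity unaries, a per-region auxiliary detection
# node and 4-neighbour spatial smoothing is built, and the exact optimum is
# found by min-cut (all pairwise weights are nonnegative, so the energy is
# submodular and the cut is globally optimal).

#' Contrast parameters of the refinement stage
#'
#' gamma is searched over \{gamma1, gamma1 + delta_gamma, ..., gamma2\};
#' defaults are the published operating point gamma1 = 0.25, gamma2 = 1,
#' delta_gamma = 0.25.
#'
#' @param gamma1,gamma2,delta_gamma the gamma search grid
#' @return list of class \code{rpl_contrast_params}
#' @export
contrast_params <- function(gamma1 = 0.25, gamma2 = 1, delta_gamma = 0.25) {
  stopifnot(gamma1 < gamma2, delta_gamma > 0)
  structure(list(gamma1 = gamma1, gamma2 = gamma2, delta_gamma = delta_gamma),
            class = "rpl_contrast_params")
}

#' Expand a detected region by half its short axis
#'
#' @param G pixel indices of the detected region
#' @param image_shape c(height, width)
#' @return list(G, G_bar, margin)
#' @export
expand_region <- function(G, image_shape) {
  margin <- if (length(G) >= 3L) {
    el <- region_ellipse(G, image_shape)
    max(round(0.5 * 2 * el$b), 2L)   # short axis = 2 * semi-minor
  } else 2L
  h <- image_shape[1]; w <- image_shape[2]
  rc <- arrayInd(G, image_shape)
  # pixels within `margin` of G: scan the padded bounding box against G's
  # boundary (exact Euclidean; regions are small so brute force is fine)
  bnd <- boundary_pixels(G, image_shape)
  brc <- arrayInd(bnd, image_shape)
  rows <- max(1L, min(rc[, 1]) - margin):min(h, max(rc[, 1]) + margin)
  cols <- max(1L, min(rc[, 2]) - margin):min(w, max(rc[, 2]) + margin)
  cand <- as.matrix(expand.grid(r = rows, c = cols))
  d2 <- outer(cand[, 1], brc[, 1], "-")^2 + outer(cand[, 2], brc[, 2], "-")^2
  near <- cand[apply(d2, 1, min) <= margin^2, , drop = FALSE]
  G_bar <- sort(union(G, (near[, 2] - 1L) * h + near[, 1]))
  list(G = G, G_bar = G_bar, margin = margin)
}

# 8-connected inner boundary: set pixels with a 4-neighbour outside the set
boundary_pixels <- function(pixels, dim) {
  h <- dim[1]
  inset <- logical(prod(dim)); inset[pixels] <- TRUE
  rc <- arrayInd(pixels, dim)
  on_border <- rc[, 1] == 1L | rc[, 1] == dim[1] | rc[, 2] == 1L | rc[, 2] == dim[2]
  nb <- cbind(pixels - 1L, pixels + 1L, pixels - h, pixels + h)
  nb[nb < 1L | nb > prod(dim)] <- NA
  outside <- !matrix(inset[nb], ncol = 4L)
  outside[is.na(outside)] <- TRUE
  pixels[on_border | rowSums(outside, na.rm = TRUE) > 0]
}

#' Regional contrast threshold lambda_G
#'
#' f_i = I_i / I_G over G; lambda_G = f_G - gamma_G (f_G - min f_i), where
#' gamma_G is the smallest grid value for which at least one pixel of G has
#' f_i > lambda_G (so the intensity term alone does not background-label the
#' entire region). Falls back to gamma2 if no grid value qualifies.
#'
#' @param G pixel indices
#' @param image intensity matrix
#' @param params \code{contrast_params()}
#' @return list(lambda_G, gamma_G, I_G, fell_back)
#' @export
compute_lambda <- function(G, image, params = contrast_params()) {
  I_G <- mean(image[G])
  f <- image[G] / I_G
  f_mean <- mean(f); f_min <- min(f)
  gammas <- seq(params$gamma1, params$gamma2, by = params$delta_gamma)
  fell_back <- TRUE
  gamma_G <- params$gamma2
  for (g in gammas) {
    lam <- f_mean - g * (f_mean - f_min)
    if (any(f > lam)) { gamma_G <- g; fell_back <- FALSE; break }
  }
  lambda_G <- f_mean - gamma_G * (f_mean - f_min)
  list(lambda_G = lambda_G, gamma_G = gamma_G, I_G = I_G,
       fell_back = fell_back)
}

#' Sigmoid intensity unary costs
#'
#' pr(F) = 1 / (1 + exp(-2 (f_i - lambda_G))); costs are the complementary
#' probabilities, so cost_F + cost_B = 1.
#'
#' @param f_i contrast feature I_i / I_G
#' @param lambda_G regional threshold
#' @return list(cost_F, cost_B), vectorized over \code{f_i}
#' @export
intensity_term <- function(f_i, lambda_G) {
  pr <- 1 / (1 + exp(-2 * (f_i - lambda_G)))
  list(cost_F = 1 - pr, cost_B = pr)
}

#' Detection edge weight to the auxiliary node
#'
#' 1 for pixels brighter than the region mean, otherwise a Gaussian falloff in
#' the squared intensity distance normalized by its population mean.
#'
#' @param I_i pixel intensity (vectorized)
#' @param I_G mean intensity of G
#' @param mean_sq_dist mean of ||I_i - I_G||^2 over the relevant population
#' @return weights in (0, 1]
#' @export
detection_weight <- function(I_i, I_G, mean_sq_dist) {
  ifelse(I_i > I_G, 1, exp(-(I_i - I_G)^2 / (2 * max(mean_sq_dist, 1e-12))))
}

#' Spatial edge weight between neighbouring pixels
#'
#' Same contrast form as the detection weight, normalized by the mean squared
#' intensity difference over neighbouring pairs; maximal (1) for equal
#' intensities, so similar pixels are penalized most for disagreeing labels.
#'
#' @param I_i,I_ip intensities of the two neighbours (vectorized)
#' @param mean_sq_dist_pairs mean of ||I_i - I_i'||^2 over neighbour pairs
#' @return weights in (0, 1]
#' @export
spatial_weight <- function(I_i, I_ip, mean_sq_dist_pairs) {
  ifelse(I_i > I_ip, 1,
         exp(-(I_i - I_ip)^2 / (2 * max(mean_sq_dist_pairs, 1e-12))))
}

# Build the CRF of one expanded region as explicit cost tables. Exported for
# the enumeration oracle in the tests.
build_crf <- function(er, image, params = contrast_params()) {
  lam <- compute_lambda(er$G, image, params)
  I <- as.numeric(image[er$G_bar])
  f <- I / lam$I_G
  un <- intensity_term(f, lam$lambda_G)
  # detection weights: normalizer over G_bar pixels not brighter than I_G
  low <- I <= lam$I_G
  msd <- if (any(low)) mean((I[low] - lam$I_G)^2) else 1
  phi <- detection_weight(I, lam$I_G, msd)
  # 4-neighbour pairs within G_bar
  h <- nrow(image)
  pos <- match(er$G_bar, er$G_bar)
  idx <- er$G_bar
  lut <- integer(length(image)); lut[idx] <- seq_along(idx)
  pairs <- NULL
  for (off in c(1L, h)) {   # down and right neighbours
    a <- idx; b <- idx + off
    ok <- b >= 1L & b <= length(image) & lut[pmax(b, 1L)] > 0
    if (off == 1L) {  # exclude wraps across column ends
      rc <- arrayInd(idx, dim(image))
      ok <- ok & rc[, 1] < h
    }
    pairs <- rbind(pairs, cbind(lut[a[ok]], lut[b[ok]]))
  }
  dI2 <- (I[pairs[, 1]] - I[pairs[, 2]])^2
  msdp <- if (nrow(pairs) > 0 && mean(dI2) > 0) mean(dI2) else 1
  # canonical pair orientation (dimmer pixel first) keeps the weight symmetric
  psi <- spatial_weight(pmin(I[pairs[, 1]], I[pairs[, 2]]),
                        pmax(I[pairs[, 1]], I[pairs[, 2]]), msdp)
  list(unary_F = un$cost_F, unary_B = un$cost_B,
       aux_unary = c(F = 0, B = length(er$G_bar)),
       phi = phi, pairs = pairs, psi = psi,
       lambda_G = lam$lambda_G, gamma_G = lam$gamma_G, I_G = lam$I_G,
       pairwise_scale = 0.5)
}

# energy of a full labeling (TRUE = F) including the auxiliary node; the
# reference definition used both by inference wiring and the test oracle
crf_energy <- function(crf, labels, aux_label = TRUE) {
  e <- sum(ifelse(labels, crf$unary_F, crf$unary_B)) +
    ifelse(aux_label, crf$aux_unary["F"], crf$aux_unary["B"]) +
    crf$pairwise_scale * (sum(crf$phi[labels != aux_label]) +
                            sum(crf$psi[labels[crf$pairs[, 1]] !=
                                          labels[crf$pairs[, 2]]]))
  as.numeric(e)
}

# exact min-cut inference via igraph; returns logical labels (TRUE = F) for
# the pixels of G_bar and the auxiliary node
crf_mincut <- function(crf) {
  n <- length(crf$unary_F)
  # nodes: 1..n pixels, n+1 aux, n+2 source (F side), n+3 sink (B side)
  aux <- n + 1L; s <- n + 2L; t <- n + 3L
  sc <- crf$pairwise_scale
  ef <- rbind(cbind(s, seq_len(n), crf$unary_B),
              cbind(seq_len(n), t, crf$unary_F),
              cbind(s, aux, crf$aux_unary["B"]),
              cbind(aux, t, crf$aux_unary["F"]),
              cbind(seq_len(n), aux, sc * crf$phi),
              cbind(aux, seq_len(n), sc * crf$phi))
  if (nrow(crf$pairs) > 0) {
    ef <- rbind(ef,
                cbind(crf$pairs[, 1], crf$pairs[, 2], sc * crf$psi),
                cbind(crf$pairs[, 2], crf$pairs[, 1], sc * crf$psi))
  }
  keep <- ef[, 3] > 0
  g <- igraph::graph_from_edgelist(matrix(as.integer(ef[keep, 1:2]), ncol = 2),
                                   directed = TRUE)
  g <- igraph::add_vertices(g, max(0, (n + 3L) - igraph::vcount(g)))
  cut <- igraph::min_cut(g, source = s, target = t,
                         capacity = ef[keep, 3], value.only = FALSE)
  src_side <- as.integer(cut$partition1)
  if (!(s %in% src_side)) src_side <- as.integer(cut$partition2)
  labels <- logical(n + 1L)
  labels[src_side[src_side <= n + 1L]] <- TRUE
  list(pixel_labels = labels[seq_len(n)], aux_label = labels[aux],
       value = cut$value)
}

#' Refine a detected region's contour
#'
#' Builds and exactly minimizes the regional-contrast CRF over the expanded
#' region, then returns the foreground connected components that intersect
#' the original region (so a neighbouring nucleus entering the band cannot be
#' claimed).
#'
#' @param G pixel indices of the detected region
#' @param image intensity matrix (enhanced working image)
#' @param params \code{contrast_params()}
#' @return list(pixels, gamma_G, energy)
#' @export
refine_contour <- function(G, image, params = contrast_params()) {
  stopifnot(length(G) > 0)
  er <- expand_region(G, dim(image))
  crf <- build_crf(er, image, params)
  res <- crf_mincut(crf)
  fg <- er$G_bar[res$pixel_labels]
  if (length(fg) == 0L)
    return(list(pixels = integer(0), gamma_G = crf$gamma_G, energy = res$value))
  mask <- matrix(FALSE, nrow(image), ncol(image))
  mask[fg] <- TRUE
  lab <- cpp_label_components(mask, 4L)
  keep_labs <- unique(lab[G])
  keep_labs <- keep_labs[keep_labs > 0]
  pixels <- which(lab %in% keep_labs)
  list(pixels = sort(pixels), gamma_G = crf$gamma_G,
       energy = crf_energy(crf, res$pixel_labels, res$aux_label))
}

#' Remove small isolated segments
#'
#' Deletes connected components smaller than one tenth of the average
#' component area of the mask.
#'
#' @param mask logical matrix
#' @return cleaned logical matrix
#' @export
postprocess_segments <- function(mask) {
  lab <- cpp_label_components(mask, 4L)
  if (max(lab) == 0L) return(mask)
  areas <- tabulate(lab[lab > 0], max(lab))
  small <- which(areas < mean(areas) / 10)
  if (length(small)) mask[lab %in% small] <- FALSE
  mask
}

#' Assemble refined regions into an instance label mask
#'
#' Regions are laid down in deterministic top-left centroid order. Contested
#' pixels (two refined regions overlap, which happens when touching nuclei
#' share one expanded band) are resolved by the originating detections when
#' \code{seeds} is given: a pixel goes to the region whose seed contains it,
#' else to the region with the nearest seed, with the higher mean-intensity
#' region breaking ties. Without seeds, the brighter region simply wins. The
#' small-segment post-processing rule is then applied to the pooled
#' foreground.
#'
#' @param regions list of refined pixel-index vectors
#' @param image intensity matrix (for the contrast tie-break)
#' @param image_shape c(height, width)
#' @param seeds optional list of the unrefined detections, parallel to
#'   \code{regions}
#' @return integer instance label matrix
#' @export
assemble_result <- function(regions, image, image_shape = dim(image),
                            seeds = NULL) {
  out <- matrix(0L, image_shape[1], image_shape[2])
  keep <- vapply(regions, function(p) length(p) > 0, logical(1))
  regions <- regions[keep]
  if (!is.null(seeds)) seeds <- seeds[keep]
  if (length(regions) == 0L) return(out)
  ctr <- t(vapply(regions, function(p) region_centroid(p, image_shape),
                  numeric(2)))
  ord <- order(ctr[, 2], ctr[, 1])
  contrast <- vapply(regions, function(p) mean(image[p]), numeric(1))
  score <- matrix(-Inf, image_shape[1], image_shape[2])
  lab <- 0L
  eps <- 1e-9
  for (i in ord) {
    lab <- lab + 1L
    px <- regions[[i]]
    if (is.null(seeds)) {
      sc <- rep(contrast[i], length(px))
    } else {
      # large score inside own seed; else decays with distance to the seed
      src <- arrayInd(seeds[[i]], image_shape)
      prc <- arrayInd(px, image_shape)
      d2 <- outer(prc[, 1], src[, 1], "-")^2 + outer(prc[, 2], src[, 2], "-")^2
      sc <- -sqrt(apply(d2, 1, min)) + eps * contrast[i]
    }
    win <- sc > score[px]
    out[px[win]] <- lab
    score[px[win]] <- sc[win]
  }
  fg <- postprocess_segments(out > 0)
  out[!fg] <- 0L
  # drop emptied labels, relabel densely
  labs <- sort(unique(out[out > 0]))
  out[] <- match(out, labs, nomatch = 0L)
  out
}
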