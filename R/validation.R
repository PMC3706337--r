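# Candidate validation by distance profiles. For each reference region k we
# hold the appearance distances to all other references; a candidate's
# distance to k is scored against that empirical distribution with a Gaussian
# KDE, normalized by the peak density at the profile's own sample points, and
# the per-reference probabilities are averaged.

#' Silverman normal-reference bandwidth
#'
#' h = 1.06 sigma n^(-1/5) on the profile distances, floored at
#' 1e-6 (1 + mean distance) so an all-equal (degenerate) profile still yields
#' a usable kernel.
#'
#' @param distances numeric vector of profile distances
#' @return positive bandwidth
#' @export
silverman_bandwidth <- function(distances) {
  n <- length(distances)
  s <- if (n > 1L) stats::sd(distances) else 0
  max(1.06 * s * n^(-1 / 5), 1e-6 * (1 + mean(distances)))
}

#' Build a distance profile for one reference
#'
#' @param reference_id index of the reference
#' @param distances distances from this reference to all other references
#' @return list of class \code{rpl_profile} with the Silverman bandwidth
#' @export
distance_profile <- function(reference_id, distances) {
  stopifnot(length(distances) >= 1L, all(distances >= 0))
  structure(list(reference_id = reference_id, distances = distances,
                 bandwidth = silverman_bandwidth(distances)),
            class = "rpl_profile")
}

kde_density <- function(x, samples, h) {
  vapply(x, function(xi) mean(stats::dnorm((xi - samples) / h)) / h, numeric(1))
}

#' Probability of a candidate distance under a reference profile
#'
#' The Gaussian KDE of the profile distances is evaluated at
#' \code{delta_kx} and normalized by the maximum fitted density over the
#' profile's own sample points, clipped to [0, 1].
#'
#' @param delta_kx appearance distance from the candidate to the reference
#' @param profile \code{rpl_profile}
#' @return probability in [0, 1]
#' @export
reference_probability <- function(delta_kx, profile) {
  h <- profile$bandwidth
  p0 <- kde_density(delta_kx, profile$distances, h)
  pmax_ref <- max(kde_density(profile$distances, profile$distances, h))
  min(max(p0 / pmax_ref, 0), 1)
}

#' Validation thresholds and patch size
#'
#' alpha1 scales the best co-candidate probability within the same cluster;
#' alpha2 is the absolute threshold used when a candidate is alone in its
#' cluster. Defaults are the published operating point alpha1 = 0.6,
#' alpha2 = 0.4, patch 8 px.
#'
#' @param alpha1,alpha2 thresholds in (0, 1)
#' @param patch_size appearance patch edge in px
#' @return list of class \code{rpl_validation_params}
#' @export
validation_params <- function(alpha1 = 0.6, alpha2 = 0.4, patch_size = 8L) {
  structure(list(alpha1 = alpha1, alpha2 = alpha2,
                 patch_size = as.integer(patch_size)),
            class = "rpl_validation_params")
}

# Q(G_x, F): average reference probability over K references.
# references: list of rpl_appearance; candidate_hist: rpl_appearance.
candidate_probability <- function(candidate_hist, reference_hists) {
  K <- length(reference_hists)
  stopifnot(K >= 2L)
  dmat <- matrix(0, K, K)
  for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
    dmat[i, j] <- dmat[j, i] <-
      diffusion_distance(reference_hists[[i]], reference_hists[[j]])
  }
  probs <- vapply(seq_len(K), function(k) {
    prof <- distance_profile(k, dmat[k, -k])
    dkx <- diffusion_distance(reference_hists[[k]], candidate_hist)
    reference_probability(dkx, prof)
  }, numeric(1))
  mean(probs)
}

#' Validate a candidate region
#'
#' Applies the thresholding rule as a conjunction: a candidate is foreground
#' when its probability Q exceeds alpha1 times the best Q among the other
#' candidates of the same cluster *and* exceeds the absolute floor alpha2;
#' with no co-candidates only the floor applies. Without the floor, a cluster
#' containing nothing but background candidates validates its own junk: each
#' one trivially beats alpha1 times the other's (equally low) probability.
#'
#' @param Q candidate probability in [0, 1]
#' @param co_Q probabilities of the other candidates in the same cluster
#'   (may be empty)
#' @param params \code{validation_params()}
#' @return label, "F" or "B"
#' @export
validate_candidate <- function(Q, co_Q, params = validation_params()) {
  rel_ok <- length(co_Q) == 0L || Q > params$alpha1 * max(co_Q)
  if (rel_ok && Q > params$alpha2) "F" else "B"
}
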