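---
title: "Progressive localization of cell nuclei: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Progressive localization of cell nuclei: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Fluorescence micrographs of nuclear markers are inhomogeneous twice over:
pixels within one nucleus vary, different nuclei in the same field differ
substantially in brightness, and the background — nominally dark — contains
elevated areas and occasional very bright artifacts that mimic nuclei. A
global threshold or a single trained classifier therefore either loses dim
nuclei or admits bright background. `rplseg` localizes nuclei progressively,
letting each stage correct the previous one with increasingly local,
data-adaptive information:

1. **Initial segmentation** — salient interest regions from maximally stable
   extremal regions (MSER, bright-on-dark), alternated with an image-adaptive
   contrast enhancement until the region count stabilizes.
2. **Decluster processing** — two-level nested regions ("clusters") are
   decomposed into candidate nuclei (enclosed upper regions plus connected
   components of pixels classified foreground on dense SIFT descriptors);
   each candidate is validated against reference nuclei from the same image
   through kernel-density distance profiles of bag-of-features appearance
   histograms.
3. **Contour refinement** — each detected region is re-labelled inside an
   expanded band by exactly minimizing a binary conditional random field
   (CRF) with regional-contrast unaries, a per-region auxiliary detection
   node, and 4-neighbour smoothing; all pairwise weights are nonnegative, so
   a single min-cut yields the global optimum.

# Models and parameters

## Stage 1: contrast-enhanced salient region detection

MSER is run on upper level sets with stability measured as the relative area
change across `delta = 5` gray levels. The stability threshold
(*MaxVariation*) is chosen at run time: starting at `v1 = 0.7` it is lowered
in steps of `delta_v = 0.1` until either `v2 = 0.4` is reached or a two-level
nest appears. Detected-region intensities then drive the enhancement

\[ I \leftarrow I \cdot \frac{C}{0.5(\{R\}_0 + \{R\}_2)} , \]

with \(\{R\}_0\) and \(\{R\}_2\) the minimum and mean intensity over the
pooled region pixels and `C = 128`; the result is clipped to [0, 255].
Detection and enhancement alternate until the number of regions stops
changing (iteration cap 10). Enhancement compounds on the working image.
Two refinements of the stopping rule proved necessary and are this package's
own choices: the loop also stops — reverting to the previous iterate — when
the region count *decreases*, because under compounding enhancement a
shrinking count signals saturation (bright regions merging, background noise
being amplified) rather than newly revealed nuclei; and the final enhanced
image returned to later stages is the one the reported hierarchy was
actually detected on.

The component tree can nest arbitrarily deep; it is collapsed to depth two.
Per selected root, the root is the lower region, and the uppers are obtained
by recursively descending through any selected node that branches into two
or more disjoint selected descendants (a clump of touching nuclei), while a
node whose selected refinement is a single chain (a nucleus over its bright
core) is kept whole. Fixed MSER parameters: `min_area = 30` px,
`max_area = 25%` of the image, branch diversity 0.2 — defaults chosen to
reject speckle and whole-image regions at the 256 px fixture scale, all
configurable.

Under-segmented nested pairs (one lower, exactly one upper) are merged into
a single region when a linear SVM accepts the shape/size features of the
combined region (area, axis ratio, solidity, best-fit-ellipse residual).
Lowers with two or more uppers are genuine clusters and are never merged.

## Stage 2: candidate identification and validation

Every upper region enclosed in a cluster is a candidate; additionally every
cluster pixel is classified foreground/background by a polynomial-kernel SVM
(degree 3, C = 1, `gamma = 1/128`, solved exactly as the dual QP) on upright
dense SIFT descriptors (4×4 cells of 4 px, 8 orientation bins, standard
0.2-clipped L2 normalization). Foreground components not touching an upper
become candidates and are completed to their minimum-volume enclosing
ellipse (Khachiyan iteration), intersected with the cluster.

A candidate's appearance is a pair of histograms over the enhanced image:
64 intensity bins over [0, 255] and 12 bag-of-features word bins, where each
non-overlapping 8×8 patch is described by min/max/mean/sd and a 64-bin
histogram of absolute pairwise pixel differences, then assigned the nearest
of 12 k-means words in per-dimension standardized space. Both histogram
blocks are *percentages* — intensity counts per region pixel, word counts
per region patch — so the two blocks carry comparable mass; normalizing the
word counts by the pixel count (a literal alternative reading) would scale
the word block down by the patch area and silence the texture channel
entirely. Distances are diffusion distances (L1 norms summed over a
smoothed/downsampled pyramid), computed per block and added.

Validation scores candidate \(x\) against reference regions (the single- and
upper-level detections of the same image): for each reference \(k\), the
distances from \(k\) to all other references form a profile whose Gaussian
KDE (Silverman bandwidth \(1.06\,\hat\sigma\,(K{-}1)^{-1/5}\), floored at
\(10^{-6}(1+\bar\delta)\)) is evaluated at \(\delta_{k,x}\) and normalized
by the density maximum over the profile's own points; the probabilities are
averaged into \(Q(G_x, F)\). A candidate with co-candidates in its cluster
is accepted when \(Q > \alpha_1 \max_{x'} Q(G_{x'})\) with
\(\alpha_1 = 0.6\); an isolated candidate when \(Q > \alpha_2 = 0.4\).

References are restricted to the candidate's image quadrant. The package
falls back to the image-wide pool when the quadrant holds fewer than **six**
references (not two): with one to four profile distances the
normal-reference bandwidth and the max-normalization are degenerate, and one
false-positive reference in a thin quadrant will validate other false
positives — we observed exactly this failure on synthetic images with two
bright artifacts in one quadrant.

## Stage 3: CRF contour refinement

Each detection \(G\) is expanded by half its short axis into \(\bar G\). With
\(f_i = I_i / I_G\), the foreground probability is the sigmoid
\(\mathrm{pr}(F) = (1 + e^{-2(f_i - \lambda_G)})^{-1}\), where
\(\lambda_G = f_G - \gamma_G (f_G - \min f_i)\) and \(\gamma_G\) is the
smallest value on the grid \(0.25, 0.5, 0.75, 1\) for which at least one
pixel of \(G\) exceeds \(\lambda_G\) (evaluated on the intensity term alone,
before any graph construction; \(\gamma_G = 1\) is the logged fallback for
degenerate constant regions). Unary costs are the complementary
probabilities. An auxiliary node with costs \((0, N_{\bar G})\) is connected
to every pixel with weight 1 for pixels brighter than \(I_G\) and
\(\exp(-\|I_i - I_G\|^2 / 2\langle\|I_i - I_G\|^2\rangle)\) otherwise, the
average taken over \(\bar G\) pixels not brighter than \(I_G\); 4-neighbour
spatial edges use the same form normalized by the neighbour-pair average.
Because the contrast function's "brighter" branch depends on which pixel of
an unordered pair is named first, spatial pairs are oriented dimmer-first,
which makes the weight symmetric while preserving the value 1 at equal
intensities. Pairwise sums enter the energy scaled by 0.5. The optimum is
found by min-cut (igraph max-flow); foreground components intersecting the
original \(G\) are returned.

At assembly, overlapping refined regions (touching nuclei refined in
overlapping bands) are resolved per pixel by originating-seed membership and
otherwise by nearest seed, with mean intensity breaking ties. Assigning the
whole contested area to the brighter region — the natural one-line rule —
deletes the dimmer of two touching nuclei entirely, which is why the seeded
rule is the default inside the pipeline; `assemble_result()` without seeds
still implements the brighter-wins rule. Finally, connected components
smaller than one tenth of the average component area are removed.

# The synthetic world

`fixture_spec()` emulates the artifacts above: elliptical nuclei (semi-axes
6–12 px, 20 per 256×256 frame) with integer mean intensities drawn from
130–200, a 30% radial falloff and correlated multiplicative chromatin-like
speckle (sd 0.12, disabled when the gradient is 0 so the exact-contrast
invariant holds); a base-30 background with smooth low bumps; three very
bright (210–250), texture-flat distractor blobs sitting on broad flat
elevated plateaus; 20% of nuclei placed near-tangent to a neighbour; and
additive Gaussian noise (sd 5), clipped and rounded to 8 bits.

Why these choices: the plateaus make the blobs *nested* interest regions, so
they must pass stage-2 validation rather than being accepted as single-level
detections — this is the configuration in which the method's filtering claim
is testable at all. Near-tangent (rather than overlapping) touching nuclei
preserve an intensity saddle, the regime in which component-tree nesting can
decompose a clump; heavily overlapping same-intensity nuclei form a single
extremal region that nothing in this method (which has no watershed-style
splitter) can separate — that is a real limitation, shared with the
published approach. Moderate brightness variation matters for the same
reason: validation presumes references are mutually more similar than they
are to artifacts, and a world where nuclei legitimately span 2× in
brightness widens every distance profile until bright artifacts are no
longer outliers. A green end-to-end test therefore establishes that the
pipeline recovers nuclei under moderate inhomogeneity with sparse bright
distractors; it does not establish performance under extreme dim-nucleus
regimes, dense clumping, uneven illumination gradients at nucleus scale, or
real microscope optics (no PSF, no Poisson statistics — deliberately out of
scope for the generator).

# Numerical choices and degenerate inputs

* The SVM dual is solved with `quadprog` after adding a `1e-8` ridge; this
  is deterministic and exact but cubic in the training size, so pixel
  sampling is capped at 300 px per training image (class-balanced, topped up
  from the larger class) — ample for the clean-fixture accuracy gates.
* KDE bandwidth flooring (`1e-6 (1 + mean distance)`) keeps all-equal
  profiles usable; the probability is clipped to [0, 1] since the candidate
  density can exceed the sample-point maximum.
* Degenerate MVEE inputs (fewer than 3 non-collinear pixels) leave the
  candidate unchanged, flagged `ellipse_completed = FALSE`.
* `enhance_contrast` on an empty hierarchy is an error (the normalizer is
  undefined); `localize` maps a structureless image to an empty mask
  instead of failing.
* Empty-set conventions: Jaccard of two empty sets is 0, Dice is 1; NSD
  requires a nonempty reference; Hausdorff requires both sets nonempty.
* Instance masks use deterministic top-left centroid label order, so runs
  are bit-identical under a fixed seed.

# Evaluation conventions

Detection counts follow the Jaccard ≥ 0.5 one-to-one matching rule
(R = TP/(TP+FN), P = TP/(TP+FP), A = TP/(TP+FN+FP)). The headline Dice is
pooled over the image foreground; NSD and the one-sided Hausdorff distance
are computed per matched object against its reference nucleus (exact
Euclidean distances to the 8-connected inner boundary) and averaged over
matches; unmatched truth objects contribute a per-object Dice of 0 and are
excluded from contour metrics. The aggregation across objects and images is
this package's convention — the corresponding published tables print single
per-dataset values without stating theirs.

# Known limitations

* Clumps of touching nuclei with near-identical brightness and no saddle
  merge irrecoverably at stage 1.
* Validation degrades when references are scarce (sparse quadrants, fewer
  than ~6 usable references) or heavily contaminated; the image-wide
  fallback mitigates but cannot fix an image whose reference pool is mostly
  artifacts.
* Co-located false positives inside one cluster can validate each other
  through the relative threshold \(\alpha_1\); the absolute gate
  \(\alpha_2\) only applies to isolated candidates.
* The grayscale pipeline rejects RGB input; colour preprocessing is the
  user's responsibility.
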