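# rplseg — region-based progressive localization of cell nuclei

`rplseg` detects and segments cell nuclei in single-channel fluorescence
micrographs whose intensities are strongly inhomogeneous — dim nuclei next to
bright ones, elevated background areas, and bright artifacts that mimic
nuclei. It is aimed at bio-image analysts who need instance masks (one label
per nucleus) from nuclear-marker images without per-image parameter tuning.

## Method

Localization proceeds in three data-adaptive stages:

1. **Salient region detection.** Maximally stable extremal regions (MSER,
   bright-on-dark) with a run-time stability schedule (MaxVariation from
   v₁ = 0.7 down to v₂ = 0.4 in steps of 0.1), alternating with the contrast
   enhancement I ← I · C / (0.5({R}₀ + {R}₂)) — {R}₀, {R}₂ the minimum and
   mean intensity of the detected regions, C = 128 — until the region count
   stabilizes. Nested pairs that form one elliptical nucleus are merged by a
   linear SVM on shape/size features.
2. **Decluster processing.** Two-level nests (clusters) are decomposed:
   enclosed upper regions and connected components of SVM-classified
   foreground pixels (dense SIFT descriptors, polynomial kernel) become
   candidates, completed to their minimum-volume enclosing ellipse. Each
   candidate x is validated against reference regions k of the same image:
   with δ the diffusion distance between bag-of-features appearance
   histograms (64 intensity bins + 12 texture words),

   p̂₀(δₖₓ) = (K−1)⁻¹ Σₖ′ h⁻¹ K((δₖₓ − δₖₖ′)/h),  p̂ = p̂₀ / maxₖ′ p̂₀(δₖₖ′),

   and Q(Gₓ, F) = K⁻¹ Σₖ p̂(δₖₓ). A candidate is kept when Q > α₁·max Q of
   its cluster co-candidates and Q > α₂ (α₁ = 0.6, α₂ = 0.4).
3. **Contour refinement.** Each detection G is re-labelled inside a band Ḡ
   (G dilated by half its short axis) by exactly minimizing

   E(L|Ḡ) = Σᵢ η(lᵢ) + η(l_G) + 0.5 { Σᵢ φ(lᵢ, l_G) + Σᵢᵢ′ ϕ(lᵢ, lᵢ′) }

   with sigmoid intensity unaries around the regional threshold
   λ_G = f_G − γ_G(f_G − min fᵢ), an auxiliary detection node, and
   4-neighbour contrast smoothing; all pairwise weights are nonnegative, so
   one min-cut gives the global optimum.

Evaluation follows the standard instance protocol: a detection is a true
positive iff its Jaccard overlap with a ground-truth nucleus is ≥ 0.5;
reported measures are recall/precision/accuracy, pooled Dice, the normalized
sum of distances (NSD) and the one-sided Hausdorff distance.

## Worked example

```r
library(rplseg)

# synthetic world: 20 nuclei, bright distractors, touching pairs, noise
train  <- generate_suite(4, fixture_spec(), seed = 99)
models <- train_models(lapply(train, `[[`, "image"),
                       lapply(train, `[[`, "truth"), seed = 1)

fx  <- generate_fixture(fixture_spec(seed = 7))
res <- localize(fx$image, models, pipeline_config())
met <- evaluate(res$mask, fx$truth)
cat("detections:", max(res$mask), "\n")
cat(sprintf("R = %.3f  P = %.3f  A = %.3f\n", met$R, met$P, met$A))
cat(sprintf("Dice = %.3f  NSD = %.4f  HD = %.2f px\n", met$dice, met$nsd, met$hd))
```

Output:

```
detections: 21
R = 1.000  P = 0.952  A = 0.952
Dice = 0.939  NSD = 0.0004  HD = 0.15 px
```

All 20 nuclei are recovered (R = 1); one bright distractor survives
validation (P = 0.952). The pooled Dice of 0.939 and the sub-pixel mean
Hausdorff distance say the contours of matched nuclei are essentially exact;
NSD near 0 means the few mislabelled pixels sit on the contour.

## Command line

```sh
rpl fixtures --out fx/ --n 5 --seed 1          # write a synthetic suite
rpl train    --images fx/ --out models.rds     # train SVMs + codebook
rpl localize --images fx/ --models models.rds --out masks/
rpl eval     --pred masks/ --truth fx/ --out report.json
rpl ablate   --out ablation.json --n 5         # per-stage S-1/S-2/S-3 metrics
```

Images are 8-bit grayscale PNG/TIFF; instance masks are written as 16-bit
TIFF; reports as JSON/CSV.

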