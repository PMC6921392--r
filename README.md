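# xraseg

Vessel enhancement and segmentation for coronary X-ray angiographic (XRA)
image sequences, for researchers in cardiovascular image analysis who need
an automatic, *online* (frame-at-a-time) layer-separation pipeline and a
fully synthetic, ground-truthed phantom to validate it on.

An angiogram frame superimposes contrast-filled arteries on ribs, vertebrae,
diaphragm, lung tissue and the catheter, each moving differently. `xraseg`
separates and segments the vascular layer in four stages:

1. **Respiratory removal** — black top-hat with a circular structuring
   element of diameter `d = 8.5/(2p)` pixels (`p` = pixel spacing in mm):
   `DI = close(I) − I` cancels large smooth structures and returns thin dark
   vessels as a positive signal.
2. **Inter-frame constrained decomposition** — streaming low-rank + sparse
   separation `DI_i ≈ Lr Ce_i + E_i` with an evolving subspace basis
   `Lr ∈ R^(D×r)`: per frame, alternate a ridge solve for the coefficients
   `Ce` and soft thresholding for the sparse vascular part `E`
   (objective `½‖DI_i − Lr Ce − E‖² + (λ₁/2)‖Ce‖² + λ₂‖E‖₁`),
   then update the basis from accumulated sufficient statistics. One pass,
   no revisiting — new frames are processed online.
3. **Intra-frame constrained smoothing** — the same objective per frame with
   an all-ones basis, which reduces the low-rank term to a constant offset
   and leaves the final enhanced vascular sequence `V` on a clean
   background.
4. **Multi-feature segmentation** — multi-scale Hessian eigenvalue analysis
   (`|λ₁| ≤ |λ₂|`; tubes have `|λ₁| ≈ 0 ≪ |λ₂|`), fusing a log-scaled
   descriptor `F₁ = ln(λ₂² + 1)` (active where `λ₂ < −√(2π)σ`) with a
   bounded ratio descriptor `F₂` built from the max-regularized eigenvalue
   `λ_r`, as `F = max_σ(α₁F₁ + α₂F₂)`; vessels are then a single threshold
   away (per-frame Otsu by default).

Defaults follow the empirical clinical settings: `r = r′ = 5`,
`λ₁ = λ₂ = λ₁′ = λ₂′ = 2.1/max(M₁, M₂)`, `d = d′ = 8.5/(2p)`, `p = 0.3`,
`α₁ = α₂ = 0.5`. Evaluation ships with the field-standard metrics:
contrast-to-noise ratio `CNR = |μ_F − μ_B|/σ_B` against the global
background and a 7-px local ring, and pixel precision/sensitivity/F1.

Clinical XRA data is not redistributable, so the package includes a
synthetic phantom generator (`generate_xra_sequence()`) producing sequences
with a known decomposition — static anatomy, translating respiratory layer,
elastically moving vessel tree with contrast inflow, catheter, noise — plus
exact per-frame vessel masks. See the methods vignette
(`vignettes/vessel-enhancement-methods.Rmd`) for the model, parameter
rationale and known limitations.

## Worked example

```r
library(xraseg)

phantom <- generate_xra_sequence(phantom_config())
phantom$sequence
#> xra_sequence: 128 x 128 pixels, 30 frame(s), spacing 0.3 mm
#>   intensity range [0.2278, 0.919]

result <- run_pipeline(phantom$sequence, pipeline_config(),
                       truth_masks = phantom$truth$vessel_mask,
                       eval_frames = 21:30)   # fully opacified frames
aggregate_metrics(result$metrics)
#>        metric     mean       sd
#> 1  cnr_global   53.800 20.11359
#> 2   cnr_local  247.458 58.35643
#> 3          tp 1398.900 63.06513
#> 4          fp  232.400 29.06774
#> 5          fn   98.900  9.46866
#> 6   precision    0.858  0.01395
#> 7 sensitivity    0.934  0.00736
#> 8          f1    0.894  0.00829

original <- evaluate_sequence(normalize_sequence(phantom$sequence),
                              phantom$truth$vessel_mask, frames = 21:30)
sprintf("original CNR  global %.2f  local %.2f",
        mean(original$cnr_global), mean(original$cnr_local))
#> [1] "original CNR  global 2.63  local 2.80"
```

The enhanced vascular sequence `result$V` lifts the mean global CNR from
2.63 to 53.8 and the local (perivascular) CNR from 2.80 to 247, and the
thresholded segmentation `result$SI` overlaps the ground-truth masks at
pixel F1 ≈ 0.89: the background layers are almost entirely removed while the
vessel tree, including its thin distal branches, is retained. A low-dose
acquisition can then be simulated by subtracting the vessel estimate back
out of the original frames:

```r
lowdose <- simulate_low_dose(normalize_sequence(phantom$sequence),
                             result$V, dose_fraction = 0)
```

which removes about three quarters of the vessel-to-surround contrast
(`dose_fraction = 1` returns the original exactly).

A command-line front end with `simulate`, `enhance`, `segment`, `evaluate`
and `lowdose` subcommands is installed under `exec/xraseg`.

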