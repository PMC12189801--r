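# nucseg

Nuclei segmentation for H&E histology images in R: Macenko-style stain
separation, morphological marker extraction, connected-component analysis
with Laplacian-of-Gaussian blob detection, and geodesic active-contour
level-set refinement — plus a seeded synthetic H&E scene generator with
instance ground truth, so the whole pipeline is testable without any
external image data.

The package is aimed at computational-pathology and bio-image-analysis work
where overlapping nuclei defeat plain thresholding or an unconstrained
active contour: thresholded components are split into per-nucleus seeds by
the distance transform (and optionally LoG blobs), and a level-set front
grown from each seed is prevented from fusing with its neighbors across
weak edges.

## The model in brief

Stains mix additively in optical density: `OD = -log10(I) ≈ M c`, with `M`
the 3×2 matrix of unit hematoxylin/eosin OD color vectors and `c ≥ 0` the
stain concentrations. `M` is estimated per image from the SVD plane of the
tissue OD tuples and the robust angular extremes of their projections
(percentiles `α = 1` and `100 − α`; tissue = any channel OD above
`β = 0.15`). The hematoxylin-only rendering `10^(−M[,1] c_H)` shows nuclei
dark on a white background; Otsu thresholding, a 3×3 opening and the exact
Euclidean distance transform yield per-nucleus seeds, which a geodesic
active contour

    du/dt = g(I) (κ + v) |∇u| + ∇g · ∇u,    g(I) = 1 / (1 + |∇I₁|^p)

grows to the nucleus boundaries: `κ` is the level-set curvature, `v` a
balloon (inflation) constant, and `g` an edge-stopping factor that is small
on boundaries. Fronts from different seeds may meet but, by default, may
not merge — a sign flip that would connect two seed basins is vetoed, which
is what keeps touching nuclei separate. See the methods vignette
(`vignettes/nucseg-methods.Rmd`) for the full account, including every
numerical default and its rationale.

## Worked example

```r
library(nucseg)

# a synthetic H&E scene with known instance labels:
# 10 elliptical nuclei, 30% placed overlapping, intensity noise sd 0.01
sc <- generate_scene(n_nuclei = 10, overlap_fraction = 0.3,
                     noise_sd = 0.01, seed = 42)
sc
#> synthetic H&E scene: 160 x 160, 10 nuclei, seed 42

res <- run_pipeline(sc$image, truth = sc$truth)
res
#> pipeline result: 9 segmented object(s)
#>   Dice 0.968, IoU 0.939, count error 1, matched Dice 0.937
#>   stages:
#>     normalize    0.04s  max H conc 1.15
#>     enhance      0.14s  3382 fg px
#>     markers      0.12s  392 sure-fg px
#>     components   0.23s  6 components, 9 seeds
#>     gac          6.04s  9 objects after 500 iters

round(res$separation$stains, 3)
#>   hematoxylin eosin
#> r       0.652 0.025
#> g       0.700 0.995
#> b       0.290 0.095
```

Reading the output: the thresholded mask holds 3,382 foreground pixels in
6 connected components — several nuclei touch — from which 9 seeds are
found; the contour evolution returns 9 objects, so one deeply-overlapped
nucleus was not separated (count error 1 against the 10 ground-truth
nuclei). Pooled foreground Dice against truth is 0.968 and the mean
per-object Dice of greedily matched instances is 0.937. The estimated stain
matrix is within a degree of the canonical H&E vectors used by the
renderer ((0.65, 0.70, 0.29) and (0.07, 0.99, 0.11), normalized).

`write_pipeline_result(res, "out/")` persists the normalized renderings,
mask, distance field, label map (16-bit TIFF), contour table (CSV) and
stage log. A thin command-line front end with subcommands `normalize`,
`enhance`, `segment`, `synth`, `run`, `augment` and `evaluate` is installed
at `system.file("cli/nucseg", package = "nucseg")`.

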