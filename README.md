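# cryptArch

Quantitative grading of crypt architectural distortion in colonic biopsies.

Chronic inflammatory bowel disease (IBD) distorts the architecture of the
colonic mucosa: crypt outlines become irregular, crypt density falls,
inter-crypt spacing grows uneven, and the crypt bases lift away from the
muscularis mucosa. Pathologists grade this as Normal or IBD grade I–III with
substantial inter-observer variability. `cryptArch` is an R implementation
of an automated grading pipeline for single well-oriented microscopy
fields, aimed at digital-pathology researchers and method developers:

* **Segmentation** — median filtering and background subtraction, then a
  greedy active contour ("snake") minimizing
  `E = Σ α·E_cont + β·E_curv + γ·E_img + κ·E_con`
  locates closed crypt boundaries; the muscularis mucosa is the upper edge
  of the dark band along the image bottom.
* **Shape features** — each boundary is parameterized in polar form r(θ)
  about its centroid; the DFT `z_u = (1/K) Σ_k r_k e^{-2πiuk/K}` is
  normalized for position (nullify z₀), size (divide by |z₁|) and rotation
  (magnitudes only), keeping `|z₁|…|z₉|`, averaged over the crypts of the
  image.
* **Density feature** — crypt centroids from mask moments
  (x̄ = M₁₀/M₀₀, ȳ = M₀₁/M₀₀); mean edge length of the Euclidean minimum
  spanning tree over the centroids (Kruskal), normalized by the maximum
  tree edge.
* **Basal-gap feature** — least-squares lines `y = ax + b` through the
  muscularis polyline and through the base points of the first crypt row;
  normalized mean perpendicular norm between them.
* **Classification** — the 11 features feed a probabilistic neural network
  (Parzen-window Bayes rule): assign V to class C_i iff
  `p_i L_i f_i(V) > p_j L_j f_j(V)` with
  `f_i(V) = (1/n_i) Σ_w exp(-||V-w||²/2σ²)` over stored training patterns.

Because no clinical images are distributed, the package includes a
first-class synthetic-field generator (`generateBiopsyImage`,
`generateCohort`) with exact ground truth — grade-parameterized crypt
distortion, density, spacing irregularity and basal gap — so the whole
chain is testable end to end. See the vignette
(`vignettes/crypt-architecture-grading.Rmd`) for the model, parameter
choices and limitations.

## Worked example

```r
library(cryptArch)

# one synthetic grade-II field with its paired background image
sim <- generateBiopsyImage(gradeParams("II"), seed = 7)
ex  <- extractFeatures(sim$image, sim$background)
round(ex$features, 4)
#>           fd1           fd2           fd3           fd4           fd5
#>        1.0000        6.8623        8.4804        7.2614        7.7421
#>           fd6           fd7           fd8           fd9   mst_spacing
#>        6.6410        0.5832        0.4441        0.6965        0.7679
#> musc_distance
#>        0.0413
```

The leading Fourier magnitudes summarize outline irregularity (grade II
values sit well above a normal field's ≈1 because the size normalizer |z₁|
is small for regular crypts), `mst_spacing` ≈ 0.77 reflects uneven
inter-crypt spacing (1.0 would be perfectly even), and `musc_distance`
≈ 0.041 is the crypt-base–to–muscularis gap as a fraction of the image
diagonal (a normal field sits near 0.015, severe disease near 0.06).
Train and apply the classifier:

```r
coh <- generateCohort(30, seed = 1201)           # 120 fields, 30 per grade
ft  <- cohortFeatures(coh)
sp  <- splitDataset(ft$grade, 2/3, seed = 1201)  # stratified 80/40
X   <- as.matrix(ft[, c(paste0("fd", 1:9), "mst_spacing", "musc_distance")])
m   <- trainPNN(X[sp$train, ], ft$grade[sp$train], sigma = 0.1)
pred <- apply(X[sp$test, ], 1, function(q) classifyPNN(m, q)$grade)
evaluateGrading(pred, ft$grade[sp$test])
#> EvaluationReport on 40 case(s); overall precision 90.00%
#>          system
#> reference Normal  I II III
#>    Normal     10  0  0   0
#>    I           0 10  0   0
#>    II          0  2  8   0
#>    III         0  0  2   8
#> precision: Normal 100.00%, I 83.33%, II 80.00%, III 100.00%
#> recall:    Normal 100.00%, I 100.00%, II 80.00%, III 80.00%
```

A thin command-line front end over these functions ships in
`inst/scripts/cryptarch` (subcommands `simulate`, `segment`, `extract`,
`train`, `predict`, `grade`, `evaluate`).

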