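# pedicleSSM

Statistical shape modelling of vertebral surfaces for pedicle-screw
guide design.

Standardised (non-patient-specific) pedicle screw insertion guides are
only feasible where vertebral anatomy is consistent across a population,
and only if the population's range of pedicle dimensions and screw
trajectories is known. This package builds statistical shape models
(SSMs) of vertebrae from unordered, arbitrarily posed 3D surface point
sets and derives those quantities. It is aimed at biomechanics and
surgical-planning researchers working with segmented vertebral surfaces
(PLY/STL/OBJ), and at anyone needing a fully testable, self-contained
SSM pipeline.

## What it implements

Given $n$ surfaces, the pipeline estimates a model

$$x \approx \bar{x} + \sum_{k=1}^{K} b_k\, s_k\, m_k, \qquad K \le n-1,$$

with mean shape $\bar{x}$, orthonormal modes $m_k$, per-mode standard
deviations $s_k$ (mm) and weights $b_k$ in SD units, via four stages:

1. **Rigid alignment** by coherent point drift (CPD) — EM on a Gaussian
   mixture whose centroids move rigidly; scale held at 1; deterministic
   principal-axes multi-start so arbitrary poses (including near-
   symmetric flips) are resolved.
2. **Relevance-based subsampling** — curvature-weighted farthest-point
   sampling.
3. **Dense correspondence** — coarse non-rigid CPD on the subsets
   (motion-coherent Gaussian-kernel field $T = Y + GW$), evaluated on
   the full template and locally refined against the original samples,
   then rigidly polished by Procrustes.
4. **Projection-pursuit PCA** (Croux–Ruiz-Gazen; variance/MAD/Qn
   indices) with the $K \le n-1$ cap and the >5% retention rule;
   classical PCA as the exact alternative.

On top of the model: ±k·SD shape synthesis, per-vertex distance maps
with per-region summaries, leave-one-out generalisability, partial-shape
completion, and the pedicle morphometry protocol (width, height,
transverse and sagittal pedicle angles from landmarks, repeat
aggregation, guide envelopes). A parametric synthetic vertebra generator
with exact ground truth (planted orthogonal modes, analytic landmarks,
known poses/permutations) makes every stage testable offline.

## Worked example

Generate 20 synthetic vertebrae (500 points each, three planted modes,
random pose and vertex order), run the full pipeline, and inspect the
result:

```r
library(pedicleSSM)

spec <- syntheticSpec(nShapes = 20, pointsPerShape = 500, seed = 7,
                      noiseSD = 0.05, scramble = "rigid+permute")
pop  <- samplePopulation(spec)
ct   <- runPipeline(pop$shapes, runConfig(method = "classical_pca",
                                          seed = 7))
ct$model
#> ShapeModel (classical_pca, index=variance): 500 points, 19 modes, n_train=20
#>   leading variance fractions: 0.735 0.192 0.062 0.001 0.001
ct$retained
#> [1] 1 2 3
```

Three components exceed the 5% retention threshold — exactly the three
planted modes; everything beyond them is noise-floor (fractions
\~0.001). The distance map of the first component at +3 SD localises the
variation anatomically:

```r
dm <- ct$distanceMaps[["pc1_sd+3"]]
regionSummary(dm, ct$model@labels)
#>                 region   max   rms   n
#>   transverse_process_R 3.809 2.577  32
#>   transverse_process_L 3.795 2.577  32
#>        spinous_process 0.840 0.491  64
#>                   body 0.223 0.156 242
#>              pedicle_L 0.202 0.162  32
#>                 lamina 0.195 0.150  66
#>              pedicle_R 0.191 0.152  32
```

The transverse processes vary by ~3.8 mm at +3 SD while the lamina stays
below 0.2 mm — the pattern that makes the lamina the natural anchor
region for a standardised guide. Generalisability:

```r
looRMSE(ct$population)$overall
#> [1] 0.0472   # mm, at the 0.05 mm synthetic noise floor
```

Morphometry and the guide envelope from a measurement table
(dimension × component × SD offset):

```r
measurePedicle(makeTemplate(spec)$landmarks)
#> PedicleMeasurement: width 5.60 mm, height 10.50 mm,
#>                     transverse 8.8 deg, sagittal 14.2 deg

tab <- read.csv(system.file("extdata", "pedicle_dimension_table.csv",
                            package = "pedicleSSM"))
guideEnvelope(tab)
#>          dimension  min  max
#>      pedicle_width  4.7  6.2
#>     pedicle_height  9.0 11.5
#>   transverse_angle  3.5 12.4
#>     sagittal_angle 13.5 21.2
```

A standardised guide set for this table would need to cover transverse
pedicle angles of 3.5°–12.4° and, given the 6.2 mm maximum pedicle
width, screw diameters up to 6 mm.

A thin command-line front end over the same functions is installed at
`inst/scripts/ssm-cli.R` (subcommands `simulate`, `align`, `correspond`,
`build`, `synthesize`, `distmap`, `loo`, `measure`, `envelope`,
`report`).

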