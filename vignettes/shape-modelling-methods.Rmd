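---
title: "Statistical shape modelling of vertebrae: methods and design notes"
author: "pedicleSSM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical shape modelling of vertebrae: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedicleSSM)
```

## The problem

Pedicle screws anchor spinal instrumentation through the pedicle, a narrow
bony corridor whose width, height and orientation vary across individuals.
Standardised (non-patient-specific) insertion guides are only feasible if
the anatomical variation of the target vertebrae is quantified: where the
surface is stable enough to seat a guide, and what range of screw
diameters and trajectories the population spans. A statistical shape model
(SSM) answers both questions: it learns, from a population of segmented
vertebral surfaces, a mean shape and a small set of orthogonal modes of
variation with per-mode standard deviations.

This package implements the full pipeline from raw, arbitrarily posed and
arbitrarily ordered surface point sets to the SSM and the derived
surgical-planning quantities, together with a synthetic vertebra
population generator with known ground truth, so that every stage is
testable without any external data.

## Pipeline

The pipeline has four stages, orchestrated by `runPipeline()`:

1. **Rigid alignment** (`rigidCPD()`, `alignPopulation()`). Each sample is
   registered to a common reference by rigid coherent point drift (CPD):
   the moving set acts as the centroids of an isotropic Gaussian mixture
   (plus an optional uniform outlier component with weight $w$), and EM
   alternates soft assignment with a closed-form weighted Procrustes
   update of rotation $R$, translation $t$, and the shared variance
   $\sigma^2$. Scaling is held fixed at 1 by default so that model
   measurements keep physical units. The negative log-likelihood is
   non-increasing across iterations.

   CPD is a local optimiser, and a vertebra is close to symmetric under
   180° rotations, so EM from an arbitrary pose can converge into a
   flipped basin. `rigidCPD()` therefore starts from a deterministic
   moment-based pre-alignment: the principal axes of the two point sets
   are matched under every proper signed axis permutation (24 candidates;
   axis *order* can swap between shapes when covariance eigenvalues are
   close), candidates are screened by a subsampled nearest-neighbour
   cost, and the survivors are each run to convergence. The winner is
   the run with the smallest final $\sigma^2$ — the residual overlay
   variance — with the likelihood as tie-break. Final likelihoods alone
   are not comparable across runs because the Gaussian likelihood is
   unbounded as $\sigma^2$ collapses on a near-perfect overlay.

2. **Relevance-based subsampling** (`relevanceSample()`). Both template
   and sample are reduced (default 500 points) by farthest-point
   sampling, optionally weighted by a per-point curvature feature
   (the kNN-PCA surface variation $\lambda_3/\sum\lambda$), so that
   feature-dense regions are sampled more densely. The first point is
   the one farthest from the centroid, which makes the selection a pure
   function of the geometry: permuting the input vertex order does not
   change the selected points or their order.

3. **Dense correspondence** (`nonrigidCPDCoarse()`, `localRefine()`,
   `correspondPopulation()`). Coarse non-rigid CPD deforms the
   subsampled template with the motion-coherence parameterisation
   $T = Y + GW$, where $G_{ij} = \exp(-\|y_i-y_j\|^2/2\beta^2)$ and the
   M-step solves $(\mathrm{d}(P\mathbf{1})G + \lambda\sigma^2 I)W =
   PX - \mathrm{d}(P\mathbf{1})Y$. The recovered field is evaluated on
   the full-resolution template and refined against the original
   (full-resolution) sample by a per-point displacement minimiser with a
   kNN-Laplacian stiffness penalty, so the subsampling leaves no imprint
   on the final correspondence. The refined template point positions
   (continuous space, not snapped to sample vertices) become the
   sample's shape-vector.

   Finally each sample's correspondence image is rigidly re-aligned to
   the template by closed-form Procrustes. The density-based rigid stage
   leaves a per-shape pose jitter of the order of 0.1–0.3°, which would
   otherwise enter the model as spurious variance; with dense
   correspondence in hand, the optimal rigid polish is closed-form and
   exact. This makes the model a model of shape modulo pose, which is
   the standard SSM convention.

4. **Projection-pursuit PCA** (`buildShapeModel()`). Components are
   found by the Croux–Ruiz-Gazen search: candidate directions are the
   normalised centred observations (optionally augmented with pairwise
   differences), each component maximises a scale index of the projected
   data over the candidates (variance, MAD, or the Qn estimator), and
   the data are deflated to the orthogonal complement before the next
   search. The number of components is capped at $n-1$. Classical PCA
   (exact eigen-decomposition) is available as `method =
   "classical_pca"` and doubles as an independent cross-check in the
   test-suite. Components whose variance fraction exceeds 5% (default)
   are retained for further analysis (`selectComponents()`).

## Derived analyses

* **Shape synthesis and distance maps.** `synthesizeShape()` evaluates
  $\bar{x} + \sum_k b_k s_k m_k$ with $b$ in SD units; ±3 SD is the
  conventional envelope covering 99.7% of a normal population
  (`normalCoverage(3)`). `makePCDistanceMaps()` overlays each synthesised
  shape on the mean; with dense correspondence the per-vertex distance is
  the corresponding-point distance (a nearest-surface variant exists for
  comparison). `regionSummary()` reduces a map to per-region max/RMS —
  the quantity that identifies low-variance anchor regions (the lamina)
  versus high-variance regions (transverse and spinous processes).

* **Generalisability.** `looRMSE()` rebuilds the model $n$ times leaving
  one shape out, reconstructs the left-out shape by least-squares
  projection on the retained modes, and pools per-point residuals into
  an overall RMSE. Pooling over points (rather than averaging per-fold
  RMSEs) is used; for homogeneous fold sizes the two differ negligibly,
  and pooling weights every point equally.

* **Morphometry.** From the landmark protocol (pedicle margins, an
  endplate triplet, the anterior-body and posterior-spinous extremes,
  and an axis target point anterior to the pedicle along its canal),
  `measurePedicle()` derives pedicle width and height (margin
  distances), the transverse pedicle angle (between the pedicle-axis
  projection into the endplate plane and the midline) and the sagittal
  pedicle angle (elevation from the plane). Angles are unsigned, in
  [0°, 90°], and all measurements are invariant under a common rigid
  transform. Repeats are aggregated as mean ± half-range
  (`aggregateRepeats()`); `guideEnvelope()` reduces a measurement table
  to per-dimension min/max — the coverage a standardised guide set must
  accommodate. The pedicle axis is operationalised as the line from the
  margin centroid to a supplied target point, because the original
  manual cross-section construction is not algorithmically specified;
  the landmark file format carries that target explicitly.

## The synthetic vertebra generator

`syntheticSpec()`/`samplePopulation()` generate populations of
vertebra-like surfaces with known ground truth. The template is assembled
from analytic primitives — an ellipsoidal body, two elliptic-cylinder
pedicles at specified transverse (8.8°) and sagittal (14.2°) angles with
width 5.6 mm and height 10.5 mm at the mean, a posterior lamina arch, two
transverse processes and a spinous process — sampled by a fixed
deterministic pattern (golden-spiral body, parametric grids elsewhere),
so templates built at different parameter values are in exact
point-to-point correspondence and roughly 2000 points cover a shape at
the default resolution.

Three design choices matter for interpretation:

* **Modes act on template parameters, linearly.** Every template
  coordinate is an affine function of each size parameter, so a mode
  that perturbs one parameter is an exact linear direction in shape
  space; the three default modes (transverse-process length,
  spinous-process length, pedicle width-radius) have disjoint regional
  support, hence exactly orthogonal directions, and every
  landmark-derived measurement has a closed form (e.g. width
  $= 2 r_w$).

* **Mode amplitude convention.** A mode's direction is normalised to a
  displacement field of $\kappa\cdot sd$ mm RMS per affected point
  ($\kappa = 0.25$), independent of sampling density. $\kappa$ was
  calibrated once so that +3 SD of the leading default mode (nominal
  sd 3 mm) produces the few-mm peak regional variation typical of
  thoracic posterior elements, with sub-mm variation elsewhere. The
  default mode regions carry equal point counts, so the planted
  variance fractions are exactly $sd_k^2/\sum_j sd_j^2$ and the
  realized fractions are the eigenvalues of
  $\mathrm{diag}(s)\,\mathrm{cov}(W)\,\mathrm{diag}(s)$ for the drawn
  weights $W$.

* **Noise convention.** `noiseSD` is the RMS 3D perturbation per point
  (per-coordinate Gaussian sd `noiseSD`/√3), so it is directly
  comparable to registration and LOO residuals in mm: an in-subspace
  population with `noiseSD = 0.1` has a leave-one-out RMSE of ≈0.1 mm.

Shapes can be scrambled by a random rigid pose and a random vertex
permutation, which is what the full pipeline must undo; the
`GroundTruth` object records weights, poses, permutations, effective
parameters and analytic landmarks pre-scramble. A pooled multi-level
population (`nLevels = 3`) applies small fixed body-size offsets per
level, mimicking the pooling of adjacent vertebral levels into one
training set.

What the generator does *not* emulate: real segmentation artefacts
(holes, topological noise, step artefacts at voxel boundaries),
non-Gaussian shape variation, level-specific mode structure, and
correlated (spatially smooth) measurement noise. Passing the recovery
tests therefore demonstrates the pipeline's correctness and its
statistical efficiency under the stated conditions, not segmentation
robustness on clinical CT.

## Numerical choices

* Rigid and non-rigid CPD stop on a relative objective change of 1e-8 or
  at the iteration cap (150 / 100); $\sigma^2$ is floored at 1e-12 and a
  collapse below 1e-8 mm² is treated as convergence.
* The coarse-stage kernel width defaults to twice the template's mean
  nearest-neighbour spacing; the regularisation weight defaults to
  $\lambda = 1$. On ground-truth warps, heavier regularisation visibly
  over-smooths locally supported stretch (the extension of a process is
  under-tracked, attenuating that mode's variance), while $\lambda = 1$
  still keeps the field coherent; λ remains config-exposed.
* The fine stage solves a sparse symmetric system
  $(I + s L)D = Q - P$ per iteration (k = 6 neighbour graph, s = 1,
  20 iterations) and stops early if the mean residual rises three
  iterations running.
* ppPCA ties are broken by first index; components are sorted by
  decreasing scale after extraction (the greedy search does not
  guarantee monotone scales); candidate rows with near-zero norm after
  deflation are dropped.
* Degenerate inputs: identical training shapes yield a flagged
  degenerate model with zero scales; collinear landmark sets and empty
  geometry are rejected at validity checking.

## Problem sizes used in the validation suite

The test-suite and the acceptance script validate at deliberately chosen
scales: component-count and end-to-end runs use 500 points per shape
(270 and 20 shapes respectively), pure model-recovery runs use the full
2000-point resolution with n = 100, and leave-one-out runs use n = 30 at
500 points. These sizes keep each check sharp — every tolerance is set
by the statistics of the problem, not by the runtime — while the
2000-point default mirrors the sampling density of the motivating
application.

## Known limitations

* Correspondence quality degrades for deformations that slide a surface
  along itself (the aperture problem); only the free ends of processes
  anchor such motion, so per-point errors concentrate at process tips.
  The test-suite bounds the mean error by the noise level plus 5% of
  the warp amplitude; the worst-case tail is larger.
* The rigid stage's moment-based multi-start makes flips rare but is
  still a heuristic for strongly symmetric shapes; the winning-run
  $\sigma^2$ criterion assumes the correct basin achieves the lowest
  residual variance.
* The model is linear; strongly non-linear variation (e.g. bending of
  long processes) is only captured as a sequence of linear modes.
* ppPCA restricted to observation candidates recovers directions with a
  few degrees of extra error compared with the exact eigen-decomposition
  under Gaussian data; this is the price of its outlier robustness, and
  the precision-facing recovery analyses in this package use the exact
  method where precision is the goal.
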