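---
title: "Models and methods behind flypose3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flypose3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models implemented in `flypose3d`, the
assumptions behind them, the parameters that matter, and the choices made
where the design was genuinely open. The package targets a specific
acquisition geometry — a ring of seven inward-looking cameras about 94 mm
from a tethered fly, 480 × 960 px frames at 100 Hz — but every quantity
below is configurable.

## Camera model

Each camera is a pinhole with radial distortion. World coordinates map to
camera coordinates by `Xc = R X + T` (axis-angle rotation, translation in
mm), to ideal pixels by `u = fx x/z + cx`, `v = fy y/z + cy`, and to
observed pixels through the radial model

```
u_pinhole = u (1 + k1x r² + k2x r⁴),   v_pinhole = v (1 + k1y r² + k2y r⁴)
```

Conventions that needed fixing:

* **The radius.** We compute `r` on principal-point-centered,
  focal-normalized coordinates and apply the scaling to those centered
  coordinates before re-offsetting. Scaling raw pixel coordinates (the
  literal reading) makes the model depend on where the principal point
  sits in the image; the normalized form is the physically meaningful one.
  The raw variant remains available via `distortion_frame = "raw"` on
  `camera_model()`.
* **Direction.** The formula above maps an *observed* (distorted) pixel to
  the pinhole prediction, which is exactly what triangulation needs
  (`to_pinhole()` is closed-form). Projection needs the inverse — finding
  the observed position of a known pinhole projection — which has no closed
  form; `project()` inverts the scaling by fixed-point iteration to 1e-14,
  so `to_pinhole(project(X))` reproduces the ideal projection to machine
  precision.
* **Pixels** are 0-based, `u` = column, `v` = row, origin top-left, integer
  coordinates at pixel centers; this convention is used everywhere,
  including file formats.

Triangulation builds the homogeneous DLT system (two rows per visible
camera, in focal-normalized coordinates for conditioning), solves it by SVD
and de-homogenizes. If the two smallest singular values coincide (parallel
rays; fewer than two distinct viewpoints) the point is reported as
degenerate rather than invented.

## Self-calibration

The animal itself is the calibration target: the robust bundle-adjustment
objective

```
argmin over {π_c}, {X_j} of  Σ_c Σ_j e_cj ρ_δ( ‖π_c(X_j) − x_cj‖ )
```

is minimized over ten free parameters per camera (three rotations, three
translations, four distortion coefficients; focal lengths and principal
points are taken from the manufacturer and held fixed) and all structure
points. `ρ_δ` is the Huber loss with δ = 20 px.

Open design points and how we resolved them:

* **Initialization.** Camera centers uniformly spaced on a horizontal ring
  of the configured radius (default 94 mm), optical axes through the origin,
  image rows horizontal, distortion zero. Per-camera azimuth overrides are
  available for rigs measured by hand.
* **Outlier pre-filtering.** For a horizontal ring, corresponding detections
  must fall on nearly the same image row in all cameras; detections more
  than 5 px (configurable) from the median row are discarded before
  optimization.
* **Optimizer.** The objective specifies no algorithm. We use sparse
  Levenberg–Marquardt: finite-difference Jacobian blocks per camera and per
  point, normal equations reduced onto the cameras via the Schur complement
  on the 3 × 3 point blocks, Marquardt diagonal damping. The robust kernel
  enters by iteratively reweighted least squares (Huber weights frozen per
  round, at most `max_outer = 5` rounds). A run on 7 cameras × 200 points
  converges to machine precision in seconds.
* **Gauge.** The objective is invariant to a global similarity transform.
  Camera 1's extrinsics are frozen (removes rotation + translation) and the
  overall scale is pinned by rescaling the mean camera-center distance to
  the configured ring radius. Recovery comparisons in the tests additionally
  align by closed-form (Umeyama) Procrustes, as any such comparison must.
* **Distortion identifiability.** At this working distance the animal
  subtends a small field, so normalized radii are ~0.01 and the `r⁴`
  distortion terms are essentially unobservable: their curvature is many
  orders below the rotations', and unconstrained they drift to absurd
  magnitudes without improving the fit (eventually breaking the distortion
  inversion). A weak zero-centered Gaussian prior (sd 10) on the
  coefficients inside the optimizer pins the unidentified directions; at
  physically plausible magnitudes (|k| ≲ 0.3) its cost is ~4e-4 px², i.e.
  nothing.
* **Gross-outlier rejection.** After the reweighted fit converges,
  observations with residuals above `3 δ` are discarded and the fit is
  refined once on the survivors (`trim = 3`; judged on the surviving
  observations). A Huber M-estimate alone bounds the influence of each
  outlier but keeps a bias of order the outlier fraction; with rejection,
  calibration on data containing 5% of 100 px outliers recovers camera
  centers as precisely as on clean data, while an ordinary squared loss is
  off by millimetres — the regime difference the robust loss exists for.

## Candidates and pictorial-structures correction

Detector output is a per-keypoint, per-camera probability map (64 × 128 by
default, carrying a scale transform to acquisition pixels; values are
non-negative scores with no sum-to-one requirement). From each map up to 10
local maxima at least one map-pixel apart (Chebyshev) are retained —
plateaus, in particular the zero background, yield none — and all pairs of
peaks from all pairs of visible cameras are triangulated: at most
`C(v, 2) · n²` candidates per keypoint (600 for four cameras seeing a
point, ten peaks per map). Candidates within 1e-3 mm of each other are
merged, keeping the best image evidence.

One candidate per keypoint is then selected by MAP inference in a
tree-structured model whose log-score sums:

* **Unary**: log map intensity at the candidate's projection in each camera
  that sees the keypoint, floored at `eps_p = 1e-6` (empty pixels would
  otherwise send the log to −∞); cameras that cannot see the keypoint
  contribute the constant `log(eps_p)`, which cancels between candidates.
* **Pairwise**: log density of the candidate segment length under a prior
  per skeleton edge — Gaussian for most segments, Beta (on `[0, L]` with
  `L = 1.05 ×` the longest observed length) for the two distal tarsal
  segments, whose *apparent* length distribution is left-skewed because
  occlusion shortens the visible tarsus.
* **Reprojection**: the log of the product over supporting cameras of
  inverse *squared* distances between the candidate's projections and its
  supporting detections, each distance clamped below at `eps_r = 1` px
  (the unclamped factor is singular at zero; the formulation leaves the
  regularization open, so the clamp is ours).

The skeleton is a forest of chains — five keypoints per leg rooted at the
body-coxa, three abdominal points per side, the two antennal points — with
loops in no component, so max-sum belief propagation (one leaf-ward message
sweep, one backtracking sweep, `O(n k²)`) is *exact*; the test suite checks
it against exhaustive enumeration on 10,000 random trees. Inter-limb edges
are never defined for this skeleton, hence per-chain inference; a keypoint
with no candidates splits its chain and the pieces are solved independently.
A user-pinned 2D annotation becomes the only admissible support in its
camera, with image likelihood one; cameras outside a keypoint's supporting
pair store the reprojection of the selected 3D point, which is also how
occluded views are filled in.

Priors are learned by maximum likelihood (sample mean/SD; numeric Beta MLE
via `fitdistrplus`, method-of-moments fallback) from a pose archive, after
excluding frames above a reprojection cutoff — the same exclusion used for
calibration. Degenerate inputs (constant lengths, too few frames) produce a
floored sigma or an explicitly uninformative prior that scores zero.

## Quality control

Per frame and keypoint, the summed squared reprojection residual of the
triangulated point is the error signal; the frame aggregate is the maximum
over keypoints (a single bad joint should flag a frame; `sum` and `mean`
are available). Frames above a threshold — the 95th percentile by default,
since no numeric cutoff is prescribed — are flagged and ranked for manual
annotation under a budget. 2D accuracy is reported as PCK (fraction of
keypoints within 50 px of truth, about a third of a femur length at this
image scale), plus RMSE and MAE with the near-stationary body-coxa and
coxa-femur joints excluded so they cannot dominate the averages.

## Behavioral embedding

The pipeline from 3D pose to a behavioral map:

1. **Smoothing** with a 1€ filter (causal adaptive low-pass; cutoff
   `fc = min_cutoff + β |dx̂|`). Defaults: min-cutoff 1 Hz, β = 0.01,
   derivative cutoff 1 Hz. Note a first-order filter at its cutoff retains
   ~80% of a 1 Hz component — the filter trades jitter for lag, it is not a
   brick wall. Its speed term acts per coordinate, so smoothing commutes
   only approximately with global rotations of the pose (deviations ~0.01
   rad in practice); exact invariance belongs to the next step.
2. **Angles.** The default 20 channels are the interior three-point angles
   (`acos` of normalized dot products): coxa-femur, femur-tibia and
   tibia-tarsus per leg (18) plus one abdominal angle per side (2) — all
   exactly invariant to translation, scale and rotation. A 27-channel
   preset adds two coxa orientation angles per leg and the antennal tilt
   against the gravity axis; those referenced angles are deliberately *not*
   rotation-invariant (the source enumerations disagree on 20 vs 27, so
   both are shipped and the invariant set is the default). Zero-length
   segments carry the previous frame's angle and are flagged.
3. **Posture dynamics.** Morlet CWT (ω₀ = 5) of each mean-removed channel at
   25 scales whose center frequencies are log2-uniform between 5 and 50 Hz
   inclusive; features are coefficient magnitudes, giving 20 × 25 = 500
   dimensions per frame. The transform runs over FFT with
   reflection padding by the largest wavelet's support, so the ends of a
   recording do not contaminate each other; the precondition is
   `rate ≥ 2 f_max` (met exactly by 100 Hz / 50 Hz).
4. **Normalization** of each frame's feature vector to unit sum, making it a
   distribution over frequency channels — required because the next step
   measures divergence between distributions ("unit length" is read as L1
   for this reason). All-zero rows become uniform and are flagged.
5. **Embedding** by exact dense t-SNE (perplexity 35, 500 iterations, early
   exaggeration, adaptive gains) with the symmetrized KL divergence
   `(KL(p‖q) + KL(q‖p))/2` in place of squared Euclidean distance in the
   affinity calibration; symmetrization is required because the affinity
   machinery assumes a symmetric dissimilarity. Rows are canonicalized
   (sorted) before optimization and un-permuted after, so results do not
   depend on frame order; a fixed seed fixes the result. No R t-SNE
   implementation is available in this environment, so the package carries
   its own; dense `O(T²)` per iteration is appropriate for the series
   lengths (hundreds to a few thousand frames) it targets.
6. **Map.** Embedded points are min–max normalized into a square grid with
   an interior margin of 5σ, accumulated into a histogram, convolved with a
   Gaussian (circular FFT convolution — conserves mass exactly; the margin
   keeps wrap-around negligible), thresholded (default 1e-3 of the density
   maximum → background), and segmented by a watershed flooding from the
   density maxima (8-neighborhood, via `EBImage`). Defaults (1000 × 1000,
   σ = 10 px) correspond to the ~10⁶-frame regime; for desk-scale runs of a
   few hundred frames we use a 150-cell grid so the kernel bridges
   within-cluster gaps — otherwise every frame becomes its own basin. This
   sample-size dependence is a real limitation of histogram + watershed
   segmentation, and the package exposes `grid`, `sigma` and `tolerance`
   for that reason.

## The synthetic scene generator

The generator emulates the features the pipeline depends on: a 7-camera
94 mm ring (fx = fy = 28,000 px, 480 × 960 frames, so the ~0.5 mm legs span
~150 px); an articulated fly (femur 0.15 mm, full segment table in
`fly_geometry()`) whose legs move by sinusoidal joint angles composed
through forward kinematics — segment lengths are constant by construction,
a property the priors rely on; tripod-phased legs, rigid abdominal wag and
head tilt; per-keypoint visibility from the ≤ 4 cameras facing the
keypoint's body side; and probability maps with σ = 1 px Gaussian peaks,
optional uniform noise and logged false-positive bumps. Everything is
deterministic given (config, seed).

What it does **not** emulate: motion blur, occlusion by the treadmill ball,
appearance-dependent detector failures, correlated multi-peak confusions
between left and right legs, and non-periodic behavior. Passing tests on
these scenes therefore validates the geometry, inference and embedding
machinery — not detector robustness on real video.

## Numerical choices and problem sizes

Noteworthy constants: distortion inversion tolerance 1e-14; triangulation
degeneracy threshold 1e-12 (relative singular-value gap); unary floor
`eps_p = 1e-6`; reprojection clamp `eps_r = 1` px; candidate merge radius
1e-3 mm; Huber δ = 20 px; trim threshold 3δ; Gaussian-prior sigma floor
1e-8 mm (tests use 0.01 mm when lengths are exactly constant); Beta support
factor 1.05; t-SNE learning rate 200, exaggeration 12 for 100 iterations,
momentum 0.5 → 0.8 at iteration 250. The shipped tests and the acceptance
script run calibration at 200 points × 7 cameras, exact-inference checks on
10⁴ random trees (≤ 6 nodes, ≤ 6 candidates), correction experiments over
hundreds of seeded trials on one leg chain, and embeddings of 400-frame
two-bout recordings — sizes chosen so the whole suite completes on a single
CPU in minutes while still exercising every code path at the geometry the
package targets.
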