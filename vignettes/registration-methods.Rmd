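---
title: "Marker-free longitudinal infrared registration: models and methods"
author: "thermoreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-free longitudinal infrared registration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoreg)
```

## The problem

Infrared (IR) thermography images the heat pattern of the body surface:
warm vascular structures appear as bright curvilinear ridges on a smooth
warm background. For longitudinal studies — following the same subject
over weeks, for instance during chemotherapy — consecutive frames must
be brought into spatial register before any pixel-wise comparison of
heat energy is meaningful. Skin markers cannot stay attached for weeks,
so registration must rely on anatomy alone. The difficulty is that IR
frames have low contrast and weak edges, the breast surface deforms
non-rigidly between sessions, and the overall intensity level shifts
with basal body temperature.

`thermoreg` implements a fully automatic pipeline for this problem:

1. **Feature detection** on both frames: modified Harris corners with
   adaptive non-maximal suppression (ANMS), and *vascular
   intersections* — branch points of the thinned skeleton of
   vessel-enhanced ridges.
2. **Two-tier matching**: a permissive *relaxation* tier (gradient-
   direction SAD template search) that matches many points but admits
   errors, and a *strict* tier (dual-map shape context with optimal
   assignment and second-best ratio tests) that matches few points
   reliably. Per-side *matching vectors* learned from the strict tier
   purge relaxed mismatches.
3. **Thin-plate-spline (TPS) warping** anchored on the merged control
   pairs.
4. **Competitive winner-guided refinement**: a self-organizing-map
   (SOM) search that perturbs each control point on a lattice of
   *competition units*, scores each candidate registration by mutual
   information (MI), and moves points toward the winning units under
   decaying learning-rate and neighborhood schedules.

`runRegistration()` executes the whole chain; every stage is exported
on its own.

## Feature detection

**Corners.** The Harris response is
$R = \det M - k\,\mathrm{tr}(M)^2$ with $M$ the Gaussian-windowed
($\sigma$ = 2 px) gradient autocorrelation matrix and $k = 0.04$.
Strict 8-neighborhood local maxima above a relative threshold
(`harris_rel_threshold`, default 0.01 of the global maximum) are kept,
with quadratic subpixel interpolation of each peak. ANMS then assigns
each point the radius of the nearest point whose response, scaled by
`anms_c_robust` = 0.9, dominates it, and retains the `anms_n` = 100
largest-radius points — spatially spread, locally dominant corners
rather than clusters.

**Vascular intersections.** The Hessian is computed at scale
`vessel_sigma` = 2 px; for a bright ridge the large-magnitude
eigenvalue $\lambda_2$ is strongly negative while $\lambda_1 \approx
0$. We use a Frangi-style likelihood
$\exp(-R_b^2/2\beta^2)\,(1 - \exp(-S^2/2c^2))$ for $\lambda_2 < 0$
(with $R_b = \lambda_1/\lambda_2$, $S$ the Frobenius norm,
$\beta = 0.5$, $c$ half the maximal $S$), thresholded by Otsu's method
on its *nonzero* values. The mask is thinned (Zhang–Suen with a
connectivity-preserving cleanup pass, so no 2×2 block stays fully set).
A skeleton pixel is a branch point when at least three distinct
branches leave it — its Rutovitz crossing number (0→1 transitions
along the circular 8-neighbor sequence) is ≥ 3. We use the crossing
number rather than a raw count of set neighbors because the raw count
also fires on every staircase pixel of diagonal skeleton runs, which
floods the subsequent clustering with false branch points. Junction
pixels are labeled into 8-connected clusters; clusters whose centroids
fall within `junction_merge_radius` = 8 px merge (single linkage), and
each merged cluster is represented by its pixel-count-weighted
barycenter.

## Two-tier matching

**Relaxation tier.** Each describable feature point carries a window
(`relax_window` = 21 px) of central-difference gradient *directions*;
zero-magnitude pixels are flagged and excluded. Correspondence is a
template search: all candidate centers within
`relax_search_radius` = 30 px of the same coordinates in the other
frame are scored by the circular sum of absolute angular differences
(SAD), and the minimum wins, with parabolic subpixel refinement of the
minimum. The tier is deliberately permissive — mismatches are expected
and repaired later. The pipeline applies it symmetrically (source
features into the target and target features into the source, the
latter inverted) so control coverage does not depend on one frame's
detections; the union is made one-to-one by letting the cheapest
claimant win.

**Strict tier.** Every feature point gets a dual-map shape-context
descriptor: 12 angular × 5 radial log-polar bins (radial edges
log-uniform from $R/16$ to $R$, $R$ = `sc_radius` = 100 px) counted
over the vascular skeleton map, concatenated with the same binning
over the binary heat-pattern map (Otsu threshold of the intensity
image) — 120 bins, each 60-bin half normalized to sum 1. Pixels closer
than $R/16$ or at $R$ and beyond lie outside the descriptor support;
the innermost log-radial edge is the natural lower cutoff and the spec
of the binning leaves no bin for them. Matching costs are
$C_s = \frac12\sum_k (g_k - h_k)^2/(g_k + h_k)$; the optimal
one-to-one assignment of the cost matrix is computed exactly
(shortest-augmenting-path Hungarian, $O(n^3)$, verified against
exhaustive permutation search in the tests). A pair survives only if
it is simultaneously the row and column minimum and passes both
second-best ratio tests
$C(i,j)/C(i_{sec},j) \le T$, $C(i,j)/C(i,j_{sec}) \le T$ with
$T = (R - r_s)/R$, $r_s$ the median finite ANMS suppression radius of
the source set (clamped into $(0,1)$ for degenerate radius sets). The
survivors are few but stable.

**Matching vectors and merge.** Because the two breasts deform
differently, strict matches are split at the vertical midline;
each side's matching vector is the *component-wise median*
displacement (median, not mean, for robustness to residual
mismatches). A relaxed match survives revision iff its side has a
vector and its displacement lies within `vector_tol` = 10 px of it.
Strict and revised-relaxed pairs merge (strict wins on a shared source
point), and ANMS over the source points with response $=-\mathrm{cost}$
keeps at most `pair_anms_n` = 40 spread pairs. Fewer than 4 pairs is a
hard, stage-named failure — the TPS below would be underdetermined.

## Thin-plate-spline warping

With control points $(x_j, y_j) \mapsto (x'_j, y'_j)$, each output
coordinate is
$f(x,y) = a_1 + a_x x + a_y y + \sum_j w_j U(r_j)$,
$U(r) = r^2 \log r^2$, $U(0) = 0$, $r_j$ the distance to the $j$-th
anchor. The coefficients solve
$L \, W = Y$ with $L = \begin{pmatrix} K + \lambda I & P \\ P^\top & 0
\end{pmatrix}$, $K_{ij} = U(r_{ij})$, $P_i = (1, x_i, y_i)$, which
enforces the orthogonality side conditions $\sum_j w_j = \sum_j w_j x_j
= \sum_j w_j y_j = 0$. With $\lambda = 0$ the spline interpolates its
anchors exactly (to 1e-6 px in the tests) and affine correspondences
yield zero bending energy $w^\top K w$. The pipeline default is
$\lambda = 300$ (in the kernel's units; $U \approx 2\times10^4$ at
$r = 50$ px): matched pairs carry roughly a pixel of noise, and a
slightly smoothing spline recovers the underlying warp better than
exact interpolation of that noise. Image resampling always uses the
*backward* model (fitted on swapped pairs, output pixel → source
position) with bilinear interpolation and zero fill outside the
source, so no map inversion is needed.

## Winner-guided SOM refinement

Matched control points sit at slightly wrong positions (different
basal temperature, local heat-pattern change). The refinement adjusts
the *target-side* points: around each one, a $G\times G$ lattice
($G$ = 5) of competition units with spacing $s$ = 2 px is laid out
(clipped to the image); each unit replaces the point, the backward TPS
is refit exactly, the source is warped and scored by mutual
information against the target (joint histogram, `mi_bins` = 32,
nats). The maximizing unit is the *winner* $N_p$; the point moves
toward it by the learning rate
$\mathrm{EtaN}(i) = \eta_0 (1 - i/i_{max})$, $\eta_0$ = 0.5, and every
other control point follows the same offset scaled by the neighborhood
kernel $K(i) = \mathrm{EtaN}(i)\exp(-d^2/2\,\mathrm{SigN}(i)^2)$ with
$\mathrm{SigN}(i) = \mathrm{Sig}_0 (1 - i/i_{max})$ and $d$ the
distance between the control points. A sweep over all points is
*committed* only if the full-grid MI did not decrease, so the
committed MI trace is non-decreasing by construction; convergence is
declared when every winner stays at its center for 3 consecutive
iterations (budget $i_{max}$ = 30).

Three numerical safeguards matter at desk scale, where images are
small and the MI estimate is correspondingly noisy:

- **Winner margin** (`som_mi_tol` = 0.02 nats): an off-center unit
  wins only if it beats the center's MI by more than this margin. We
  measured single-point ±2 px moves of *correctly placed* points
  producing spurious MI gains with 95th percentile ≈ 0.01–0.026 nats,
  while genuine corrections of a 4 px error gain 0.065–0.098 nats; the
  margin sits between the two regimes. Without it the optimizer
  random-walks well-matched points along flat MI ridges.
- **Trust region** (`som_trust_radius` = 6 px): no point may travel
  farther than this from its matched position — the refinement's
  mandate is *slight* adjustment, and the bound caps the damage any
  spurious MI optimum can cause.
- **Neighborhood scale** $\mathrm{Sig}_0$ = 10 px: on a 160×128 frame
  a broad neighborhood couples the entire control set and lets one
  point's move drag all others; 10 px keeps the update local while
  preserving the SOM's cooperative character.

Candidate units are scored on a stride-2 pixel grid for speed; the
committed (reported) MI always uses the full grid.

## Evaluation utilities

SSIM (11×11 Gaussian window, σ = 1.5, K1 = 0.01, K2 = 0.03 on the
[0, 1] range), mutual information, Canny-edge overlays (white = source
only, red = target only, green = agreement within 1 px; hysteresis at
0.1/0.2 of the maximal gradient), marker-error summaries
(min/mean/max of per-marker Euclidean distances), and the coincidence
rate of delineated line masks. The coincidence rate is a *tolerant
Jaccard* index: pixels of either mask within `tol` px (disc dilation)
of the other, over the plain union, in percent; `tol = 0` is the exact
Jaccard index. The underlying clinical quantity is reported without a
formula in the literature this package draws on, so the definition is
a documented, configurable choice.

## The synthetic scene generator

Clinical dual-spectrum IR data are not distributable, so the package
ships a generator whose scenes contain exactly the structures the
pipeline exploits, with ground truth stored exactly:

- a warm anisotropic Gaussian background blob (the breast surface);
- a mottled *heat pattern* of 45 warm/cool Gaussian spots (sd 3–10 px,
  amplitude −0.13..+0.15) whose centers deform with the scene — the
  subject-specific thermal signature. This texture is what makes
  mutual information geometrically informative; with a featureless
  background, MI rewards many wrong warps equally and no registration
  refinement can be validated against it;
- 3 junctions with 3 gently curving vessel branches each
  (Gaussian-profile ridges, width 3 px, brightness 0.28–0.38 above
  background), centerlines and junction coordinates recorded exactly;
- additive Gaussian noise (σ = 0.01) and a global intensity offset
  (0.05) on the second time point, emulating basal-temperature change.

Scenes default to 160×128 px — half the linear resolution of a
320×256 IR detector — so that the full validation suite runs at desk
scale. Ground-truth deformations are identity, translation, or a TPS
on a 3×3 anchor grid with displacements drawn in a disc of stated
radius (default 15 px, about an eighth of the image width); warps that
fold (non-positive Jacobian on a sample grid) or displace more than a
quarter of the image are rejected. Rendering is a pure function of
(scene, warp, noise seeds).

What the generator does *not* emulate: physically realistic heat
diffusion, camera fixed-pattern noise, pose changes out of the image
plane, or the appearance/disappearance of vessels between sessions.
Passing the synthetic suite therefore demonstrates the algorithmic
contract — detectors find what is there, matchers pair what
corresponds, the warp recovers the deformation — not clinical-grade
performance on real thermograms.

## Numerical choices and degenerate inputs

- Intensities are normalized to [0, 1] on reading (dividing by the
  format maximum), so all thresholds are depth-independent.
  Coordinates are 0-based, x = column, y = row.
- A constant image yields zero Harris response and an empty vessel
  mask — "no features detected" is a named pipeline error, as is an
  underdetermined control-pair set (< 4).
- Collinear TPS anchors raise an explicit rank error; duplicate
  anchors with conflicting targets are rejected, consistent ones
  collapse.
- Assignment ties and winner ties break deterministically (nearest
  unit to the current position, then lowest lattice index), making
  the whole pipeline reproducible bit-for-bit for fixed inputs and
  configuration.
- The SAD of two descriptor windows skips pixels flagged
  zero-magnitude in either window and returns `Inf` when nothing is
  comparable.

## Problem sizes in the shipped validation

The test suite and the acceptance script run the full pipeline on
160×128 scenes (10 and 5 seeded pairs respectively), the SOM recovery
fixtures on 12 ground-truth control points, and the oracle checks
(Hungarian vs. permutations, ANMS vs. double loop, χ² vs. explicit
sum) on hundreds of random instances. A single end-to-end
registration takes a few seconds on one core.

## Known limitations

- Matching assumes the two frames share orientation (shape context is
  deliberately not rotation-invariant; the imaging protocol fixes the
  pose).
- The per-side matching vector is a single median displacement; a
  warp whose local displacement deviates from its side's median by
  more than `vector_tol` will see correct relaxed matches discarded.
- MI-guided refinement is only as good as the heat pattern's texture;
  on texture-poor frames the margin safeguard deliberately freezes
  the control points rather than risk drift.
- Control coverage follows the detected features; in regions with
  neither corners nor vessels the warp is pure TPS interpolation and
  carries no data support.
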