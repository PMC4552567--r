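---
title: "Measuring vascular networks and their scaling exponents"
author: "angioscale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring vascular networks and their scaling exponents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angioscale)
```

## The problem

Contrast-enhanced 3D angiography renders the blood pool bright against dark
tissue. Latent in such an image is the geometry of every resolvable vessel:
its effective radius $r$, centerline length $l$, volume $V$, and its place
in the branching tree. Biological scaling theory cares about how these
quantities change across branching generations. Two *vascular scaling
exponents* summarise that change: $a$ for radius and $b$ for length. At a
single branching junction they appear in the generalised conservation law

$$ r_p^{1/a} = \sum_i r_{c,i}^{1/a}, \qquad l_p^{1/b} = \sum_i l_{c,i}^{1/b}, $$

where $p$ indexes the parent and $c,i$ its children. Murray's law is the
special case $a = 1/3$ (flow $\propto r^3$); area-preserving branching (Da
Vinci's rule, predicted where pulse-wave reflection dominates) is $a = 1/2$.
For a symmetric dichotomous tree the child/parent scale factors are
$\beta = r_{k+1}/r_k = 2^{-a}$ and $\gamma = l_{k+1}/l_k = 2^{-b}$, the
size-frequency distribution follows $N = (r/r_0)^{-1/a} = (l/l_0)^{-1/b}$,
and any segment's dimensions relate to the number of downstream tips $N_d$
by $r \propto N_d^{\,a}$, $l \propto N_d^{\,b}$.

These four relationships yield four *estimators* of the same exponents —
conservation-based and ratio-based (local, per junction), and
distribution-based and regression-based (global, whole network). They are
provably identical only for strictly self-similar, symmetrically branching
networks; on real vasculature they need not agree, which is exactly why
measuring all four on the same data is informative. angioscale implements
the full chain: volume → lumen mask → skeleton → measured segment tree →
the four estimators with confidence intervals, plus synthetic ground-truth
generators and sensitivity sweeps.

## Extraction pipeline

1. **Network mask.** Voxels whose intensity strictly exceeds a threshold,
   restricted to the largest 26-connected component
   (`makeNetworkMask`). The threshold is a user decision: for real
   angiograms it is chosen against visual vessel identification (the
   reference workflow used a manual binary search); `suggestThreshold`
   offers an Otsu starting point as a convenience only. Connectivity is
   fixed at 26 by default — the most permissive choice, which avoids
   artificially disconnecting thin, obliquely oriented vessels.

2. **Root.** The voxel maximising the exact Euclidean distance transform
   (EDT) of the mask — the deepest interior point, which for vascular masks
   lies on the axis of the widest vessel (assumed aortic). Ties break
   lexicographically.

3. **Tips.** Vessel endpoints are local maxima of the geodesic
   (within-mask) distance from the root, kept only when they are the
   farthest point of their own geodesic neighbourhood of radius
   `min_separation` voxel-widths, then snapped one voxel toward the
   interior (maximum EDT) so blunt vessel ends contribute an on-axis tip
   rather than a rim corner. The operation default is `min_separation = 3`;
   the pipeline (`extractNetwork`) scales it automatically to
   `max(3, ceil(max EDT) + 2)` because a wall bulge at a junction of a
   vessel of radius $\rho$ voxels produces spurious geodesic maxima with
   prominence up to $\rho$: the suppression radius must exceed the radius
   of the widest vessel. The root's own neighbourhood (radius
   $\sqrt 2 \times$ the suppression radius, covering the rim of a flat
   inlet face) contributes no endpoint; the root voxel itself is protected
   instead, so the skeleton always reaches the inlet.

4. **Skeleton.** Connectivity-preserving erosion: boundary voxels are
   peeled in increasing EDT order (lexicographic tie-break), and a voxel is
   removed only if it is *simple* — its remaining 26-neighbours form one
   connected component **and** the adjacent background stays 6-connected in
   its 18-neighbourhood (the Malandain–Bertrand characterisation). The
   second condition stops the erosion from drilling tunnels through thick
   junctions, which would otherwise leave small skeleton loops. Protected
   voxels (tips and root) are never removed; erosion stops when nothing
   removable remains, so no voxel can be deleted without disconnecting some
   endpoint pair. For straight-tube phantoms of radius 2–5 voxels the
   surviving centerline stays within about one voxel-width of the true
   axis.

5. **Paths and junctions.** Skeleton voxels are classified by their number
   of skeleton 26-neighbours (1 endpoint, 2 regular, ≥3 branch) and split
   into maximal paths with regular interiors. Adjacent branch voxels are
   merged into junction clusters, and a path that runs from one branch node
   to another in less than `junction_merge_factor` (default 1.5) times the
   local vessel depth is *junction plumbing* — skeleton structure inside a
   single junction ball, where two child centerlines rarely fuse at exactly
   one voxel — and is contracted into the junction node rather than
   reported as a vessel. Each junction is represented by one junction
   point, the deepest voxel among its members; incident centerlines are
   measured from that point, with their in-ball wander replaced by a
   straight step. A segment terminating at the root voxel is lengthened by
   the root depth so it spans the inlet slab its voxels cover.

6. **Measurement.** Every mask voxel is attributed to the segment with the
   nearest centerline voxel (physical distance, ties to the lower segment
   id). Length is the sum of Euclidean steps along the centerline — no
   quantisation correction, so lengths are overestimated by the jagged
   digital polyline and radii $r = \sqrt{V/(\pi l)}$ are correspondingly
   underestimated; both biases are scale-free and cancel in the scaling
   ratios. Volume is voxel count × voxel volume. A segment is
   *well-segmented* when at most 20% of its voxels lie farther than
   $(r + 1)$ voxel-widths from its centerline and it has at least 4 voxels;
   the $+1$ is one voxel of tolerance, so the rule is applied in
   voxel-width units.

7. **Tree.** The segment graph is rooted at the maximum-radius segment and
   oriented outward breadth-first. Segments on cycles (anatomical
   reticulation, e.g. the Circle of Willis) are flagged `in_loop` —
   detected as non-bridge edges — and excluded from junction records; no
   loop-breaking is attempted. Downstream tips count leaves, each leaf
   counting itself ($N_d = 1$). Parent misattribution at ambiguous
   junctions is not corrected: orientation is purely by traversal from the
   root, reproducing the reference behaviour.

## The four estimators

All estimators consume a segment table (from extraction, from a TSV, or
synthetic) and filter to well-segmented, non-loop segments.

* **Conservation** (`conservationEstimate`): solve
  $\sum_i (c_i/p)^{1/x} = 1$ at each junction by safeguarded Newton
  iteration. When every child is strictly smaller than its parent the power
  sum is monotone in $x$, the root is unique, and convergence is fast; we
  iterate to machine convergence, far inside the required residual
  tolerance of $10^{-5}$ (stopping exactly at $10^{-5}$ residual would
  leave ~$10^{-5}$ error in $x$ itself). If any child equals or exceeds the
  parent the junction's exponent is undefined and it is dropped. The
  estimate is the unweighted arithmetic mean over defined junctions
  (subjects pooled), with a 95% CI of 1.96 standard errors.

* **Ratio** (`ratioEstimate`): per-pair exponents $-\log_2\beta$ and
  $-\log_2\gamma$ from parent–child pairs at *dichotomous* junctions (two
  non-loop children, both vessels well-segmented), averaged as above.
  Trichotomous junctions contribute to the conservation estimate only.

* **Distribution** (`distributionEstimate`): bin $\ln$(size) into 20
  equal-width bins, discard the first 5 (radius) or 7 (length) bins — the
  smallest vessels, whose counts are unreliable because vessels near the
  resolution limit are censored — drop empty bins, and SMA-fit
  $\ln$(relative frequency per bin) against $\ln$(mean size in bin); the
  exponent is $-1/\mathrm{slope}$. Using per-log-bin relative frequency
  (rather than a linear density, which would shift the slope by $-1$) makes
  the ideal-tree slope exactly $-1/a$; the choice is validated by synthetic
  recovery. The CI is the middle-95% range of exponents over all binnings
  with both parameters varied by up to ±3 (discard floored at 0).
  Maximum-likelihood power-law fitting is deliberately not offered: the
  data are neither cleanly continuous nor discrete (sizes cluster near
  powers of $\beta$), and binned SMA fits are stable on simulated tables.

* **Regression** (`regressionEstimate`): SMA fit of $\ln r$ (or $\ln l$)
  against $\ln N_d$ over all well-segmented segments; the slope estimates
  the exponent, with the closed-form SMA slope CI.

SMA (standard major axis) regression is used for both network-level fits
because the two variables carry comparable error and the goal is the slope,
not prediction of $y$ from $x$: the slope is
$\mathrm{sign}(\rho)\,s_y/s_x$, so fitting $y\sim x$ and $x\sim y$ gives
exact reciprocals. The slope CI is the Warton-style closed form
$\mathrm{slope}\,(\sqrt{B+1} \pm \sqrt B)$ with
$B = (1-r^2)\,t^2_{0.975,n-2}/(n-2)$.

`welchCompare` tests any two estimates against each other from their means
and standard errors (Welch–Satterthwaite), which is how disagreements
between the four methods are quantified.

## Synthetic ground truth

`makeIdealTable` builds the segment table of a full $n$-ary tree with
$r_k = r_0 n^{-ak}$, $l_k = l_0 n^{-bk}$ and $N_d = n^{K-k}$ — the exact
regime where the four estimators provably coincide; optional lognormal
jitter and the asymmetric two-ratio variant break that identity in
controlled ways. `perturbTable` adds multiplicative lognormal noise to an
existing table for bias/variance studies.

`layoutAndVoxelize` rasterises the same tree as straight capsules in 3D:
children leave the parent tip at ±40° in branching planes that rotate 90°
each generation (an H-tree-like space-filler), tubes are checked for
non-adjacent overlap, caps are rounded where tubes meet and cut flat at the
root inlet and leaf tips (so a lone tube is a true cylinder). The layout
geometry itself is plumbing, not science: only the topology and the
per-segment dimensions matter to the estimators, so any non-overlapping
arrangement serves. Optional 3× supersampling produces partial-volume
boundary intensities that mimic MRI softness; the default is a hard
two-level image because it makes mask identities exact and tests sharp.

The default phantom conditions — 4 generations, root radius 12 voxels
(leaf radii 3 voxels, near the resolution floor of the quality filter),
root length 40 voxels, $a = 0.5$, $b = 1/3$, intensity 100 over background
0 — give a ~160³ volume with ~57k lumen voxels that extracts in about a
second. These phantoms emulate the *geometry* of angiographic data:
straight, non-tapering tubes with sharp walls and exact self-similarity.
They do not emulate tortuosity, tapering within a segment, intensity
inhomogeneity, partial-volume blur (unless supersampled), or anatomical
reticulation, so passing recovery tests demonstrates correctness of the
measurement chain, not robustness to everything real angiograms do.

## Numerical choices and degenerate inputs

* Strict `>` thresholding; empty masks are an error that names the
  threshold as too high.
* Component-size ties in `largestComponent` go to the component holding the
  lexicographically smallest voxel; all voxel-order tie-breaks in the
  package are lexicographic on (x, y, z).
* A single-voxel centerline gets length = one voxel width rather than 0,
  so its radius stays finite.
* `downsample2x2x2` crops trailing odd slices before averaging, so every
  output voxel is an exact 8-voxel mean; spacing doubles and the origin
  moves to the first block centre (voxel-centre convention:
  position = origin + index × spacing, indices 0-based).
* Masks with interior cavities are processed as-is (no hole filling); the
  background condition of the simple-point test merely prevents *new*
  tunnels.
* Newton iteration for the conservation exponent starts at $x_0 = 0.5$ and
  falls back to bisection on a bracket that is expanded until it straddles
  the root.
* Sweeps derive one sub-seed per step from the sweep seed, so any single
  step is reproducible in isolation; `maxThreshold` bisects over the sorted
  unique foreground intensities, counting well-segmented vessels.

## Design choices that were genuinely open

* **Endpoint criterion.** The geodesic-local-maximum rule with an adaptive
  suppression radius is this package's own criterion; detailed endpoint
  heuristics vary between implementations and are rarely published in
  full. It is deliberately isolated in `detectEndpoints` so it can be
  swapped.
* **Junction-plumbing contraction and junction points** (step 5 above) are
  likewise this package's resolution of what "a branch point" means on a
  thick 26-connected skeleton; the 1.5 × depth threshold says "a vessel
  shorter than 1.5 of its parent's radius cannot be resolved as a vessel at
  this grid resolution". On the 4-generation phantom this reduces the
  segment graph exactly to the generating topology.
* **Well-segmented counting in sweeps.** "Visible segments" for the
  maximum-threshold search counts vessels passing the quality filter;
  counting raw fragments would let noise shards near the intensity ceiling
  masquerade as vasculature.
* **Undefined conservation junctions** use strict inequality (children
  must be *smaller*); equality makes the power-sum equation degenerate at
  the boundary.

## Problem sizes

The test-suite defaults are: ideal tables with $K = 10$ (2047 segments) for
estimator identities; 200–1000 random junctions for the solver contract;
the $K = 4$ phantom above for end-to-end recovery; and a 21-step threshold
sweep plus a one-multiple noise sweep for sensitivity, all chosen so the
whole suite completes in a few minutes on one CPU while leaving the
estimator sample sizes large enough that Monte-Carlo wobble is far below
the asserted tolerances.

## Known limitations

* Vessels shorter than ~1.5× their parent's radius are absorbed into the
  junction by the plumbing contraction.
* Lengths carry the digital-polyline overestimate (several percent,
  orientation-dependent); radii inherit the opposite bias. Relative
  (scaling) quantities are unaffected, which is what the exponents are.
* Loop handling is flag-and-exclude; networks that are mostly reticulated
  will yield few junction records.
* The published raw human vessel-segment dataset is not redistributed with
  the package; `readSegmentTable` accepts it (header-name mapping, unknown
  columns ignored) when placed at `inst/extdata/s1_vessel_segments.tsv`,
  and the corresponding checks in the test suite report its absence
  otherwise.

## A worked example

```{r example, eval = FALSE}
ph <- layoutAndVoxelize(treeSpec(K = 4, r0 = 12, l0 = 40, a = 0.5, b = 1/3),
                        voxel_mm = 1)
tree <- extractNetwork(ph$volume, threshold = 50)
tree
scalingExponentTable(tree)
```
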