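---
title: "Models and methods behind organellometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind organellometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

organellometry quantifies the morphology and motility of intracellular
structures — mitochondrial networks, endoplasmic reticulum, vesicles,
Golgi — in 2D or 3D fluorescence timelapses. This vignette explains the
models the pipeline rests on, the parameters that matter, the choices made
where the design was genuinely open, and what validation on synthetic data
does and does not establish.

## Structural enhancement

Fluorescence intensity varies with labelling density and laser power, so the
pipeline segments on *local structure* rather than brightness. Each frame is
analysed with a multiscale Hessian filter: at a scale $\sigma$ (microns) the
image is smoothed by an anisotropy-aware Gaussian (per-axis width
$\sigma/\Delta_a$ voxels for spacing $\Delta_a$), the Hessian is computed
with $\sigma^2$-normalised derivatives, and its eigenvalues
$\lambda_1, \lambda_2(, \lambda_3)$ (sorted by magnitude) give the response

$$ R_\sigma = \left(1 - e^{-S^2 / 2\gamma^2}\right)
   \quad\text{where}\quad S = \lVert \lambda \rVert_2, $$

set to zero unless all principal eigenvalues are negative (bright
structures). The final response is the voxelwise maximum of $R_\sigma$ over
scales.

Three choices here differ from the classic vesselness filter and deserve
justification:

* **No plate or blobness penalty.** The classical terms
  $R_a = \lambda_2/\lambda_3$ and $R_b = |\lambda_1|/\sqrt{|\lambda_2\lambda_3|}$
  suppress non-tubular shapes; a sphere or disc has $R_b \approx 1$ and
  would be attenuated roughly sevenfold at the usual $\beta = 0.5$, dropping
  vesicle-like organelles below any automatic threshold. Since the filter
  must serve round and tubular structures alike, the default response keeps
  only the structureness term; `hessian_response_at_scale(beta = )` restores
  the classical penalty if wanted.
* **One $\gamma$ shared across scales**, equal to half the maximum
  eigenvalue norm over all scales. The $\sigma^2$-normalised derivatives
  already put a thin and a thick tube of equal contrast on a comparable
  response scale (a radius-2 and a radius-6 voxel tube both reach at least
  half the global maximum). Renormalising each scale by its *own* maximum
  instead would amplify the weak, broad halo that a large-$\sigma$ kernel
  produces around a thin structure up to full response, roughly doubling the
  mask width and capping achievable segmentation Dice near 0.6.
* **Scales from physics, not from the image.** Scales are log-spaced over a
  target radius range, 0.25–1.0 µm by default — the size range of typical
  organelle cross-sections under diffraction-limited light microscopy — and
  converted to per-axis voxel widths from the stack's spacing, so the filter
  adapts to magnification and anisotropy with no user input. Scales below a
  quarter voxel are dropped.

Gaussian derivative kernels are sampled analytically, mirror-padded at the
borders, and corrected to a vanishing discrete zeroth moment so constant
images (and constant offsets) produce exactly zero response.

## Thresholding and the segmentation hierarchy

The semantic mask is `response > threshold` with single-voxel specks
removed (a physical minimum size in µm² or µm³ is available). The default
automatic threshold is **Otsu on the 256-bin histogram of the strictly
positive response values**. The more sensitive min-of-Otsu-and-triangle
variant (`threshold_method = "minotri"`) is implemented and exported, but is
not the default: on response histograms whose mass decays smoothly from the
noise floor, the triangle knee settles just above that floor and admits the
filter's residual halo, which costs 10–40 Dice points on our synthetic
benchmarks while gaining little dim-structure sensitivity that Otsu misses.

The mask is then deconstructed:

1. **Organelles** — connected components under full connectivity
   (8-connectivity in 2D, 26 in 3D), labelled deterministically in scan
   order.
2. **Distance transform** — exact anisotropic Euclidean distance to the
   nearest background voxel centre, in microns; at the skeleton it estimates
   the local radius.
3. **Skeleton** — topology-preserving curve thinning: border voxels are
   removed in increasing distance-transform order in six directional
   subpasses per iteration, removing only *simple* points (foreground
   8/26-connectivity and background 4/6-connectivity both preserved,
   checked at removal time) and never curve endpoints. Ordering by the
   distance transform centres the skeleton; directional subpasses stop
   removals from cascading through a structure within one pass. Loops
   survive (a ring yields a closed one-voxel-wide cycle), every component
   keeps at least one voxel, and a 1-voxel object is its own skeleton.
4. **Branches** — junction voxels (more than two skeleton neighbours) are
   removed; remaining components are branches; each junction voxel then
   joins its adjacent branch with the lowest label so that every skeleton
   voxel carries a branch label. All-junction fragments become branches of
   their own.
5. **Nodes and voxel assignment** — every skeleton voxel is a node with its
   radius from the distance transform; every mask voxel is assigned to the
   nearest node of its own organelle (physical distance, ties to the lowest
   node index). The assignment partitions the mask exactly, which is what
   lets features roll up and down the hierarchy without double counting.

Each frame is segmented independently; no temporal smoothing is applied,
because the tracking stage is deliberately independent of instance labels.

## Motion-capture markers and linking

Consistent instance segmentation across frames is notoriously fragile, so
tracking uses label-independent *motion-capture markers*: local maxima of
the distance transform inside the mask, selected by greedy non-maximum
suppression with an adaptive exclusion footprint of per-axis half-width
$\max(1, r/\Delta_a)$ voxels, where $r$ is the local radius. Thick regions
therefore carry sparse markers and thin regions dense ones; plateau maxima
resolve deterministically to the lowest-index voxel, and every organelle
receives at least one marker.

Each marker also carries a **sub-voxel centre**: the centroid of
background-subtracted intensity (the photon centroid) over a window half
again as wide as the footprint. Detection and feature patches stay on the
voxel grid; all geometry — cost distances, displacement vectors, flow
queries — uses the refined centre. This matters: with integer marker
coordinates every link vector is quantised to whole voxels, which floors the
achievable tracking error at about half a voxel regardless of the linker.
The window factor 1.5 captures the PSF tails that carry the sub-voxel
position without reaching into neighbouring structures; the intensity
centroid (rather than a distance-transform centroid) moves continuously
with the object, whereas any mask-derived quantity can only move when a
boundary voxel flips.

Markers are characterised within a radius-adaptive bounding box (half-width
equal to the radius in voxels per axis): the **stats vector** holds mean and
variance of the raw and enhanced image in the box; the **Hu vector** holds
the first six Hu moment invariants of the raw and enhanced patch (2D), or of
the xy/xz/yz maximum-intensity projections of the box (3D, 36 values),
stored as $\mathrm{sign}(\phi)\log_{10}(|\phi| + 10^{-30})$ since the raw
invariants span many orders of magnitude. Note that odd-order invariants of
nearly symmetric patches are near zero, where the log-magnitude is
ill-defined noise; invariance checks are meaningful only for asymmetric
patterns.

Linking builds three difference matrices over marker pairs within the
maximum travel distance (1 µm per frame by default — roughly an organelle
radius per second at 1 Hz): physical distance, stats-vector distance and
Hu-vector distance, each z-scored over the admissible entries of the current
frame pair and summed with equal weights. Markers link to their cheapest
admissible partner in each direction separately — no global assignment is
solved — so 1-to-1, 1-to-n and n-to-1 matches all arise, which is exactly
what splitting and merging membrane networks require.

## Flow interpolation, tracks and voxel fates

Any coordinate of interest receives a displacement vector as the normalised
weighted sum of nearby linked markers' vectors, with weights
$(d_k + \varepsilon_d)^{-1}(c_k - c_{\min} + \varepsilon_c)^{-1}$ over links
within the travel radius. With the default $\varepsilon = 10^{-6}$ the
closest/cheapest link effectively wins; larger values blend neighbouring
linkages into a smoother field. A coordinate with no link in range gets the
zero vector (flagged by `support = 0`) — conservative "unmoved" rather than
extrapolated. Interpolated vectors always lie in the convex hull of the
contributing link vectors.

Tracks advance seeds frame by frame at fractional (sub-voxel) precision;
rounding happens only in voxel-fate matching, where each mask voxel at $t$
is displaced, rounded, and matched to the frame-$t{+}1$ mask voxel it lands
on (or the nearest one within one voxel, else flagged unmatched), carrying
the target's node/branch/organelle labels.

## Features

All lengths are microns, times seconds, angles radians; `_12` marks the
interval $t \to t{+}1$ and `_01` the interval $t{-}1 \to t$; accelerations
need both and are `NA` on boundary frames (single-frame runs omit motility
columns entirely).

* **Voxel level**: raw/enhanced intensity; linear velocity magnitudes and
  (zyx) components — components are exported because a mean of magnitudes is
  biased upward at speeds comparable to the flow noise, while the magnitude
  of the mean velocity is not; pivot-relative linear and angular kinematics;
  the pivot's own kinematics (`ref_`); and the branch's directionality
  relative to the intensity centre of mass (`com_directionality`, positive =
  moving away from it).
* **The pivot** of a branch is its skeleton node nearest the branch's voxel
  centroid; its position at adjacent frames advances with the branch's
  *mean voxel flow*. A point interpolation at the pivot coordinate would
  agree for rigid translation but inherits the noise of a single flow
  query; the centroid velocity is the stable estimator, and for a rigidly
  rotating branch it correctly leaves the pivot at the centre of rotation.
  Because segmentation is per-frame, the pivot is defined per frame and
  advanced only across the two adjacent frame pairs that the features need.
* **Node level**: thickness (twice the radius) and vergence — the mean
  outward component of the surrounding voxels' flow relative to the node
  centre's flow; positive for diverging, negative for converging motion,
  and zero for any uniform field.
* **Branch level**: length (longest geodesic through the branch's skeleton
  under 26-adjacency with anisotropic step weights), mean radius,
  tortuosity (length over end-to-end distance; 1 for single-node branches),
  aspect ratio (length over twice the mean radius — the package's
  definition), voxel count and volume.
* **Organelle level**: volume/area, extent, solidity (voxel count over the
  rasterized convex hull — voxel centres inside the hull of the organelle's
  voxels, computed by an incremental 3D quickhull or the 2D hull), inertia
  tensor eigenvalues of the physical voxel cloud sorted ascending, and
  ellipse-convention axis lengths $4\sqrt{\lambda}$.
* **Aggregation**: any child table rolls up to any parent as
  `{child}_{stat}_{feature}` columns over mean/std/min/max/median/sum;
  empty child sets yield `NA`. The pipeline's default tables aggregate each
  level's intrinsic features one level up plus voxel aggregates at every
  level; unrestricted nested aggregation is available through
  `aggregate_features()` but is not the default, since aggregating every
  aggregate multiplies columns combinatorially.

Note the radius convention: the distance transform measures to the nearest
*background voxel centre*, so a tube of true radius $r$ reads
$r + \Delta/2$ on average (worst case one voxel when the axis is
grid-aligned). Thickness and aspect-ratio values inherit this half-voxel
bias; at typical sampling (radius at least two voxels) it stays within the
15% the validation demands.

## Graphs and the multi-mesh

For network topology, junction voxel clusters contract to single graph
nodes, tips are nodes, and each branch becomes one edge between the nodes at
its ends — a multigraph: a branch whose ends meet the same junction is a
self-loop, an isolated cyclic skeleton becomes one node with one self-loop,
and parallel branches stay parallel edges, because collapsing either would
corrupt cycle counts. Per node the package reports degree (self-loops count
twice) and betweenness centrality — computed on the underlying simple
graph, normalised by $2/((n-1)(n-2))$, and zero for graphs with fewer than
three nodes; per graph the degree distribution, means, the cyclomatic
number $E - N + C$ and its normalisation by $N$ (the normalisation choice is
a package convention, exposed prominently since no standard exists).

The multi-mesh orders one organelle's skeleton nodes by depth-first
traversal from the lexicographically smallest tip (children in
lexicographic order; the smallest-coordinate node is the fallback root),
then connects traversal indices $k 2^\ell$ and $(k{+}1) 2^\ell$ at level
$\ell$: level 0 is the chain of consecutive nodes and a path of $2^k + 1$
nodes has levels with $2^k, 2^{k-1}, \dots, 1$ edges. Only stride-aligned
pairs are connected, keeping the edge count linear in $N$. DFS ordering
keeps indices contiguous along branches, so power-of-two jumps respect
geometry; the trade-off is that a jump can span a junction, which is
accepted for determinism. Per-node feature vectors aggregate intensity and
motility over the node's voxels plus the radius, z-scored per organelle, and
export as a sparse `(level, i, j)` edge list plus node features — the exact
input a graph autoencoder consumes; the autoencoder itself is out of scope.

## The synthetic generator

`scene_spec()` / `build_scene()` / `render_timelapse()` produce
deterministic timelapses with analytic ground truth: capsule tubes, circular
arcs, ellipsoidal blobs and hexagonal lattice patches, rasterized by signed
distance at voxel centres, moved rigidly (per-frame translation plus
in-plane rotation about a pivot), blurred with a Gaussian PSF, and corrupted
by Poisson photon noise plus Gaussian read noise — the standard fluorescence
acquisition model. Ground truth (instance masks, centreline samples, dense
displacement fields) is computed before noise, so it is exact.

What the generator emulates: tubular and round geometry at organelle scales,
anisotropic sampling, diffraction-scale blur, photon-limited noise, rigid
motion. What it does not: deformation, fission/fusion, photobleaching,
background gradients, out-of-focus light. Validation on these scenes
therefore demonstrates correctness of the algorithms under controlled
conditions, not biological performance on real data.

Two scene-design points deserve honesty. First, the tracking scenes are
fields of round organelles of distinct radii: on a perfectly uniform,
constant-radius tube, every interior marker looks identical and pattern
matching is uninformative *by construction* — no linker can recover motion
larger than half the marker spacing there; the failure is the scene's
degeneracy, not a property the validation should hide. Second, the
segmentation scenes use 0.15 µm pixels so that the criterion's 1–6 voxel
radius range (0.15–0.9 µm) lies inside the filter's default 0.25–1.0 µm
radius range; a 1-voxel tube at much finer sampling falls below the smallest
default scale and is not a regime the defaults claim to cover.

## Problem sizes and numerical choices

Validation runs use 2D frames of roughly 70 × 100 pixels at 0.15 µm, five or
six frames, and small 3D volumes (about 14 × 48 × 56) — the scales at which
every quantity the checks need is measurable. Determinism is absolute: the
analysis pipeline contains no randomness, labels are assigned in scan order,
ties break to the lowest index everywhere, and rerunning a configuration
reproduces outputs byte for byte; the only seed in the system belongs to the
synthetic generator's noise.

Degenerate inputs are defined, not fatal: constant frames enhance to zero
(with an explicit numerical floor so kernel roundoff cannot masquerade as
curvature); empty masks warn and propagate empty outputs; single-frame
stacks run morphology-only; collinear point clouds fall back to
lower-dimensional hulls; a missing frame interval defaults to one second
with a warning, so velocities read per frame.

## Known limitations

The filter under-segments solid structures much larger than the largest
scale (their interior has no curvature), so nucleus-scale objects are out of
scope. The distance-transform radius carries a half-voxel positive bias.
Angular kinematics are noisy near the pivot (angle noise scales with the
inverse lever arm); consumers should aggregate robustly, as the validation
does with a lever-restricted median. Marker appearance features are
uninformative on texture-free objects, bounding tracking accuracy there.
Tracks do not close gaps across more than one frame, and no fission or
fusion events are classified — voxel fates expose the raw material for such
analyses instead.
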