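---
title: "Skeleton-driven registration of plant point clouds over time: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skeleton-driven registration of plant point clouds over time: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

plantreg4d registers 3D point clouds of a single plant scanned on different
days. Plants grow anisotropically, sag, and sprout new organs between scans,
so a single rigid transform — the model behind classical iterative-closest-point
(ICP) registration — cannot align them. The package instead summarizes each
scan as a *semantic curve skeleton*, matches the skeletons across time with a
hidden Markov model, attaches one affine deformation to every skeleton node,
and blends these node transforms to warp the full cloud. This vignette
explains each model, the tunable parameters, and the places where we made a
genuine design choice, in the spirit of a methods section.

All internal computation is in meters. Reported errors are converted to
millimeters for display only.

## Data model

A `point_cloud` is an n x 3 matrix of positions with an optional per-point
class (`stem`/`leaf`) and an optional organ instance id. A `skeleton` is an
undirected acyclic connected graph; each node stores a 3D position, a class
label, an organ id, and (during registration) a 4 x 4 affine transform. The
root is the stem node with the smallest height — the stem base. All graph
invariants are enforced by the `skeleton()` constructor, so every function
downstream may assume a tree.

## Organ segmentation

Each point is classified as stem or leaf by a support vector machine
(RBF kernel, via e1071) on a 36-dimensional feature: the point's coordinates
concatenated with a 33-bin fast point feature histogram (FPFH). The FPFH bins
the three Darboux-frame angles between a point's normal and each radius
neighbor's normal into 11 bins per angle; each point's histogram is then
augmented with a distance-weighted mean of its neighbors' histograms. It is a
rotation-invariant summary of local surface shape that separates the
cylindrical stem surface from the flat leaf blades.

Two choices matter here:

* **Coordinates are centered on the stem base** (the lowest point of the
  cloud) before being used as features. Raw absolute coordinates would not
  transfer between scans of a growing plant; height above the pot, in
  contrast, is informative (stem points occur at all heights, leaf points
  cluster at blade heights) and transfers well.
* **The descriptor radius defaults to 5x the median nearest-neighbor
  spacing** of the cloud, and the DBSCAN radius below to 4x. Tying these
  radii to the sampling resolution makes the defaults density-independent.

Classified leaf points are grouped into leaf instances by DBSCAN
(`min_samples = 10`). Clusters smaller than `min_cluster_size = 50` points
are dissolved and their points reassigned by a majority vote of their
`k_reassign = 5` nearest retained-cluster neighbors; stem points always form
a single instance, since the plant has one stem. The result partitions the
cloud: every point carries exactly one instance id.

## Skeletonization with SOM chains

Each organ is summarized by an *n x 1 chain* of keypoints fitted with a 1-D
self-organizing map (SOM). The chain length is proportional to organ size:
`n = max(1, floor(extent / min_spacing))`, where the extent is measured along
the organ's first principal axis and `min_spacing` defaults to 1 cm.

Training alternates the two classic competitive-learning steps: a randomly
drawn point selects its best matching unit (the nearest chain unit), and
every unit `u` moves toward the point by
`w_u <- w_u + eta * beta(u) * (x - w_u)`, with `beta` a Gaussian over
chain-index distance to the best matching unit. We deliberately use the
standard Kohonen update — each unit moves toward the sample relative to *its
own* weight. The variant in which every unit shares the best-matching unit's
difference vector would translate the chain rigidly and could never spread it
along the organ, so it cannot be what a working implementation does.

Schedules are documented defaults, not tuned values: the learning rate decays
linearly from 0.5 to 0.01 over at most 200 epochs; the neighborhood width
decays linearly from n/2 to 0.5; training stops early when no keypoint moves
more than 0.1 mm in an epoch. The chain is initialized on n evenly spaced
positions along the organ's first principal axis, which makes convergence
fast, keeps the chain ordered monotonically along the organ, and — together
with a caller-supplied seed — makes the fit bit-reproducible.

The skeleton is assembled stem-first: the stem chain is ordered bottom-up,
each leaf chain is oriented so its proximal end is the endpoint nearest the
stem, and one edge connects that proximal node to its nearest stem node. The
nearest-node attachment rule is our choice; the plants considered here have
leaves that attach directly to the stem, so it is the natural one.

## Correspondence estimation as an HMM

Given skeletons S1 (earlier scan) and S2 (later scan), the nodes of S1 in
depth-first order from the stem base form the observation sequence of a
hidden Markov model whose states are the nodes of S2 plus an explicit
*not-matched* state per observation. Matching node i of S1 to node j of S2
has emission cost

    Z = w_d |deg(i) - deg(j)| + w_e ||x_i - x_j|| + w_sem [label(i) != label(j)]

with `w_d = 1, w_e = 10, w_sem = 1`. With coordinates in meters these three
terms have comparable magnitude on decimeter-scale plants, which is why the
package stores meters internally. The transition cost between consecutive
correspondences (i -> j) and (k -> h) compares path structure:

    Gamma = |d_g(i,k) - d_g(j,h)| + w_nbr |nbr(i,k) - nbr(j,h)| + rho_dir

where `d_g` is the geodesic (summed edge length) along the respective
skeleton, `nbr` counts branching nodes (degree > 2) strictly between the two
nodes, `w_nbr` is set automatically to the maximum geodesic distance between
any two S1 nodes, and `rho_dir` adds that same maximum-geodesic penalty when
the displacement vectors `x_i - x_j` and `x_k - x_h` point in opposite
directions (angle greater than pi/2). The minimum-cost state sequence is
found by the Viterbi algorithm in min-sum form — the monotone equivalent of
max-product on negative log probabilities; no normalization is needed because
only the argmin path is used. If two source nodes land on the same target,
the pair with the smaller Euclidean distance keeps the match (one-to-one
resolution).

Conventions we had to fix ourselves:

* **Not-matched states.** The not-matched emission cost defaults to
  `c_nm = w_e * 0.05`, the cost of a 5 cm residual: a node whose best
  candidate is further than that (in combined cost) is better left unmatched.
  For transitions involving a not-matched state, the missing target position
  is substituted by the source node's own position and the target-side
  geodesic/branch terms by the source-side ones, so every term stays defined
  and such transitions contribute zero structural cost.
* **Degenerate directions.** Displacement vectors shorter than 0.1 mm carry
  no usable direction (they are sensor-noise scale), so they never trigger
  `rho_dir`. This matters inside the iterative loop: after a first
  deformation the moved source nodes coincide with their targets to within
  1e-6 m, and the sign of a dot product between two such vectors is
  numerical noise. Without the threshold the maximum-geodesic penalty
  toggles randomly between iterations and the correspondence set can cycle
  forever instead of stabilizing.
* **Ties** in the Viterbi minimization break toward the lower S2 node id,
  and depth-first children are visited in ascending id order, making the
  matching fully deterministic.

## Per-node affine deformation

Every S1 node i receives a 4 x 4 affine transform T_i (12 free parameters:
the 3 x 3 linear part and a translation). The transforms minimize

    E_total = w_corresp E_corresp + w_rot E_rot + w_reg E_reg

with `w_corresp = 100, w_rot = 10, w_reg = 1`:

* `E_corresp` — the distance `||T_i x_i - y_j||` summed over matched pairs,
  with each residual passed through the Cauchy robust loss
  `rho(r) = s^2/2 log(1 + (r/s)^2)` so that wrong correspondences have
  bounded influence;
* `E_rot` — per node, the squared pairwise dot products of the linear part's
  columns plus the squared deviations of their norms from 1; zero exactly on
  orthonormal linear parts. It penalizes shear and keeps deformations
  natural-looking;
* `E_reg` — per skeleton edge (taken once, lower id first), the Frobenius
  norm of `T_i^-1 T_j - I` after homogeneous normalization; it propagates
  constraints to nodes without correspondences and smooths the field.

The optimizer is Gauss-Newton with Levenberg-style damping on the
least-squares form of these energies, from identity initialization, with
analytic Jacobians for every residual block (including the `T_i^-1 T_j`
block, via the matrix-inverse differential). The robust loss enters as
iteratively reweighted least squares. A step is accepted only if the robust
objective decreases, so the energy trace is non-increasing by construction.

Numerical choices:

* **Cauchy scale `s_c = 2 mm`.** The scale should sit at the expected inlier
  residual level, which for SOM-extracted skeletons is one to two
  millimeters. A larger scale (say 10 mm) leaves a 0.3 m outlier
  correspondence enough residual influence to drag its node by more than a
  centimeter against the printed regularizer stiffness; at 2 mm the same
  outlier moves the solution by well under a millimeter while inlier
  residuals, which the correspondence term can drive to near zero, are
  unaffected.
* **Iteration cap 200, step tolerance 1e-8.** The damped iteration
  approaches zero-residual solutions (e.g. a pure rigid motion) through a
  flat, translation-dominated valley and needs roughly 70 accepted steps to
  reach parameter errors below 1e-3 on 25-40-node skeletons; a cap of 50
  returns visibly unconverged transforms. With warm starts inside the outer
  loop, later solves take only a handful of steps.

### A structural property worth knowing

Because `E_corresp` constrains each node at a single point, a uniform growth
of the whole plant by factor s admits two competing explanations: carry the
scale in the linear parts (`T_i = sI`, penalized heavily by `E_rot` since
`(s^2-1)^2` terms appear per node) or absorb it into per-node translations
(`t_i = (s-1) x_i`, penalized only lightly by `E_reg` through neighboring
translation differences of order `(s-1) * edge length`). Under the printed
energies the translation field is cheaper by orders of magnitude, so the
recovered linear parts stay near rotations and *uniform scale is expressed in
the translation field, not in the linear parts' determinants*. The warped
cloud is essentially unaffected — the blended translation field interpolates
the growth — but anyone reading the per-node linear parts as "growth tensors"
should be aware of this. A regularizer that predicts each neighbor's position
from the node's full transform (as in embedded-deformation approaches for
meshes) would instead force the scale into the linear parts; that is a
different energy than the one this package implements, and we kept the
printed form. The test suite contains one deliberately strict check of
determinant-based scale recovery that documents this property by failing.

## Warping and temporal interpolation

To warp the full cloud, each point p finds its nearest skeleton edge (by
point-to-segment distance, ties to the lower edge index) and is mapped to
`alpha_a T_a p + alpha_b T_b p`, where the weights are the complementary
normalized projection parameters of p along that edge, clamped to [0, 1] —
points beyond an endpoint (leaf tips, stem base) take that endpoint's
transform fully. The two weights always sum to 1, so applying the same rigid
transform at every node reproduces that rigid transform exactly.

For interpolation at a fraction t of the inter-scan interval, each transform
is factored `T = T_s T_R T_t` by polar decomposition (symmetric
positive-definite scale/shear times rotation, translation isolated;
reflections are rejected). `T_s` and `T_t` interpolate linearly from the
identity, `T_R` by quaternion slerp, and the three factors are recomposed.
`T(0)` is the identity and `T(1)` reproduces `T` to machine precision.
Interpolation predicts neither physiology nor mechanics — it is a smooth
path between two registered states, useful for densifying a time series or
animating growth, and its error against a truly intermediate scan is bounded
only empirically (see the acceptance script).

## The outer registration loop

`register_pair()` alternates correspondence estimation and deformation
fitting. In iteration k the source nodes are moved by the current transforms
before matching, so correspondences missed because of a large initial
distance can be captured; the structural (geodesic and branch-count) terms,
however, are always taken from the original source skeleton, whose topology
is the plant's own and does not change with a deformation estimate. The loop
stops when the correspondence set is unchanged between successive iterations
(empty symmetric difference) or after `max_outer_iter = 10` iterations, and
each deformation solve warm-starts from the previous one. On the synthetic
fixtures the set stabilizes within one to three iterations.

When input clouds carry per-point labels (as the synthetic generator's
clouds do), segmentation uses them directly by default
(`pipeline$use_labels`); otherwise a trained classifier must be supplied.
This separates the evaluation of registration from the evaluation of
classification, which the package measures independently.

## Phenotypic traits

* **Organ length**: sum of the skeleton edge lengths internal to the organ's
  chain.
* **Stem diameter**: stem points are assigned to their nearest stem node;
  per node, the local main axis comes from an SVD of the node's points
  pooled with its chain neighbors' points (pooling keeps the axis estimate
  well-conditioned when one node's slice is shorter than the stem is wide),
  and the diameter is twice the mean over nodes of the mean point-to-axis
  distance. Nodes are weighted equally regardless of how many points they
  hold.
* **Leaf area**: per node of the organ, the assigned points are projected
  onto the node's dominant SVD plane and the 2D convex hull area is taken;
  the organ's area is the sum over nodes. Adjacent per-node hulls can
  overlap slightly near node boundaries, so the sum is a mild
  overestimate; we keep the per-node form because it tolerates curved
  blades that a single global hull would misrepresent far more.
* **Tracking**: persistent organ identities are propagated through the
  correspondence chain — an organ inherits the identity holding a strict
  majority (> 50%) of its matched nodes; organs without such a predecessor
  are emergence events and receive fresh, never-reused ids.

## The synthetic generator

Every quantitative statement the package's tests make is made on clouds from
`generate_plant()`/`grow_plant()`, so it matters what they do and do not
emulate. They emulate: a potted seedling with a smoothly bowed stem (tube
surface), 2-8 planar elliptical leaves attached at set heights with azimuth
and droop, per-point Gaussian sensor noise of 0.5 mm (a plausible figure for
a precision arm-mounted laser scanner), anisotropic growth (global scaling
about the stem base at 1.15 between scans, per-leaf elongation 1.2 along the
leaf axis, droop increasing by 10 degrees as leaves sag), and topology change
through newly inserted leaves. Two presets set the morphology scale: a
tomato-like plant (five small leaflets, 12 cm) and a maize-like plant (three
long leaves, 22 cm). The growth transforms applied to each skeleton node are
returned exactly, as is the node correspondence, which is what enables
parameter-recovery and closed-loop tests.

They do **not** emulate: self-occlusion and view-dependent sampling holes,
curved or lobed leaf blades, petioles and compound leaves, non-rigid motion
between scans that is not growth (wind), background clutter, or outlier
returns. Passing tests therefore demonstrate the method's correctness and
its behavior under controlled growth and noise — not performance on raw
field scans.

Problem sizes used throughout the checks: clouds of roughly 7,000-10,000
points and skeletons of 25-55 nodes per scan — enough that every stage runs
at realistic density while a full end-to-end run stays in the seconds range.

## Known limitations

* The stem must be a single chain; multi-stem or heavily branched woody
  architectures are out of scope.
* Matching assumes the earlier scan's organs persist into the later scan;
  organ loss is expressed only through not-matched states.
* Determinant-based readouts of growth from the per-node linear parts are
  uninformative under the printed energies (see above); use the trait
  series, which measure geometry directly.
* The ICP baseline is intentionally plain (point-to-point, median-based
  outlier rejection) — it is a reference point, not a competitive rigid
  registration.
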