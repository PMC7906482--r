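# plantreg4d

Non-rigid, skeleton-driven registration of time-series 3D point clouds of
individual plants ("4D registration"), with organ-level trait tracking.

Plant phenotyping increasingly relies on 3D scans of plants taken day after
day. Comparing those scans requires knowing which part of today's cloud
corresponds to which part of yesterday's — a data-association problem that
rigid registration cannot solve, because plants grow anisotropically, sag,
and sprout new organs between scans. plantreg4d is for researchers and
engineers building automated phenotyping pipelines from laser-scanner or
depth-camera data of single plants (seedling scale): it registers consecutive
scans despite growth and topology change, and turns the resulting
correspondences into per-organ trait time series (leaf length and area, stem
length and diameter) with emergence detection.

## Method

Each scan is reduced to a **semantic curve skeleton**: points are classified
stem/leaf by an SVM on fast point feature histograms (FPFH), clustered into
organ instances by DBSCAN, and each organ is summarized by a 1-D
self-organizing-map chain of keypoints (at least 1 cm apart), connected into
a rooted tree.

Correspondences between two skeletons S1, S2 are the hidden states of an
**HMM** solved by the Viterbi algorithm. Matching nodes i and j costs

    Z(c_ij) = w_d |deg(n_i) − deg(n_j)| + w_e ‖x_i − x_j‖ + w_sem ρ_sem ,

and transitioning between correspondences c_ij, c_kh costs

    Γ = |d_g(n_i,n_k) − d_g(n_j,n_h)| + w_nbr |nbr(n_i,n_k) − nbr(n_j,n_h)| + ρ_dir ,

with geodesic distances d_g and branch counts nbr along each skeleton, plus
an explicit not-matched state per node for new or vanished organs
(w_d = 1, w_e = 10, w_sem = 1).

Deformation is modeled by one **affine transform T_i per skeleton node**
(12 parameters each), estimated by damped Gauss-Newton on

    E_total = w_corresp E_corresp + w_rot E_rot + w_reg E_reg ,

where E_corresp = Σ ρ_cauchy(‖T_i x_i − y_j‖) pulls matched nodes together
under a Cauchy robust kernel, E_rot keeps each linear part near a rotation,
and E_reg = Σ_edges ‖T_i⁻¹T_j − I‖_F couples neighboring transforms and
carries unmatched nodes (w_corresp = 100, w_rot = 10, w_reg = 1). Matching
and deformation alternate — re-matching with the moved source nodes — until
the correspondence set stops changing. The full cloud is warped by blending
the two nearest node transforms of each point along its nearest skeleton
edge, and deformations can be interpolated at intermediate times via polar
decomposition (lerp on scale/shear and translation, slerp on rotation).

A deterministic synthetic-plant generator (curved stem tube, drooped
elliptical leaves, 0.5 mm sensor noise, known growth transforms, emerging
leaves) makes the whole pipeline testable end to end without any downloads.

## Worked example

Register two synthetic scans of a growing tomato-like seedling (the second
scan is scaled 1.15x, its leaves elongated and drooped, with one new leaf):

```r
library(plantreg4d)

parent <- generate_plant(plant_spec("tomato", seed = 3))
child  <- grow_plant(parent, growth_spec(seed = 4))
parent$cloud
#> point_cloud: 7500 points [leaf: 4500, stem: 3000], 6 organ instance(s)

reg <- register_pair(parent$cloud, child$cloud, seed = 7)
reg
#> registration_result: 25 -> 33 skeleton nodes, 23 matched,
#>   e_reg 0.83 mm (sd 0.58, max 5.62), 2 outer iteration(s)

icp <- icp_baseline(parent$cloud, child$cloud)
round(1000 * c(nonrigid = reg$e_reg$mean, rigid_icp = icp$e_reg$mean), 2)
#>  nonrigid rigid_icp
#>      0.83      2.12
```

The mean nearest-neighbor error of the warped cloud (e_reg) is 0.83 mm —
about the sensor-noise floor of the synthetic scans — versus 2.12 mm for the
rigid ICP baseline, which cannot express growth. Organ-level association is
exact and the warp sends almost every point into the correct organ:

```r
m1 <- persistent_organ_map(reg$S1, reg$seg1, parent$cloud)
m2 <- persistent_organ_map(reg$S2, reg$seg2, child$cloud)
correspondence_accuracy(reg$correspondences, m1, m2)
#> [1] 1
instance_transfer_accuracy(reg$deformed, child$cloud)
#> [1] 0.997
```

Traits are tracked over the (here, two-scan) series; the inserted leaf shows
up as an emergence event:

```r
ts <- track_traits(
  list(list(cloud = parent$cloud, skeleton = parent$skeleton),
       list(cloud = child$cloud,  skeleton = child$skeleton)),
  list(child$correspondences))
ts
#> trait_series: 7 organ(s), 2 time point(s), 1 emergence event(s)
head(subset(ts$traits, trait == "length"), 4)
#>   time organ class  trait     value
#> 1    1     1  stem length 0.1204106
#> 3    1     2  leaf length 0.0400000
#> 5    1     3  leaf length 0.0400000
#> 7    1     4  leaf length 0.0350000
```

A thin command-line front end over the same functions ships in
`inst/cli/plantreg4d.R` (subcommands `synth`, `train`, `segment`,
`skeletonize`, `match`, `deform`, `warp`, `register`, `traits`).

## Package layout

- `R/` — point-cloud and skeleton containers and I/O; FPFH features + SVM
  classification; DBSCAN organ clustering; SOM skeletonization; HMM/Viterbi
  correspondence; Gauss-Newton deformation; cloud warping and interpolation;
  the registration pipeline and metrics; trait computation and tracking; the
  synthetic generator.
- `src/` — Rcpp kernels: neighbor search, normals, FPFH, SOM training,
  nearest-neighbor queries.
- `vignettes/plant-registration-methods.Rmd` — models, parameters, numerical
  choices, and known limitations.
- `tests/testthat/` — unit and property tests with independent brute-force
  oracles, plus the end-to-end acceptance suite.
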