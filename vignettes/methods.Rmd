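---
title: "Cross-modality atlas mapping with image varifolds: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modality atlas mapping with image varifolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(varifoldmap)
```

# The model

## Image varifolds

Both a tissue-scale atlas section and a molecular-scale dataset are modelled
as *image varifolds*: measures over `R^2 x F` for a finite feature space
`F`,

$$\mu = \sum_{i} w_i\,\delta_{x_i} \otimes p_i,$$

with positions in micrometres, nonnegative masses $w_i$ (total mRNA, total
cells, or 1 per foreground pixel for an atlas) and per-location probability
distributions $p_i$ over features. Two carriers are implemented:

* **particles** (`particle_varifold`): positions, weights, distributions —
  the universal form; built from point tables at native resolution (one
  Dirac per detection) or by binning into $h \times h$ cells
  (count-weighted centroids, so the first spatial moment is preserved);
* **meshes** (`mesh_varifold`): a triangulation of a regular grid covering
  the data support, each positively oriented simplex carrying a constant
  density $\alpha_j$ (mass per $\mu m^2$) and a distribution $p_j$. The
  grid squares are split along a fixed diagonal — for a regular grid this
  *is* a Delaunay triangulation (all four cell corners are cocircular, so
  either diagonal is Delaunay-valid), and the fixed choice makes the
  construction deterministic. Simplices containing no data point are
  pruned unless every edge-neighbour is a retained occupied simplex
  (interior hole fill); only the largest edge-connected component of
  occupied simplices survives, so detached fragments are dropped.

## Actions of diffeomorphisms

A deformation $\varphi$ acts on particles by
$\varphi\cdot\mu = \sum_i |D\varphi|_{x_i} w_i \delta_{\varphi(x_i)}\otimes p_i$:
the Jacobian factor preserves the *spatial density* of the object. On meshes
the vertices move and the weight of a simplex becomes
$\alpha_j\,|\gamma_j(\varphi(x))|$, its density times its deformed area —
the deformed-area approximation of $|D\varphi|_{m_j}|\gamma_j|$. A deformed
simplex with non-positive area signals fold-over and raises an error, which
in practice means the deformation was too large for the chosen kernel.

## Deformations

Diffeomorphisms are generated by integrating a time-discretized RKHS
velocity field $v_t(x)=\sum_k K_V(x,q_k(t))\,a_k(t)$ with a Gaussian kernel
of bandwidth $\sigma_V$, forward-Euler with $T$ steps, control points
advected by their own flow. The Jacobian determinant is co-integrated from
analytic kernel derivatives, so it is the exact derivative of the discrete
map (finite differences of mapped positions agree to the differencing
error). The inverse map integrates the negated velocities in reversed time
order against the forward control trajectory; its consistency error decays
like $1/T$ and, for the default $T = 10$ and displacements small relative to
$\sigma_V$, round trips close to within $10^{-3}\sigma_V$. Momenta are free
per-timestep variables; the kinetic-energy penalty
$\tfrac12\int\|v_t\|_V^2\,dt$ drives solutions toward geodesics without
imposing the momentum-shooting parameterization.

## The latent feature law

Each atlas label $\ell$ receives an unnormalized distribution $\pi_\ell$
over target features; the atlas varifold is carried into the target feature
space by the mixture $w_i' p_i' = w_i \sum_\ell p_i(\ell)\,\pi_\ell$. Row
masses of $\pi$ are target mass per unit atlas mass, so the law encodes
predicted density as well as composition. At fixed geometry the data term is
a convex quadratic in $\pi$; with the discrete feature kernel its Hessian is
block-diagonal across features with a common block $B^\top K_1 B$,
$B_{i\ell} = w_i p_i(\ell)$ (deformed weights). The program is solved

* in closed form / by Lawson–Hanson active-set NNLS when only nonnegativity
  binds (the per-feature problems decouple), and
* by an operator-splitting (ADMM) solver with absolute/relative tolerances
  $10^{-8}$, followed by an active-set KKT polish, when density-bound rows
  $w^{min} \le w_i' \le w^{max}$ are active. Infeasible bounds are reported
  with the violating rows.

The greedy approximation collapses each atlas distribution to its dominant
label before assembly; for atlases whose locations are interior to a single
region (delta distributions) it is exact, and the two assemblies provably
coincide.

# The optimizers

Registration pre-aligns with a rigid+scale transform (scale from the
template/target support-area ratio, rotation and translation by quasi-Newton
descent of the varifold normed difference, translation initialized at the
centroid offset; across feature spaces the rigid stage compares total-mass
measures). The template is represented as a mesh (particle templates are
meshed first) and two schemes minimize the total cost:

* **alternating**: initialize the law uniform on the target's mass scale
  (see below), then alternate L-BFGS descent over the momenta at fixed law
  (phase A) with the exact quadratic program at fixed flow (phase B). An
  initial program solve (phase B0) runs before the first LDDMM phase.
  Neither phase can increase the cost (asserted at tolerance $10^{-6}$;
  the B-phase assertion applies when the incoming law is feasible for the
  bounds).
* **joint**: L-BFGS over momenta and law simultaneously, positivity by a
  softplus reparameterization, with a KL-to-uniform penalty of weight
  `lambda_kl` (default 1) riding on the data term's scale.

Gradients are analytic end to end: the varifold-norm gradients with respect
to simplex centers and areas are backpropagated through the Euler flow using
cached kernel matrices; a finite-difference agreement test at $10^{-6}$
guards the implementation.

## Design choices worth knowing about

* **Mass-calibrated uniform initialization.** The law starts at
  $\pi_\ell(f) = m/|F|$ with $m$ the target/template total-mass ratio. In
  the constant-density atlas-to-atlas setting $m = 1$ and this is exactly
  the classical $1/|F|$ initialization; in cross-modality problems it
  prevents the first geometric phase from bending the template to
  compensate a global mass imbalance that the law will absorb anyway
  (without it, first-phase distortions of 70 µm and more were measured on
  problems whose true deformations were recoverable to 17 µm).
* **Initial program phase (B0).** Solving the law once at the pre-aligned
  geometry gives the first LDDMM phase region-to-feature structure to work
  with; with a featureless uniform law the geometry phase only sees the
  outer boundary and readily walks into local minima.
* **Data-term weight.** The relative weighting of kinetic energy and data
  attachment is not canonical: the data term scales with squared mass while
  the kinetic term is mass-free. The default `data_weight = "auto"` sets
  $100/\bar w_T^2$ (target masses counted in units of a tenth of the mean
  per-particle mass), making the balance independent of the target's count
  scale. Recovery error was flat across two orders of magnitude around this
  default; `data_weight = 1` reproduces the raw convention.
* **Coarse-to-fine schedule.** The norm is a sum of Gaussian scales; the
  default schedule runs (400, 200, 100) µm, then (100, 50) µm, warm-starting
  momenta and law. A final fine stage sharpens region boundaries, which is
  what the feature law is most sensitive to.
* **Density bounds.** The alternating scheme's default bound mode
  (`"density"`) converts the target's 5th-percentile-to-maximum per-particle
  *density* range into per-simplex bounds on $w'$ (scaled by deformed
  simplex area), so the prior is meaningful even when template simplices
  and target particles have different support sizes. Literal bounds on
  $w'$, constant-density bounds ($w^{min}=w^{max}=1$, the atlas-to-atlas
  convention), and no bounds are also available.
* **Numerics.** Nearest-rank percentiles; natural logarithms in KL and
  entropy; point-in-simplex ties on shared edges go to the lowest simplex
  index; nearest-particle ties to the lowest particle index; region
  membership at exactly half mass goes to the lowest label index; zero-mass
  locations get a uniform distribution placeholder and contribute nothing.

# The synthetic generator

`synthetic_scenario()` emulates the model's generative assumption: a
polygonal partition (by default the Voronoi cells of 5 seeds in a
600 × 450 µm rectangle — Voronoi cells of a rectangle are a polygonal
partition), a ground-truth law $\pi^*$ over 8 features with row masses near
1, and per-region detection intensities (default 0.25 /µm², i.e. 10–16
thousand expected detections per region — the regime in which the law is
recoverable to a few percent). Detections are a homogeneous Poisson process
per region with features i.i.d. from the normalized law row, so the law the
estimation should recover is `ground_truth_law()` = intensity × π*.

When a ground-truth warp is requested, the generator preserves the model's
homogeneity assumption **on the observed tissue**: the process is sampled
with atlas-space intensity proportional to $|D\varphi|$ (exact Poisson
thinning) and positions are then transported, so the warped regions carry a
homogeneous process of the same density law. Transporting a
uniformly-sampled process instead would make observed density proportional
to $1/|D\varphi|$ within each region — data the homogeneous model cannot
represent, biasing recovered law rows by up to their own mass under strong
compression. Ground-truth warps draw seeded momenta on a coarse (150 µm)
control grid, scaled to a requested peak displacement (default 80 µm — a
section-to-section distortion scale well inside the diffeomorphic range of
the 100 µm deformation kernel), with positivity of $|D\varphi|$ verified on
a dense probe grid.

What the generator does *not* emulate: segmentation errors, transcript
dropout, partial detection efficiency, spatially graded expression within a
region, and 3D section obliqueness. Passing recovery tests on these phantoms
therefore demonstrates correctness of the estimation machinery under the
model's own assumptions, not robustness to real-tissue violations of them.

# Test and report problem sizes

The recovery studies register 216-simplex templates (50 µm mesh) onto ~430
binned target particles (25 µm cells, ~64k detections), with 216 control
points, $T = 10$ timesteps, the (400/200/100, 100/50, 50) µm schedule and
(3, 2, 2) outer alternations of 60 inner iterations — a registration then
takes seconds on one core, and mean probe-point recovery error lands near
15 µm against ground-truth warps of 80 µm peak displacement. The
variance-reduction study uses a coarser 60 µm mesh, 50 µm target bins and a
two-stage schedule. These sizes are the package's chosen study conditions;
the same code runs unchanged at finer resolutions.

# Known limitations

* 2D sections only; no multi-section stacks or 3D volumes.
* The homogeneity assumption is the model: spatially graded expression
  within a region is absorbed into the law's average (the empirical
  pullback distributions, which drop the assumption, are the tool for
  checking where it holds).
* Interior deformation of a homogeneous region is unidentifiable from the
  data term; the kinetic regularizer interpolates it smoothly, which is
  usually — not always — close to a smooth ground truth.
* The inverse flow is the reversed-time integration of the forward field,
  accurate to $O(1/T)$; applications needing exact inverses should raise
  `n_steps`.
* Feature kernels other than the discrete identity (e.g. similarity between
  genes) are not implemented.
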