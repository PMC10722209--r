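---
title: "Voxel-based atrial wall thickness: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-based atrial wall thickness: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atriawall)
```

## The problem

Atrial wall thickness (AWT) is a structural substrate of atrial
fibrillation: localized re-entrant drivers preferentially anchor where the
wall is thick and heterogeneous (in the right atrium, at the crista
terminalis and pectinate-muscle junctions) or, in the left atrium, where it
is locally thin. Quantifying AWT from high-resolution contrast-enhanced MRI
requires a definition of "thickness" that is well posed on a curved,
branching, voxelized wall — a simple nearest-surface distance is biased low
at oblique and curved walls, and a pure Laplace/field-line length computed
voxel-by-voxel is noisy.

`atriawall` implements the coupled-PDE definition of thickness on a binary
tissue segmentation, together with everything around it: surface
separation, chamber delineation, local-variance mapping, and the cohort
statistics used to compare driver and non-driver chambers and regions.
Because suitable imaging data cannot be redistributed, the package also
ships analytic phantom generators with known ground truth; every stage is
validated against them.

## The thickness model

Write $\Omega$ for the set of wall voxels, $\partial\Omega_0$ for the
endocardial (cavity-facing) surface and $\partial\Omega_1$ for the
epicardial surface. Three fields are solved:

1. **Harmonic potential.** $\nabla^2 u = 0$ on $\Omega$, $u = 0$ on
   $\partial\Omega_0$, $u = 1$ on $\partial\Omega_1$, zero flux on any
   wall boundary that is neither surface. $u$ interpolates smoothly across
   the wall and its normalized gradient $T = \nabla u / \lVert\nabla
   u\rVert$ defines a non-crossing family of trajectories connecting the
   two surfaces.
2. **Trajectory lengths.** Two first-order transport equations are solved
   along $T$: $\nabla L_0 \cdot T = 1$ with $L_0 = 0$ on the endocardium,
   and $-\nabla L_1 \cdot T = 1$ with $L_1 = 0$ on the epicardium. $L_0$
   and $L_1$ are the arc lengths from each voxel to the two surfaces along
   its trajectory.
3. **Thickness.** $W = L_0 + L_1$, in mm, at every wall voxel. Along any
   single trajectory $W$ is constant — the defining property of the
   trajectory-pair construction, and the reason the field is smooth where
   nearest-distance measures are noisy.

Two baselines are provided: `thickness_laplace_streamline()` integrates the
same trajectories explicitly (fixed-step RK2 midpoint stepping with
trilinear interpolation, step = half the smallest voxel; the exit point is
refined by bisection) and doubles as a brute-force oracle for the PDE
solver; `thickness_nearest_boundary()` sums exact Euclidean distance
transforms to the two surface voxel sets, a fast sanity baseline that is
deliberately biased low at curved walls.

## Where exactly is the surface? (boundary conventions)

On a voxel grid the wall surface is only known to within half a voxel, and
the choice of where Dirichlet data live dominates the accuracy of every
derived quantity. `atriawall` places both Dirichlet surfaces at the
tissue/cavity and tissue/exterior voxel *faces*:

* the Laplace solve uses reflection ghosts ($u_{\text{ghost}} = -u$ across
  an endocardial face, $2 - u$ across an epicardial face), equivalent to a
  Dirichlet value at the face midpoint with doubled stencil weight. On a
  slab of $K$ voxels this gives the exact profile $u_k = (k + 1/2)/K$;
* the transport solves apply a half-voxel correction at exit faces (the
  upwind value behind an exit face is $-s/2$ for axis spacing $s$), which
  makes $W$ exact on a slab and unbiased on shells.

The alternative — pinning $u$ and $L$ to the boundary *voxel centres* —
shortens every wall by one voxel (a 4 mm slab at 0.5 mm spacing reads
3.5 mm) and was rejected for that reason. A consequence of the face
convention is that surface voxels carry small nonzero values ($u$ about
half a voxel-step from 0/1, $L_0$ about half a voxel) rather than exact
zeros; tests assert the face-convention values.

What no convention can remove is the half-voxel *jitter* of a binary
surface. Pointwise, the potential of a 0.5 mm-sampled spherical shell
deviates from the radial closed form by up to ~0.04 in the first voxel
layer, while its radial profile (0.25 mm bin means) agrees to better than
0.015; streamline lengths similarly scatter within about a voxel around an
unbiased mean. Accuracy statements in the tests distinguish the two
regimes deliberately.

## Surface separation and chamber delineation

**Multi-planar hull.** The epicardium and endocardium are separated by
closing the wall with a convex hull computed slice-wise: in every slice
perpendicular to each of the three principal axes, the 2D convex hull of
the tissue is filled (exact integer half-plane tests on voxel centres), and
the three filled stacks are intersected. This closure caps openings such as
vein ostia, contains the tissue, and is *contained in* the full 3D convex
hull — it is the tightest of the three, which keeps spurious "cavity" to a
minimum. The exact 3D hull is available as an option
(`method = "hull3d"`, integer facet enumeration; intended for moderate
volumes). Space is then classified by flood fill: the exterior is the
non-hull component touching the grid border, the cavity is all remaining
non-tissue inside the hull; tissue voxels 6-adjacent to cavity are
endocardial, to exterior epicardial, to both `transmural_contact` (such
voxels receive both face conditions — on a one-voxel wall the two surfaces
genuinely coincide and the tie is resolved by physics rather than fiat,
though the voxels stay flagged in the diagnostics).

**Chambers.** The right/left chamber split solves the same Laplace
operator on the full tissue domain with $v$ pinned to 0/1 on two
user-supplied seed sets (the data do not define where "RA ends and LA
begins"; making the seeds explicit makes the step testable). Voxels with
$v < 0.5$ are labelled chamber 1, $v \ge 0.5$ chamber 2; the tie rule makes
the labelling exactly antisymmetric under a seed swap. Delineation is done
on the tissue domain (not the cavity), matching the phantom ground truth.

## Numerics

* 7-point finite differences with anisotropic $1/s^2$ weights; red-black
  Gauss–Seidel with over-relaxation ($\omega = 1.7$ for the thin-wall
  solve, $1.9$ for the long-range chamber solve; a Jacobi mode exists for
  sweep-order checks and forces $\omega = 1$, since over-relaxed Jacobi
  diverges). Convergence is declared when the largest update in a sweep
  falls below `tol` (default $10^{-6}$); the default sweep budget is
  $10 N^{2/3}$ for $N$ active voxels. Non-convergence is an error carrying
  the achieved residual, never a silent result.
* The transport equations use first-order upwinding — the upwind neighbour
  per axis is chosen by the sign of the corresponding component of $T$ —
  with Gauss–Seidel sweeps alternating over the eight axis orderings;
  convergence is typically reached in tens of sweeps.
* Gradients use central differences with ghost values at Dirichlet faces
  and one-sided differences at zero-flux boundaries. Voxels with
  $\lVert\nabla u\rVert < 10^{-8}$ are flagged degenerate and filled by
  6-neighbour averaging after the transport solve (harmonic potentials
  vanish only at discretization artifacts).
* The variance map is the population variance over the wall voxels within
  a 3-pixel index-space Euclidean radius (the voxel itself included,
  neighbourhoods clipped to the wall). The radius is interpreted in pixels
  even under anisotropic spacing, as is conventional for this map; an
  mm-radius mode exists but is off by default. The computation is two-pass
  and returns exactly zero on locally constant fields.
* Thresholds after interpolation sit at exactly 0.5 with ties mapping to
  tissue; connectivity defaults to 6 everywhere (conservative: no diagonal
  leaks through thin walls). All distances are in mm; voxel centres sit at
  `index * spacing + spacing/2`. The pipeline has no stochastic stage —
  reruns are bit-identical.

## Statistics

Summaries report mean, *population* standard deviation (the voxel set is
the entire population of the map), median and type-7 quartiles. Two-group
comparisons use Welch's two-tailed t-test (the F-tests routinely reject
variance equality, making the pooled test unsafe; a pooled option exists)
and a two-tailed variance-ratio F-test with the larger sample variance in
the numerator, both on sample ($n-1$) variances. Voxel-level tests treat
voxels as independent observations; with millions of spatially correlated
voxels the p-values are optimistic, which is documented rather than
corrected — an optional every-k-th-voxel subsampling (`subsample`) is the
provided mitigation. No multiple-testing correction is applied. Cohort
pooling across hearts is volume-weighted: pooled mean
$\sum w_i m_i / \sum w_i$ and pooled variance
$\sum w_i (s_i^2 + m_i^2)/\sum w_i - m^2$ with tissue volumes as weights —
the mixture moments of the per-heart distributions; with equal weights and
equal voxel counts this reproduces voxel-pooled statistics exactly. How a
published cohort mean was pooled is rarely stated; volume weighting is the
package's declared convention.

## The phantom generators

The generators emulate the geometric regime of high-resolution ex vivo
atrial imaging — thin curved shells 2–8 mm thick at sub-millimetre
isotropic spacing — with analytic ground truth:

* `make_slab()`: constant-thickness plate; the exactness benchmark.
* `make_spherical_shell()`: constant truth $r_{out} - r_{in}$; the radial
  closed form of $u$ is known. An optional seed jitters the centre by up
  to a quarter voxel to de-align the shell from the grid.
* `make_ellipsoidal_shell()`: smoothly varying truth computed by an
  independent geometric oracle (nearest distance to each surface by dense
  quasi-uniform point sampling).
* `make_ridged_shell()`: a crista-terminalis analogue producing the
  bimodal thickness histogram with a secondary thick peak. The defaults
  are sized like an adult atrium (inner radius 30 mm, 4 mm base wall,
  4 mm extra ridge depth, plateau covering 15% of the surface, cosine
  flank over a further 0.20 of $|z|/r$). Two design points matter: the
  ridge must be *wider than it is deep* for any transmural measure to read
  its full depth (on a 10 mm shell the same surface fraction degenerates
  into a thin deep fin), and it must merge *smoothly* into the wall — a
  sharp-edged trench exposes side walls that trajectories correctly read
  as thin. Flank voxels are flagged as transition voxels and their ground
  truth is the perpendicular wall width (radial depth times the cosine of
  the local slope), the standard geometric thickness of a slanted wall.
* `make_two_chamber()`: two fused shells sharing a planar septum band,
  with per-voxel chamber truth and polar seed patches.

What the phantoms do **not** emulate: real segmentation noise, fibrotic
texture, pectinate branching, appendage anatomy, vein ostia of realistic
shape, and partial-volume effects at tissue interfaces. Passing the
phantom suite therefore demonstrates correctness of the geometry and the
solvers under the stated voxelization limits, not robustness to
segmentation error; the preprocessing knobs (`smooth_mask()`,
`resample_mask()`, largest-component cleanup) exist for real data but
default to off/identity so that tests measure the solvers, not the
smoothing.

Problem sizes used by the test-suite and the acceptance script: shells at
0.5 mm spacing on 64³ grids (about 58 000 wall voxels), the ridged shell on
a 142³ grid (about 460 000 wall voxels), the two-chamber phantom on
106×62×62 (about 112 000 tissue voxels) — the scale at which the complete
suite runs in well under a minute on one core while keeping walls at least
8 voxels across.

## Known limitations

* Thickness inherits the half-voxel surface quantisation of the input
  mask; at 0.5 mm spacing individual voxels carry ±0.5 mm of surface
  jitter even though means are unbiased. Finer acquisition, not
  post-processing, is the remedy.
* First-order upwinding makes the coupled-PDE field slightly diffusive:
  on the 10/14 mm shell the mean reads about 3.4% low. The streamline
  estimator is unbiased and serves as the cross-check.
* Near steep thickness gradients (ridge flanks), trajectory thickness is
  intermediate between the thick and thin regimes; "thickness" itself is
  ill-defined at a cliff. The ridged phantom's flank is excluded from
  mode assertions for exactly this reason.
* The multiplanar hull caps concavities slice-wise; for strongly
  non-convex anatomy (deep atrioventricular grooves) the resulting
  "cavity" can include space outside the anatomical chamber. Region
  masks and the chamber split mitigate this in practice.
* Welch/F tests on voxels ignore spatial autocorrelation (see above).
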