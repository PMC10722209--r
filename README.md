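# atriawall

Voxel-based 3D atrial wall thickness (AWT) mapping from binary tissue
segmentations, for cardiac image analysts studying the structural
substrates of atrial fibrillation. Given a segmented atrial wall (NIfTI),
the package separates the epicardial and endocardial surfaces with a
multi-planar convex-hull closure, delineates the two chambers by a Laplace
potential between seed patches, estimates per-voxel wall thickness by the
coupled-PDE (trajectory-pair) method, maps local thickness variance, and
computes the cohort summaries and two-sample t/F comparisons used to
contrast driver and non-driver chambers and regions. Analytic phantom
generators with known ground truth make every stage testable without
imaging data.

## The method

On the wall domain $\Omega$ with endocardial surface $\partial\Omega_0$
and epicardial surface $\partial\Omega_1$:

1. solve $\nabla^2 u = 0$ with $u=0$ on $\partial\Omega_0$, $u=1$ on
   $\partial\Omega_1$ (zero flux elsewhere), and set
   $T = \nabla u/\lVert\nabla u\rVert$;
2. solve the transport pair $\nabla L_0\cdot T = 1$ ($L_0=0$ on the
   endocardium) and $-\nabla L_1\cdot T = 1$ ($L_1=0$ on the epicardium)
   by first-order upwinding;
3. thickness is $W = L_0 + L_1$ (mm) at every wall voxel; $W$ is constant
   along each trajectory of $T$.

Two baselines are included: explicit streamline integration of the same
trajectories (also the brute-force oracle for the PDE solver) and a
nearest-boundary distance-transform estimator. The local AWT variance map
is the population variance of $W$ within a 3-pixel-radius neighbourhood.
Dirichlet data are imposed at the tissue/background voxel *faces*
(reflection ghosts), which makes $W$ exact on a slab phantom and unbiased
on shells; see the methods vignette
(`vignettes/wall-thickness-methods.Rmd`) for conventions, numerics and
limitations.

## Worked example

```r
library(atriawall)

# a 4 mm-thick spherical shell, 0.5 mm isotropic voxels
ph <- make_spherical_shell(r_in = 10, r_out = 14, spacing = 0.5, dims = 64)
b  <- label_boundaries(ph$tissue)   # hull closure + surface separation
b
#> <awt_boundaries> 58544 tissue voxels: 4344 endocardial, 7992 epicardial, 0 transmural-contact
#>   cavity 4.19 cm^3, tissue 7.32 cm^3

th <- thickness_coupled_pde(b)
th
#> <awt_thickness> method 'coupled_pde': 58544 wall voxels, mean 3.87 mm, sd 0.08 mm

summarize_thickness(th, cavity_volume_cm3 = b$diagnostics$cavity_volume_cm3)
#>   n_voxels mean_mm std_mm median_mm q25_mm q75_mm tissue_volume_cm3 cavity_volume_cm3
#> 1    58544    3.87  0.077      3.86   3.82   3.91              7.32              4.19
```

The true thickness is 4.0 mm everywhere; the estimate is 3.87 ± 0.08 mm
(the ~3% low bias is the first-order upwind diffusion of the PDE solver;
the streamline baseline is unbiased). The cavity volume matches the inner
ball ($\tfrac43\pi\,10^3 = 4.19$ cm³) and the tissue volume the shell
($\tfrac43\pi(14^3-10^3) = 7.31$ cm³).

Cohort-level pooling of the bundled per-heart summary table (seven ex vivo
human atria) reproduces the published right-atrial mean:

```r
tab <- human_awt_cohort()
ra  <- tab[tab$atrium == "RA", ]
pooled_cohort_summary(ra$mean_mm, ra$std_mm, ra$tissue_cm3)
#>   mean_mm std_mm weight_total
#> 1    4.77   2.51          213
```

i.e. RA AWT 4.8 ± 2.5 mm after volume-weighted pooling. The full pipeline
(`run_pipeline()`) runs preprocess → hull/boundaries → thickness →
variance → statistics from a NIfTI file or an in-memory volume, writes
every intermediate plus the resolved YAML configuration to a run
directory, and is bit-for-bit deterministic.

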