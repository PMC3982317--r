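# parasurf

Fit **C² continuous tensor-product cubic B-spline surfaces** to the
boundaries of structures segmented from 3D grayscale image volumes —
the kind of organ-scale reconstruction needed when a micro-CT scan of,
say, heart ventricles must become an analytic surface that supports
areas, volumes, curvatures, mesh generation and boundary conditions for
simulation.

Direct surface fitting is hard because every scattered boundary point
needs a unique parametric coordinate, and the fit quality hinges on how
those coordinates are distributed. parasurf implements the full
pipeline that solves this:

1. **Extraction** — voxels crossing an intensity threshold are
   labelled; their external faces form a quad surface (or a triangle
   isosurface via a tetrahedral marching decomposition), with full
   vertex-adjacency and inverse connectivity tables.
2. **Projection** — a patch delimited by 4 anchor vertices is mapped
   one-to-one onto a rectangle: anchors to corners, boundary paths
   equidistributed along the edges, and every interior vertex placed at
   the mean of its neighbours (a Tutte-type embedding; the reduced
   systems are symmetric, diagonally dominant, and solved by conjugate
   gradients to 1e−10).
3. **Regularization** — the projected mesh is made uniform in element
   area and edge length by minimizing the deformation energy
   `sum_e ∫ ‖J_e − Adj(J_e)/|J_e|‖²_F`, where `J_e` is the Jacobian
   against a scaled reference element; in singular values the integrand
   is `Σ_i (s_i − 1/s_i)²` — zero for rigid motions, growing with
   scaling and shear. A Gauss–Newton/Levenberg–Marquardt loop with
   determinant safeguards keeps the map one-to-one.
4. **Fitting** — three penalized least-squares problems (one per
   physical coordinate) over `(n_bx+3)(n_by+3)` control coefficients:
   `(1−λ)‖x − X(u,v)‖² + λ∫(X_uu² + 2X_uv² + X_vv²)dΩ`, with λ ∈ [0,1)
   and optional exact clamping of a domain edge to a codimension-1
   spline curve (ghost-coefficient elimination
   `ghost = 6γ − 4·edge − inner`).
5. **Distance metrics** — the closest distance from each data point to
   the surface via companion-matrix quintic root finding on 4+4
   coordinate lines per element, Newton refinement, and convex-hull
   pruning; reported as min/max/mean/variance tables.

Voxelized analytic phantoms (ball, bumpy hemisphere, and a hemisphere
with a papillary-muscle-like protrusion, all with exact implicit ground
truth) make everything runnable and testable with no external data.

## Worked example

Reconstruct a papillary phantom (radius 12 voxels, protrusion length 6)
end to end and report fit quality:

```r
library(parasurf)

cfg <- list(
  seed = 1L, output_dir = "papillary-run",
  input = list(phantom = list(type = "papillary", radius = 12,
                              protrusion_length = 6, protrusion_radius = 3,
                              spacing = 1)),
  project  = list(anchors = "auto", domain = c(0, 100, 0, 100)),
  fit      = list(n_bx = 9L, n_by = 9L, lambda = 0.2),
  distance = list(max_points = 200L))
man <- run_pipeline(cfg)
```

Output (abridged from the manifest):

```
vertices: 1928
faces: 1926
flipped after projection: 0
regularization status: converged iterations: 10
fit rms residual: 0.5592
distance summary over 200 points: min 0.0043  max 1.6764  mean 0.3745  variance 0.0722
```

Reading: the extracted boundary has 1928 vertices; the parametric
projection is one-to-one (no flipped elements); after regularization a
9 × 9-element spline (144 coefficients per coordinate) fits the patch
with a mean closest distance of **0.37 voxel spacings** — the whole
convoluted surface, protrusion included, captured at sub-voxel accuracy
by 432 numbers. The run directory contains the extracted mesh (OBJ),
the projected and regularized `(vertex, u, v)` tables (CSV), the
surface in a documented JSON schema, a tessellated OBJ for
visualization, the distance report (CSV) and `manifest.json` with every
parameter used.

A command-line wrapper with `pipeline`, `phantom`, `fit` and `distance`
subcommands is installed at
`system.file("cli", "parasurf.R", package = "parasurf")`.

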