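---
title: "Fitting C2 B-spline surfaces to segmented anatomical boundaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting C2 B-spline surfaces to segmented anatomical boundaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

parasurf reconstructs compact, twice continuously differentiable
parametric surfaces from the boundaries of segmented 3D image volumes —
the setting is organ-scale grayscale tomography (for instance micro-CT
of heart ventricles), where thresholding delineates cavity and organ
boundaries well, and downstream modelling (areas, volumes, curvatures,
mesh generation, boundary conditions for field equations) benefits
enormously from an analytic surface instead of a million-polygon
extraction. The pipeline has five stages; every stage is exposed as
ordinary functions and orchestrated by `run_pipeline()`.

## 1. Polygonal surface extraction

A voxel is labelled when its intensity crosses a threshold (default 100
on 8-bit data; `>=` by default, configurable to `>`). The external faces
of labelled voxels — faces not shared with another labelled voxel — form
a quad surface (`extract_boundary_quads()`); vertices are deduplicated
on exact integer corner coordinates, so this step is exact by
construction. For visualization or high-precision work,
`extract_isosurface_triangles()` extracts the iso-level of the
voxel-centre field as a triangle mesh with a tetrahedral cube
decomposition (Freudenthal 6-tet split sharing the main diagonal). The
decomposition is translation-invariant, so face diagonals of adjacent
cubes coincide and the result is a consistent oriented surface without
ambiguous configurations; iso-vertices are deduplicated per lattice
edge, which makes the surface watertight away from the volume border.
Both extractors build the full connectivity tables: vertex adjacency
(the neighbour graph used by the projection) and the inverse
vertex-to-face table. Multiple connected components are reduced to the
largest by face count (logged).

## 2. One-to-one projection onto the parametric plane

The user (or the pipeline's `anchors: auto` helper) picks 4 anchor
vertices in cyclic order; `trace_patch()` joins consecutive anchors by
shortest paths on the surface edge graph (hop count, physical length as
tie-break) and the enclosed region becomes the patch. Anchors map to the
corners of a rectangular domain, path vertices are equidistributed along
the domain edges (by vertex count; arc-length weighting is available),
and each free vertex's coordinates minimize the summed squared distance
to its graph neighbours. The stationarity condition makes every free
vertex the mean of its neighbours — a Tutte-type embedding with uniform
weights. The reduced linear systems (diagonal = vertex degree,
off-diagonal −1) are symmetric and strictly diagonally dominant, hence
positive definite, and are solved by unpreconditioned conjugate
gradients to a relative residual of 1e−10 (cap `10 n` iterations).
For a triangulated disk with convex pinned boundary this map is
one-to-one by Tutte's theorem; quad patches behave identically in
practice and are verified by a signed-area scan (`flipped_elements()`).

Two practical failure modes of digitized staircase rims required care.
First, consecutive shortest paths can touch at non-anchor vertices; the
segments are therefore traced sequentially, later segments avoiding the
vertices of earlier ones, which makes the loop simple by construction.
Second, the loop occasionally runs along three edges of a single quad
(an "ear", typically at a staircase corner near an anchor); pinning all
four of its corners onto the domain border would force that quad's
image to be degenerate or inverted no matter how the rest of the mesh
is laid out. Ears are rerouted through the face's remaining edge, which
releases the middle vertices into the interior; when an anchor sits on
a released vertex the anchor label moves to the run endpoint (the
returned `patch_spec` carries the anchors actually used).

The default pipeline domain is `[0, 100]^2`; the extent is arbitrary
(the bare `solve_projection()` defaults to the unit square) but the
100-unit convention keeps stiffness weights on the scale used for
organ-sized reconstructions. Interior holes of a patch are left
unconstrained, so spurious segmentation holes close by themselves
during projection. `repair_collisions()` implements the optional dense
point-cloud post-processing: properly crossing non-adjacent edges are
collapsed onto their intersection and nearly parallel edges sharing a
vertex (angle below 1e−3 rad) are fused, for at most 5 passes.

## 3. Mesh regularization

The projected mesh is regular in connectivity but wildly irregular in
element area: convoluted features (a papillary-muscle-like protrusion,
deep ridges) compress thousands of elements into a tiny parametric
region, and a fit would average away exactly the features of interest.
Regularization moves the free vertices so that elements become uniform
in area and edge length while the pinned boundary stays fixed.

Each element is compared with a scaled reference element (the square
`[-1, 1]^2` with bilinear shape functions, or an equilateral triangle
with linear ones) through the Jacobian `J` of the isoparametric map.
The energy integrates `|| J - Adj(J)/|J| ||_F^2` over the element by
2 × 2 Gauss quadrature (3-point rule for triangles) and sums over
elements. We take the adjugate as the cofactor matrix, so the
subtracted term is the inverse transpose and, in singular values,
the integrand is `sum_i (s_i - 1/s_i)^2`: zero exactly when the element
is a rigid motion of the reference, growing with scaling and shear, and
exactly invariant under rotation. Rotation invariance is not cosmetic —
rotation changes neither area nor edge length, so a deformation measure
for this purpose must ignore it; with the rotation-sensitive reading
`J - J^{-1}` the minimization provably stalls far from a uniform mesh
because arbitrary local rotations of a flattened staircase surface
dominate the energy. The reference scale sigma is chosen once per run
so that a mean-area element has `J = I` (`sqrt(mean area)/2`).

The minimizer is a Gauss–Newton/Levenberg–Marquardt iteration on the
residuals `sqrt(w) vec(J - J^{-T})`, with analytic residual Jacobians,
a sparse normal matrix rebuilt every iteration, Armijo backtracking,
and two safeguards: candidate steps must keep every quadrature-point
determinant positive (for the 2 × 2 rule this implies positive element
areas, because the bilinear determinant is integrated exactly), and the
flipped-element count may never increase. Termination is
`||g||_2 < epsilon` with `epsilon = 1e-4 ||g_0||` by default, capped at
200 iterations.

Tutte projections of convoluted patches usually contain strongly
non-convex or numerically collapsed quads on which the exact energy is
an infinite barrier, so a feasibility phase runs first: the same energy
with the smooth determinant regularization
`h(det) = (det + sqrt(det^2 + delta^2))/2` is minimized under a
shrinking-delta continuation until all quadrature determinants are
positive. If an isolated collapsed element (a numerically degenerate
bowtie) survives, the main phase keeps a tiny determinant floor
(~1e−6 of the mean determinant), which perturbs healthy-element
energies at the 1e−12 relative level and lets the barrier drive the
residual degeneracy out.

What regularization achieves on the voxel phantoms: the max/min
element-area ratio improves by about two orders of magnitude (roughly
1400× down to 26× on the papillary phantom), elements covering the
protrusion grow from invisibly small to average-sized, and the fit
below resolves the protrusion it would otherwise smooth away. The
*coefficient of variation* of element areas decreases less dramatically
(about a third at this phantom scale): its floor is set by a boundary
layer — equidistribution-by-count fixes the rim spacing at
perimeter/N_rim, about twice the interior element side — and by the
irregular vertex valences of voxel surfaces, while its initial value
grows with resolution. CV is therefore reported alongside the max/min
ratio rather than used as the sole quality measure.

## 4. Constrained spline fitting

The surface is a codimension-2, dimension-3 tensor-product cubic
B-spline: the domain splits into `n_bx x n_by` equal elements and each
axis carries `n + 3` coefficients (interior junctions plus one extra
row/column per end so border elements keep full degrees of freedom).
The basis is the uniform cubic B-spline — support of 4 knot segments,
value and first two derivatives vanishing at the support border, exact
partition of unity — so any coefficient combination is C2 everywhere,
including across knot lines. Fitting solves three independent penalized
least-squares problems (one per physical coordinate):

`(1 - lambda) * sum_i || data_i - X(u_i, v_i) ||^2 +
 lambda * int (X_uu^2 + 2 X_uv^2 + X_vv^2) dOmega`,
`lambda in [0, 1)`.

The stiffness integral is assembled exactly from per-axis Gram matrices
of basis derivatives (4-point Gauss per element, exact for these
polynomial degrees). Systems are solved by sparse Cholesky by default;
a restarted GMRES mode is available. With `lambda = 0` every element
must contain at least one data point (otherwise a structured error
advises raising lambda). `lambda` trades data fidelity against
curvature and twist; the pipeline's `sweep_lambda` mode fits several
values and reports the distance summaries so the choice can be made
from a table instead of interactively. The study configuration uses
9 × 9 elements and `lambda = 0.2` — a low stiffness appropriate for
smooth-but-convoluted cavity walls.

Clamping constrains one domain edge to coincide exactly with a
codimension-1 B-spline curve that has the same element count and knot
spacing as the clamped axis. Along an edge only three coefficient
layers contribute, with knot weights (1/6, 2/3, 1/6), so requiring the
edge to equal the curve coefficient-by-coefficient gives the exact
elimination `ghost = 6 gamma - 4 edge - inner`; the ghost layer is
removed from the unknowns, the reduced system is solved, and the ghost
coefficients are reconstructed. Two patches clamped to the same curve
join with a C0 seam (C1 coupling between patches is out of scope).
`edge_curve()` extracts the restriction of a fitted surface to an edge
for exactly this purpose.

## 5. Distance metrics

Fit quality is the closest distance from every data point to the
surface. Inside one element the surface is bicubic, so the derivative
of the squared distance along a `u = const` or `v = const` line is a
degree-5 polynomial; its real roots come from the eigenvalues of the
companion matrix (balanced Hessenberg QR, as provided by LAPACK through
`eigen()`), with numerically vanishing leading coefficients trimmed so
degree-degenerate cases introduce no spurious roots. Four lines per
direction per element are searched — the element borders plus interior
lines at offsets 1/3 and 2/3 (configurable) — plus the four corners.
The best candidate is refined by a damped Newton iteration on the local
quadratic model of the squared distance (minimizing D^2 rather than D:
the minimizers coincide and D^2 stays smooth at zero distance), which
stops at gradient norm below 1e−10 times the squared control-point
bounding-box diagonal, after 50 iterations, or as soon as a step would
cross an element edge — the neighbouring element's own candidates cover
the remainder, and the global minimum over elements makes the hand-off
safe. Elements are visited in order of the distance to their
control-point bounding box (the spline patch lies in the convex hull of
its 16 control points) and pruned once the bound exceeds the best
distance; unrefined candidate values are collected first so the bound
tightens before any refinement runs, and the best few well-separated
candidates of an element are each refined (a single start can slide
into a neighbouring basin and miss a minimum sitting between
coordinate lines). Reports carry per-point distances with their
parametric argmin and the min/max/mean/population-variance summary;
pipeline-level summaries use a deterministic 400-point subsample of the
patch vertices, which estimates the mean distance to well under the
reported precision.

## Phantoms: what they emulate and what they do not

The original imaging data behind this class of reconstruction is not
shippable, so the package generates voxelized analytic solids with
exact implicit ground truth: a ball (calibration), an open bumpy
hemisphere (`r(theta, phi) = R + A sin(k theta + p1) sin(k phi + p2)`,
phases drawn reproducibly from a seed), and a hemisphere carrying a
finger-like capsule protrusion whose tip reaches `R + L` — the
papillary-muscle analogue, hardest for low-degree-of-freedom fits.
Phantom volumes are binary 0/255 (threshold 100 separates them); an
optional Gaussian blur mimics partial-volume softness. The standard
study scale is radius 20 voxels with protrusion length 10 and radius 5
(proportions matching a papillary muscle in a small-animal ventricle:
thickness about R/4, length about R/2), giving patches of roughly 5000
vertices that the whole suite processes in minutes. Real tomography
differs in ways the phantoms deliberately omit: noise and
reconstruction artifacts, anisotropic voxels, segmentation holes where
surfaces nearly touch, and organ-scale resolution (hundreds of voxel
diameters, which makes the pre-regularization compression far more
extreme than at phantom scale). Passing tests therefore demonstrate the
machinery — exact extraction, one-to-one projection, density
equalization, sub-voxel fits, exact clamps — not robustness to
acquisition pathology.

## Numerical choices and degenerate inputs

- Conjugate gradient: relative residual 1e−10, cap `10 n`; failure to
  converge is a structured error, not a warning.
- Regularization: 2 × 2 Gauss points (quads), 3-point rule (triangles);
  `epsilon = 1e-4 ||g_0||` (floored at 1e−12 so an already-optimal mesh
  terminates immediately); 200 iterations; LM damping adapted by
  factors 10 and 1/3; 25 step halvings. Global map orientation is
  normalized to counterclockwise by winding reversal when the anchor
  loop runs clockwise.
- Spline fits: `lambda` validated in `[0, 1)`; `lambda = 1` is
  rejected because it drops the data term entirely.
- Quintic roots: eigenvalues with `|Im| <= 1e-8 (1 + |Re|)` count as
  real; leading coefficients below 1e−13 of the largest are trimmed.
- Ties and exact hits: volume samples exactly at the iso-level are
  nudged by 1e−9 of the intensity scale so every crossing is proper;
  parametric points exactly on a knot line evaluate in the
  right-adjacent element (values agree from both sides by C2).
- Serialization: spline JSON stores 15 significant digits; a
  write/read/write cycle is byte-identical.

## Known limitations

- One patch per run: multi-patch decomposition is supported only
  through explicit clamping to shared edge curves, with C0 seams.
- Uniform Tutte weights only (no cotangent/conformal variants), as the
  projection objective is the plain neighbour-distance sum.
- The marching-tetrahedra extractor produces more (smaller) triangles
  than table-based marching cubes for the same volume.
- The collision post-processing is a best-effort repair intended for
  very dense clouds; it is off by default in the pipeline.
- Quad patches lack the theoretical one-to-one guarantee of
  triangulated ones; the signed-area scan plus the regularizer's
  determinant safeguards stand in for it in practice.
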