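# mdpcarto

Cartography of cell behaviours in the embryonic mandibular prominence (MdP).

Early facial outgrowth is driven by oriented cell behaviours in a mesenchyme
that looks structurally uniform. This package quantifies those behaviours in
3D from the primitives a light-sheet study produces — spindle-pole
annotations, nuclear shape measurements, landmark files and tissue surface
meshes — and maps them onto the tissue surface. It is built for the analysis
of mediolaterally patterned mitotic behaviour at around embryonic day 10.5,
and ships a seeded synthetic-tissue generator so the entire pipeline is
testable without any imaging data.

## What it computes

Division axes are *axial*: a spindle orientation has no head or tail, so an
angle θ is identified with θ + 180° and a 3D axis u with −u. The package
works in this geometry throughout:

- **Mitotic angles**: the in-plane angle of a pole pair, measured from the
  anterior (rostral) direction and folded to [0°, 180°).
- **Axial statistics by angle doubling**: means via
  ½·arg Σ e^{i2θ}; in 3D via the leading eigenvector of the orientation
  tensor T = (1/n) Σ uuᵀ; Kuiper's V for uniformity and the two-sample
  Watson U² (permutation or asymptotic p), applied to doubled angles.
- **Mitotic alignment score**: for each dividing cell, the axial difference
  (0–90°) between its division axis and the mean axis of all dividing cells
  within a 200 µm ball around it; low = locally aligned.
- **Mediolateral segment analysis**: six equal-width segments along the
  mediolateral axis; per-segment rose histograms, uniformity tests, mean
  alignment scores and mitotic index.
- **Nuclear morphometrics**: area, perimeter, aspect ratio, eccentricity and
  long-axis orientation from fitted ellipses or binary masks; PCA of the
  standardized features; the signed spindle-versus-long-axis offset;
  feature–position rank correlations; per-segment variance profiles.
- **Landmark shape analysis**: ordinary Procrustes superimposition onto an
  atlas at unit centroid size (reflections excluded; mirror explicitly),
  per-age mean configurations, thin-plate-spline atlas morphing, and signed
  closest-point displacement maps between surfaces (positive = outward).
- **Surface cartography**: per-vertex 200 µm neighbourhood averages,
  relative proliferation maps (local mitotic index / global), nested
  isomorphic depth shells, and ray-cast positional mitotic orientation
  (both directions of each axis cast to the surface; hits per face,
  area-normalized).
- **Synthetic tissue**: a watertight ellipsoidal MdP stand-in with 7
  analytic landmarks, cells uniform in its interior, and mediolateral
  gradients of division-axis concentration (medial aligned, lateral
  isotropic), mitotic rate (lateral high) and nuclear shape variance
  (lateral variable), plus similarity-transformed replicate specimens.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
tissue (seed via the `MDP_SEED` environment variable, default 1), writing
tables and PLY maps under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_align_cells.R
Rscript analysis/03_circular_stats.R
Rscript analysis/04_nuclear_morphometrics.R
Rscript analysis/05_shape_atlas.R
Rscript analysis/06_surface_maps.R
```

At seed 1, stage 2 prints:

```
pooled 30000 cells (4580 mitotic, 4580 scored) from 4 specimens
per-segment mean alignment score (deg, medial -> lateral): 7.2 9.4 11.7 13 15.9 26.2
per-segment mitotic index: 0.074 0.105 0.135 0.178 0.195 0.234
```

i.e. the pipeline recovers the generator's two ground-truth gradients:
alignment scores rise monotonically from medial to lateral (divisions are
locally aligned medially, near-random laterally) while the mitotic index
rises in the same direction — the inverse relationship between alignment and
proliferation. Stage 4 prints the nuclear-shape PC1 variance per segment
(`2.11 … 5.76`, Spearman ρ = 1.0 with segment index), recovering the lateral
shape-variability gradient, and stage 6 summarizes the same alignment
contrast at four tissue depths and reports the ray-cast hit map
(`9066 hits = 2 × 4533 cells cast`).

The same composition is available as one call:

```r
library(mdpcarto)
run_demo("results/demo", seed = 1)
```

Equivalent results for your own data start from `read_cell_table()`,
`read_mesh()` and `read_landmarks()` (CSV/TSV cell tables, ASCII PLY/OBJ
meshes, 3D Slicer FCSV landmarks).

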