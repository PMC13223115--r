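---
title: "Quantifying 3D cell behaviours in the mandibular prominence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D cell behaviours in the mandibular prominence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, what the synthetic-tissue generator
does and does not emulate, and the design choices made where the problem was
genuinely open.

## The measurement problem

In the E10.5 mandibular prominence (MdP), mesenchymal cells divide with
orientations that are locally coordinated in some regions and random in
others. The primitive observation is a pair of spindle-pole coordinates per
dividing cell, plus the nuclear centroid and, per nucleus, a fitted ellipse.
A division axis is *axial* — there is no biological difference between a
vector and its negation — so every statistic here is built to be invariant
to swapping or negating pole pairs.

Coordinates are micrometres in a right-handed frame: +x lateral, +y
anterior (rostral), +z dorsal. Sagittal sections span (y, z) and coronal
sections span (x, z). In-plane angles are measured from the anterior
direction for sagittal sections. For coronal sections the anterior axis is
out of plane; we use the dorsal direction as the in-plane reference, with
angles increasing toward lateral. The dorsal-positive sense of sagittal
angles is itself a convention the source data do not fix; it is documented
here so results are reproducible, and all downstream statistics are
invariant to it.

## Axial statistics

Axial angles live in [0°, 180°). Doubling (θ → 2θ) maps them bijectively to
the full circle, where standard circular statistics apply; results are
halved back. Concretely:

- 2D axial mean: ½·arg Σ e^{i2θ}, with concentration measured by the
  doubled resultant length R̄ ∈ [0, 1].
- 3D axial mean: leading eigenvector of T = (1/n) Σ uuᵀ, with concentration
  λ₁ ∈ [1/3, 1] (1/3 = isotropy).
- Degeneracy: when R̄ < 10⁻³, or λ₁ − λ₂ < 10⁻³, the mean axis is not
  identifiable (e.g. two orthogonal axes) and is reported as undefined
  rather than as an arbitrary direction. Undefined means propagate as
  missing values into every downstream summary; they are flagged, never
  silently dropped. This thresholded behaviour is a deliberate choice: an
  arbitrary axis here would contaminate alignment scores invisibly.

Uniformity is tested with Kuiper's V = D⁺ + D⁻ on the doubled angles
(rotation-invariant by construction), two-sample comparisons with Watson's
U² computed from the pooled cumulative difference with mean correction.
Both offer a seeded Monte-Carlo/permutation p-value (the default, with the
+1 convention p = (1 + #{extreme}) / (reps + 1)) and a classical asymptotic
series. Permutation inference is the default because per-segment samples
can be small and because it makes no distributional claims; the asymptotic
series is provided for speed on large samples. No multiple-testing
correction is applied across segments by default; `holm_adjust()` is
available when a family-wise rate is wanted.

## The mitotic alignment score

For each dividing cell, the score is the axial difference (0–90°) between
its own division axis and the 3D axial mean of all dividing cells within a
200 µm closed Euclidean ball around it. Two documented choices:

- The focal cell is excluded from its own neighbourhood mean (configurable).
  Including it shrinks every score toward 0 and turns the score into a
  partly self-referential quantity; exclusion makes it a genuine
  cell-versus-neighbours contrast.
- The ball is Euclidean, not geodesic within the tissue: at 200 µm in a
  tissue a few hundred µm across, the difference is small, and a Euclidean
  ball is exactly reproducible.

Mediolateral segments are equal-width bins of the cells' x coordinates over
the occupied extent (not the mesh bounding box, so a generous mesh margin
cannot shift the bins), right-open except the last. Segment 1 is the most
medial.

## Nuclear morphometrics

Five features per dividing nucleus: area, perimeter, aspect ratio (AR),
eccentricity, long-axis orientation. From ellipse parameters they are
analytic (perimeter by Ramanujan's second approximation, accurate to ~10⁻⁵
relative at AR ≤ 4); from binary masks they are the pixel-count area, the
crack-length perimeter and the second-central-moment equivalent ellipse.
AR is defined major/minor (≥ 1), which makes AR and eccentricity
co-monotone — consistent with their joint loading on a "circularity"
component.

The PCA standardizes each column (z-scores, denominator n − 1) and
eigendecomposes the correlation matrix; loading signs are fixed so each
component's largest-magnitude loading is positive. By default the PCA uses
the four linear features and *excludes* orientation: orientation is axial,
and a circular variable has no canonical z-score. A documented option
(`include_orientation = TRUE`) adds the doubled-angle cosine/sine pair
instead, for analyses that want all five features represented. Neither
variant claims numerical parity with any particular upstream software.

The spindle-versus-long-axis offset is the signed axial difference folded
to (−90°, 90°], with the summary mean computed on doubled angles and halved
— a plain arithmetic mean would be wrong near the fold. The significance
of variance-versus-position profiles is assessed by permuting segment
labels with the range of per-segment variances as the statistic; this is
this package's defined method, chosen because a variance-heterogeneity test
across ordered spatial bins has no single standard form.

## Shape analysis

Landmark configurations (7 ordered points) are superimposed onto an atlas
by ordinary Procrustes analysis: translate to the centroid, scale to unit
centroid size, rotate by the SVD solution with determinant correction.
Reflections are never folded in silently — mirrored (right-side) specimens
are reflected explicitly with `mirror_landmarks()` before superimposition,
which keeps the provenance of every reflection visible. Ordinary (onto a
fixed atlas) rather than generalized iterative Procrustes is used
throughout; per-age means are averages of superimposed configurations,
re-scaled to unit size.

Atlas meshes are morphed to mean configurations by a 3D thin-plate spline
with kernel U(r) = r and an affine part; interpolation at the landmarks is
exact (residuals below 10⁻⁶ µm), and coplanar landmark sets are rejected
(singular system). Shape change between two surfaces is the per-vertex
closest-point distance (exact point-to-triangle minimum), signed by
watertight containment — positive outside the target surface, i.e. outward
displacement. Containment is used for the sign, rather than normal dot
products, because it is robust to noisy or inconsistent normals. The map
is directional (A onto B); the direction is named in the output rather than
symmetrized.

For cell-level work in a common frame, the Procrustes transform of each
specimen is composed back to the atlas's micrometre scale
(`opa_to_reference_transform()`), positions are transformed fully, and
division axes by the rotation only — pairwise axial differences are
preserved exactly, so alignment scores computed before and after
superimposition agree.

## Surface cartography

Scalar fields on the atlas surface are unweighted means of cell values in
the 200 µm ball of each vertex, with a per-vertex coverage count; a vertex
with no covered cells is undefined, and undefined is representable all the
way through serialization (PLY `quality` plus a sidecar table with an
explicit −9999 sentinel documented in both headers).

Depth is represented by nested isomorphic shells: copies of the surface
scaled about its volume centroid (default scales 1.0, 0.8, 0.6, 0.4).
Centroid scaling — rather than normal offsetting — preserves the mesh
topology exactly ("isomorphic") and cannot self-intersect on concave
regions. Cells are assigned to bands between successive shells by
containment; band 0 is outermost. Cells falling just outside the outermost
shell (which happens after cross-specimen superimposition with landmark
noise) are assigned band 0 and counted in a warning.

Positional mitotic orientation ray-casts each division axis from the cell
in both directions (divisions are bidirectional) to its first surface
intersection; each of the two hits increments a face counter, so total hits
are exactly twice the cells cast. The frequency field divides per-face
counts by face area and total hits; the per-face, area-normalized
convention is this package's documented choice.

## The synthetic-tissue generator

The generator exists so that every downstream stage has a testable input
with known ground truth. It emulates:

- a watertight ellipsoidal MdP-like surface (subdivided icosphere scaled to
  semi-axes 300 × 150 × 100 µm — mediolateral × anteroposterior ×
  dorsoventral, the order of an E10.5 prominence) with 7 analytically
  placed landmarks;
- cells i.i.d. uniform in the interior (rejection sampling, seeded);
- a mediolateral gradient of division alignment: each parameter is linearly
  interpolated in the normalized mediolateral coordinate u ∈ [0, 1], with
  axial concentration κ(u) from κ_medial = 30 (angular SD ≈ 11°) down to
  κ_lateral = 0.5 (SD ≈ 81°, near-isotropic);
- a mitotic-rate gradient from 0.05 (medial) to 0.25 (lateral);
- nuclear ellipses with fixed 5 µm minor axis, lognormal aspect ratio
  (median 1.3) whose log-SD grows 0.10 → 0.20 medial to lateral, and
  orientation equal to the in-plane division angle plus 20° wrapped-normal
  noise;
- multiple specimens: similarity transforms (uniform SO(3) rotation, scale
  0.9–1.1, ±50 µm translation) with 2 µm isotropic landmark jitter, the
  drawn transform stored as ground truth.

Axial sampling draws the polar deviation from the preferred axis as
|wrapped-normal(0, 1/√κ)| with uniform azimuth — a simple, seedable,
concentration-monotone scheme. At κ = 0 that scheme is undefined (infinite
SD), so concentrations below 10⁻⁸ draw the axis uniformly on the sphere,
the exact isotropic limit (which also makes the projected in-plane angle
exactly uniform). Aspect ratios drawn below 1 are folded to their
reciprocal so AR ≥ 1 always holds. Pole separation is fixed at 6 µm — the
order of a metaphase spindle; only its consistency matters.

Default problem size: 7 500 cells per specimen and 4 specimens, so the
pooled data carry ≈ 4 500 mitotic cells — the scale of the study this
analysis is designed for (about 1 100 mitotic cells per specimen at the
mean mitotic rate of 0.15). Parameter-recovery tests run at this pooled
scale; reduced sizes are used only where a test checks an exact property
that does not depend on n.

What the generator does **not** emulate — and hence what passing tests do
not show about real tissue: anisotropic imaging artefacts and segmentation
error; a genuinely two-domain (step-like) medial/lateral pattern — the
linear κ gradient keeps even fairly lateral segments weakly concentrated,
so, unlike real data, lateral segments can still reject uniformity at
pooled sample sizes; cell migration, intercalation or any dynamics; spatial
autocorrelation ("patchiness") of positional orientation; and realistic
nuclear-shape covariance — with the minor axis fixed, the four linear
features are driven by one latent variable, so the synthetic feature PCA is
nearly one-dimensional (PC1 ≈ 95%+), unlike real nuclei where size and
circularity vary separately. Recovery tests therefore target the gradients
the generator encodes (alignment, rate, shape variance), not the full
covariance structure of real nuclei.

## Numerical choices and degenerate inputs

- Watertightness = every undirected edge shared by exactly two faces;
  containment by ray parity with a fixed (irrational-direction) ray and
  fallback directions when a cast grazes an edge. The parity kernel is
  compiled (Rcpp); a pure-R reference path is kept and tested against it.
- Point-to-triangle distance: project to the supporting plane, clamp to
  edges when the foot is outside the triangle; queries scan all faces
  (exact, no spatial pruning) — adequate at the mesh sizes used here.
- Ball queries use a uniform grid at the query radius (27-cell stencil);
  results are exact and tested against the O(n²) scan.
- Ties and boundaries: ball queries are closed (boundary included);
  segment bins right-open except the last; pole–nucleus matching resolves
  sub-nanometre distance ties lexicographically so the result is
  order-invariant; greedy one-to-one matching with a 10 µm cap (nearest
  neighbour alone can pair absurdly distant annotations in sparse regions).
- All randomness flows from one integer seed; each pipeline stage derives
  its own sub-seed from the stage name (`stage_seed()`), so stages rerun in
  isolation reproduce their outputs byte for byte.
- Degenerate inputs fail loudly with classed errors naming the offending
  cell, column or feature: coincident pole pairs on mitotic rows, axes
  normal to the projection plane, zero-variance PCA columns, coplanar TPS
  landmarks, all-equal mediolateral coordinates, non-watertight meshes
  where containment is required.

## Known limitations

- The coronal-plane angle reference (dorsal) is a convention; statistics
  are invariant to it but raw angle tables are not comparable across
  different conventions without re-folding.
- Closest-point displacement maps are computed A→B only; strongly
  non-corresponding surfaces make any closest-point map hard to interpret.
- The TPS uses kernel U(r) = r with exact interpolation; no smoothing
  parameter is exposed, so very noisy landmarks produce wiggly warps.
- Greedy pole–nucleus matching is not globally optimal bipartite matching;
  with a tight distance cap the difference is rare, and the matching report
  flags ambiguous cases. De-duplication of the same spindle annotated in
  adjacent slices is out of scope here and should happen upstream.
- Mean alignment-score differences between *adjacent* medial segments are
  small under a linear κ gradient (≈ 1° against a segment SE of ≈ 0.5° at
  the default scale), so strict six-segment monotonicity is recovered in
  most but not every replicate; the medial-versus-lateral contrast itself
  is unambiguous.
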