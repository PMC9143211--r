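---
title: "Dose-volume analysis of segmental mandibular resections: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-volume analysis of segmental mandibular resections: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resectRT)
```

## The problem

Osteoradionecrosis (ORN) of the mandible is a late complication of head-and-neck
radiotherapy: irradiated bone loses its capacity to heal, and severe cases are
treated by segmental resection — removing a full-thickness segment of the
mandible between two osteotomy (bone-cut) planes. Where to place those cuts is
an open surgical question. One candidate criterion is dosimetric: place the
margins outside the bone volume that received at least 56 Gy, on the reasoning
that bone beyond that threshold has the highest necrosis risk.

Evaluating that criterion retrospectively requires fusing three data sources in
one patient-space frame: the radiotherapy planning CT (bone anatomy), the
planned dose distribution (DICOM RTDOSE), and structure sets (DICOM RTSTRUCT:
mandible, planning target volume). From these the analysis derives, per
patient:

* `Vm` — total mandible volume (mL);
* `V56`, `V_PTV` — the whole-grid volumes receiving ≥ 56 Gy and the PTV region;
* `Vm56`, `Vm_PTV` — the mandibular portions of those regions;
* `VmR` — the resected mandibular volume;
* `Vm56R`, `Vm_PTV_R` — irradiated mandibular volume *left behind* after the
  resection;
* each volume also as a percentage of `Vm`;
* per osteotomy plane, whether it intersects `Vm56`, and if so whether the
  lingual (inner) cortex, the buccal (outer) cortex, or both are involved.

Group comparisons (recurrent vs non-recurrent ORN) then use a
normality-gated two-sample test per metric.

`resectRT` implements this pipeline end to end, plus a synthetic phantom and
cohort generator so that every stage is testable without patient imaging —
patient data of this kind are not publicly distributable.

## Geometry model

All geometry lives in one `image_frame`: DICOM LPS patient coordinates in
millimetres, voxel centers at `origin + direction %*% ((ijk - 1) * spacing)`.
Oblique orientations are supported in the frame model and in dose resampling;
contour rasterisation and the arch-midline construction require an
axis-aligned frame (clinical RT planning CTs are acquired axially, and all
synthetic fixtures are axis-aligned).

Membership of a voxel in any region is decided by its **center** (half-open
behaviour at boundaries). This makes every downstream boolean exact — resected
and residual segments partition the mandible voxel-for-voxel — and converges
to the continuum value as spacing shrinks. Volumes are voxel counts times the
voxel volume, reported in mL.

Dose is resampled to the reference frame by trilinear interpolation, which is
exact for affine fields; points outside the dose grid's support get 0 Gy
(conservative: clinical dose grids cover the treated region). Isodose regions
are `dose >= threshold` (inclusive), which makes regions from one grid nested
across thresholds. The RTSTRUCT route — isodose lines exported as contours —
is supported through the same rasteriser used for anatomical structures
(`isodose_from_contours`), since some planning systems export isodose
surfaces only that way. The PTV is always taken from its structure-set
contour, not from a dose threshold, because the prescribed PTV dose varies
per patient (56–72 Gy here) while the analysis threshold is fixed at 56 Gy.

Contour rasterisation assigns each planar polygon to the nearest voxel plane
(within half the slice spacing; the tie at exactly half a slice goes to the
lower-index plane, for determinism), then applies an even-odd center-in test,
so nested polygons produce holes.

## Surface meshes

`mesh_from_mask` extracts the 0.5 iso-surface of the binary indicator using
**marching tetrahedra** on the six-tetrahedron (Kuhn) decomposition of each
cell. Compared with classic marching cubes, the tetrahedral decomposition has
no ambiguous cases, so the extracted surface is watertight by construction —
every edge is shared by exactly two triangles — without case-table repairs.
The cost is a somewhat higher triangle count; for this analysis mesh quality
matters less than a guaranteed closed surface, because enclosed volume
(divergence theorem) is used as an independent check against voxel-count
volume. Masks are zero-padded by one voxel before extraction so regions
touching the array border still close. On a 10 mm sphere at 0.5 mm spacing,
voxel volume and mesh-enclosed volume are both within 2% of the closed form,
and halving the spacing at least halves the error.

## Virtual resection and plane recovery

A `resection_spec` carries 1..n oriented planes (unit normal pointing into the
removed segment). In the default half-space mode the resected segment is the
intersection of the positive half-spaces with the mandible; in seed mode the
planes act as cuts, voxels are grouped by their pattern of plane sides, and
the connected group containing a seed point is removed — the representation
needed for cuts (e.g. condylar removal) where a half-space intersection is
ambiguous.

`fit_cut_planes` solves the inverse problem: given the pre-operative mandible
and the registered post-operative (residual) bone, it finds the removed
material, keeps its boundary voxels adjacent to retained bone, estimates a
local normal per boundary voxel from the principal axes of its neighbourhood,
clusters position + scaled orientation with k-means into the requested number
of cuts, and fits a total-least-squares plane per cluster. On convex phantoms
planted planes are recovered within 1° and 0.5 mm.

Rigid registration (`register_rigid`) is initialised by centroid +
principal-axes alignment (all four proper sign combinations, best kept),
refined by point-to-point ICP with a Kabsch solve per iteration, and polished
by linearized point-to-plane iterations. Point-to-point ICP alone stalls at
the vertex-spacing scale; the point-to-plane stage aligns to the surface
itself and reports a true point-to-surface RMS. Because a mandibular arch is
nearly mirror-symmetric, ICP has deep mirrored local minima; when the
principal-axes start ends above 0.3 mm RMS, deterministic restarts (including
half-turns) are tried. Two-segment registration (`register_two_segment`)
simply registers each segment independently — the situation after a free-flap
reconstruction changes the assembled shape but not the segments.

## Lingual/buccal classification

Clinically, "lingual" is the tongue-facing (concave) side of the arch and
"buccal" the cheek-facing (convex) side. No standard quantitative definition
exists, so the package constructs one automatically from the mask: the axial
occupancy of the mandible is fitted with a least-squares circle (Kasa fit),
a smoothing spline of radius versus arch angle gives the midline radius at
every angle, and a point is lingual iff its radius is below the midline at its
angle. For arch-shaped (horseshoe) topology this radial mid-curve is the
natural skeleton; it is fully deterministic and testable on phantoms.

`classify_osteotomy` takes the `Vm56` voxels within half a voxel diagonal of
the plane (a slab thick enough that the plane cannot slip between voxel
centers) and within the cortical shell — the outer `shell_mm` of the mandible,
default 2 mm, obtained by spherical erosion; cortical thickness is not
measurable on planning CT at this resolution, so the shell is a configurable
convention. Contact areas are voxel counts times in-plane voxel area. The
category follows the invariant table: `outside` iff no contact,
`lingual_only` / `buccal_only` for one-sided contact, `bicortical` otherwise.
`buccal_only` is reported as its own category even though clinical series
typically report only the other three. For resections with no bone-cutting
plane, the convention is: if irradiated mandibular volume remains after the
resection, the case counts as bicortical, with areas measured on the
resection boundary.

## Statistics

`normality_test` is the Kolmogorov–Smirnov distance against a normal with
parameters estimated from the sample. Estimated parameters make the plain KS
null anticonservative, so the p-value comes from a Monte-Carlo null
distribution of the statistic — the Lilliefors correction — with 10^4 seeded
draws memoised per sample size (the null depends only on n). The seeded null
makes p-values reproducible and independent of the caller's RNG state.

`compare_groups` applies the gate at α = 0.05: both groups normal (and n ≥ 4,
the minimum for the normality test) → pooled-variance Student t-test, matching
the classical label (Welch available by flag); otherwise Mann–Whitney U, exact
for small tie-free samples and tie-corrected normal approximation otherwise.
All tests are two-sided; no multiplicity correction is applied by default
(a per-metric comparison table mirrors the usual clinical presentation), and
none of the operating-characteristic guarantees below depend on one.
Under the null the gated procedure's type-I error is ≈ 0.05 (checked by
simulation at the cohort's group sizes of 28 vs 5), and at the observed
effect size for the irradiated mandibular volume (means ≈ 30.7 vs 10.9 mL,
SDs 8 vs 5) rejection exceeds 90%.

`cohort_summary` recomputes every percentage from its mL fields and flags
rows where the stored percentage deviates by more than half a percentage
point — clinical summary tables occasionally contain such internal
inconsistencies, and the package surfaces rather than reconciles them.

## The synthetic generator

`make_phantom` builds two-level HU images: spheres and horseshoes (torus
segments — arch radius, tube radius, arc span), with closed-form volumes
(4/3·π·r³; Pappus: π·r_tube²·arch arc length). `make_dose` provides a linear
ramp and an isotropic Gaussian focus `peak·exp(−d²/2σ²)`; the peak must lie in
the 56–72 Gy prescription envelope. The Gaussian is not a beam model — the
analysis only needs a monotone field with a controllable ≥ 56 Gy fraction.

`make_case` composes a case the way the clinical material is structured: a
horseshoe mandible with volume drawn from N(62.7, 15) truncated to the
observed 26.4–95 mL range; a dose focus on the arch whose falloff scale σ is
calibrated by bisection so a target fraction of the mandible (uniform on the
observed 9–83% range) receives ≥ 56 Gy; a PTV as the ≥ PTV-dose isodose
sphere of the Gaussian (PTV dose drawn between 56 Gy and the peak, hence
nested inside the 56 Gy region); and two cut planes bracketing the focus, the
resected arch fraction drawn uniformly on 0.07–0.60 (observed resected
fractions average 35%, range 7–78%; the upper bound is capped where two
half-space cuts stop describing a wedge). Cohort mode draws group-dependent
parameters: recurrent patients Vm ~ N(47.8, 10), irradiated fraction centred
on 23%; non-recurrent Vm ~ N(65.4, 15), fraction centred on 45% — the
group structure of the clinical summary tables.

Ground truth for every case is computed on a grid 4× finer than the analysis
grid, directly from the closed-form membership functions (torus section,
Gaussian ball, half-spaces) — independent of the package's voxel machinery.
The fine lattice subdivides each analysis voxel exactly, so both grids
estimate the same physical region.

What the generator does **not** emulate: real HU heterogeneity (trabecular vs
cortical bone), metal artefacts, realistic IMRT dose textures, curved or
multi-segment osteotomies, and anatomical detail beyond horseshoe topology.
Passing tests therefore demonstrate correctness of the geometry and
statistics, not robustness to clinical image quality.

## Numerical choices and tolerances

* **Analysis grid**: `make_case` defaults to 0.8 mm isotropic. A cut plane
  assigns whole voxels to one side, so the expected absolute volume error at a
  cut scales like (cut area) × spacing/2 ≈ 250 mm² × 0.4 mm ≈ 0.1 mL — the
  same order as the 0.1 mL (one decimal) reporting precision of the volume
  tables. Ground-truth agreement is therefore assessed at 2% relative with an
  absolute floor of one reporting unit (0.1 mL for volumes, 0.5 percentage
  points for percentages); for near-empty residual regions — which the
  clinical conditions genuinely produce (residual irradiated volume can be
  exactly 0) — a pure relative bound is not meaningful at any clinically used
  voxel size.
* **Cohort grid**: group statistics are insensitive to sub-voxel accuracy, so
  cohort simulation defaults to 1.5 mm for speed; the per-case oracle checks
  run at 0.8 mm. The 100-case oracle sweep and the statistical simulations
  (2000 null replicates, 500 power replicates) keep the whole validation
  suite within a few minutes on one CPU.
* **Dose round trip**: RTDOSE files store integers × a scaling factor chosen
  as max dose/60000; the round-trip quantum is that factor (≈ 0.001 Gy).
* **Ties and degeneracies**: contour-to-plane ties go to the lower plane;
  voxel centers exactly on a cut plane go to the resected side; constant
  samples make the normality test error and `compare_groups` fall back to
  p = 1 for fully identical groups; an empty resected segment is a warning,
  not an error.
* **UIDs**: DICOM UIDs are generated deterministically from the case seed, so
  fixed-seed fixtures are byte-identical across runs.

## Known limitations

* Contour rasterisation and midline construction assume axis-aligned frames;
  oblique acquisitions must be resampled first.
* The arch midline assumes horseshoe topology; it is not meaningful for
  arbitrary bone shapes.
* Plane fitting assumes planar cuts; saw curvature or stepped cuts will be
  approximated by their best plane.
* The Lilliefors null is simulated at 10^4 draws, so p-values have Monte-Carlo
  granularity of about 10^-4.
* `buccal_only` involvement is reported as its own category; series that fold
  it into bicortical will differ in that cell.

## A worked example

```{r example, eval = FALSE}
library(resectRT)

case <- make_case(seed = 42)      # synthetic patient, 0.8 mm grid
case$metrics                      # pipeline volumes on the analysis grid
case$truth                        # 4x-finer closed-form ground truth

# classify the two osteotomy planes
vm56 <- intersect_volumes(case$mandible, case$isodose)
classify_osteotomy(case$planes[[1]], vm56, case$mandible)

# a full cohort and its group comparison table
coh <- make_cohort(n_nonrecurrent = 28, n_recurrent = 5, seed = 1)
res <- cohort_summary(coh$metrics)
res$comparisons$Vm56
tabulate_osteotomies(coh$planes)
```
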