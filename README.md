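# resectRT

Dose–volume analysis of segmental mandibular resections after radiotherapy.

Severe mandibular osteoradionecrosis (ORN) is treated by removing a
full-thickness segment of the jaw between two osteotomy planes. Whether those
bone cuts should avoid the heavily irradiated bone — conventionally the volume
that received at least 56 Gy — is a live surgical-planning question. Answering
it retrospectively requires fusing the radiotherapy planning CT, the planned
dose grid (DICOM RTDOSE) and structure sets (DICOM RTSTRUCT) into one
patient-space frame, reconstructing isodose volumes, applying the performed
resection virtually, and quantifying what irradiated bone was removed and what
was left behind.

`resectRT` implements that pipeline for R:

* **DICOM-RT I/O** — reads CT series, RTDOSE and RTSTRUCT (and writes them,
  for synthetic fixtures); masks as NIfTI, meshes as STL/PLY.
* **Volumetrics** — voxel masks in a common frame; trilinear dose resampling;
  bone segmentation (HU threshold + largest 26-connected component); inclusive
  isodose regions `dose >= T`; watertight iso-surface meshes by marching
  tetrahedra.
* **Virtual resection** — osteotomy planes as point + unit normal; exact
  voxel partition into resected and residual segments; recovery of cut planes
  from pre/post-operative masks; rigid (ICP) registration of post-operative
  segments, singly or per segment.
* **Cortical classification** — each plane's relation to the irradiated
  mandibular volume: `outside`, `lingual_only`, `buccal_only`, `bicortical`,
  using an automatically constructed arch midline to separate the lingual
  (inner) from the buccal (outer) cortex.
* **Metrics and statistics** — the per-patient record
  (Vm, V56, V-PTV, Vm56, Vm-PTV, VmR, Vm56R, Vm-PTV-R, and percentages of
  Vm), plus normality-gated two-group comparisons: Lilliefors-corrected
  Kolmogorov–Smirnov gate, pooled-variance Student t or Mann–Whitney U.
* **Synthetic data** — sphere and horseshoe phantoms with closed-form
  volumes, calibrated Gaussian dose foci, full synthetic cases (with DICOM
  fixtures and 4×-finer-grid ground truth) and two-group cohorts, so the
  whole pipeline is testable without patient imaging.

## The quantities

For a mandible mask $M$, dose $D$, PTV region $P$ and resected segment $R$
(all voxel sets in one frame, volumes in mL):

$$V_m = |M|, \quad V_{m56} = |M \cap \{D \ge 56\,\mathrm{Gy}\}|, \quad
V_{mR} = |M \cap R|, \quad V_{m56R} = |(M \setminus R) \cap \{D \ge 56\}|$$

and analogously for the PTV; each also as a percentage of $V_m$. Osteotomy
planes intersecting $V_{m56}$ within the cortical shell are classified by
which cortical plate (lingual/buccal) the contact touches.

## Worked example

```r
library(resectRT)

case <- make_case(seed = 42)   # synthetic patient on a 0.8 mm grid
case$metrics
#> <volume_metrics> (mL, 1 decimal; percentages of Vm)
#>   Vm            54.2
#>   V56          118.9
#>   V_PTV         61.5
#>   Vm56          30.6
#>   Vm_PTV        19.2
#>   VmR           18.7
#>   Vm56R         11.9
#>   Vm_PTV_R       1.0
#>   Vm56_over_Vm       56%
#>   Vm_PTV_over_Vm     35%
#>   VmR_over_Vm        35%
```

Here 56% of the 54.2 mL mandible received at least 56 Gy; the virtual
two-plane resection removed 18.7 mL (35%) and left 11.9 mL of irradiated
mandible behind. The independent ground truth on a 4×-finer grid
(`case$truth`) agrees field by field within 2% (with a 0.1 mL floor for
near-empty residuals). Classifying the first osteotomy plane:

```r
vm56 <- intersect_volumes(case$mandible, case$isodose)
classify_osteotomy(case$planes[[1]], vm56, case$mandible)
#> <cortical_classification> bicortical (lingual 69.1 mm2, buccal 59.12 mm2)
```

A cohort with the clinical group structure (28 non-recurrent vs 5 recurrent)
and its comparison table:

```r
coh <- make_cohort(n_nonrecurrent = 28, n_recurrent = 5, seed = 1)
cohort_summary(coh$metrics)$comparisons$Vm56
#> <group_comparison> Vm56
#>   non_recurrent n=28 mean=   32.66 min=   13.08 max=   70.00
#>   recurrent    n= 5 mean=   12.15 min=   10.18 max=   15.60
#>   MWW test: statistic = 138, p = 3.371e-05

tabulate_osteotomies(coh$planes)$total
#>      outside lingual_only  buccal_only   bicortical
#>            6           12            0           48
```

The irradiated mandibular volume is markedly smaller in the recurrent group —
the pattern the analysis is designed to detect — and most synthetic cuts run
through irradiated bone bicortically.

A thin command-line front end is installed at `inst/cli/resectrt.R`
(`run-case`, `cohort-stats`, `render`, `make-phantom`, `make-cohort`).

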