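---
title: "An LSCC-based coordinate system for temporal-bone CT and MR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An LSCC-based coordinate system for temporal-bone CT and MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsccframe)
```

## Why an internal coordinate system

Small-field-of-view temporal-bone imaging excludes the orbital and
maxillofacial landmarks that classical head frames rely on, and external
fiducials are invasive and cannot be applied to images already acquired.
The lateral semicircular canals (LSCC) are visible in both cone-beam CT
and high-resolution T2 MR, and the junctions of each canal with the
vestibule — anterior (within the ampulla) and posterior — are point-like
features an expert can select repeatedly. Four such points, two per ear,
are enough to define an origin and three orthogonal axes, and because the
same anatomy is visible in both modalities the frame doubles as a
landmark-based rigid co-registration.

## The frame construction

Input is an `lscc_landmark_set`: the four labelled points in world
millimetres, LPS convention (+x right→left, +y anterior→posterior, +z
inferior→superior, right-handed). `build_lscc_frame()` then:

1. fits a plane to the four landmarks by **total least squares**
   (smallest principal direction of the centred points). Orthogonal
   regression, not `z ~ x + y`, because step 2 projects the landmarks
   *orthogonally* onto this plane — only the orthogonal-distance plane
   makes the fit and the projection mutually consistent;
2. projects the four landmarks onto the plane;
3. takes the **origin** as the mean of the four projections (so the
   origin itself lies on the plane);
4. sets **x̂** along the line joining the right and left
   anterior–posterior midpoints (right→left), and **ŷ** as the
   anterior→posterior direction within the plane, orthogonalised against
   x̂;
5. completes **ẑ = x̂ × ŷ** (superior for a right-handed landmark
   configuration) and finally rotates ŷ and ẑ about x̂ by
   `tilt_degrees` (default +20°).

The tilt exists purely for orientation convenience: the canal plane sits
roughly 20° away from the Reid horizontal, so tipping the frame by +20°
about x̂ brings its xy plane close to the familiar upright head
orientation. The rotation sense follows the right-hand rule about +x̂;
since the defining description ("counter-clockwise about x") depends on
an unstated viewing direction, the parameter is signed and configurable —
pass `-20` for the opposite convention, or `0` to keep the raw canal
frame.

Two conventions are fixed deterministically rather than left to the
numerics: the plane normal points superior (z ≥ 0, ties broken by y then
x), and a landmark set whose left points do not have strictly greater x
than its right points is an *error*, not something to repair silently —
swapped sides in a clinical table indicate data-entry mistakes that
should be surfaced.

The resulting rigid map `p′ = Rᵀ(p − origin)` is exposed as a
`rigid_transform`, serialisable as a row-major 4×4 homogeneous matrix in
a JSON sidecar tagged with the LPS convention. NIfTI volumes, which carry
RAS affines, are converted at the I/O boundary by negating the x and y
world axes.

## Co-registration and resampling

Expressing each modality's volume in its own LSCC frame co-registers the
pair; `cross_modality_transform()` returns the implied CT→MR world map
`F_MR ∘ F_CT⁻¹`. `resample_to_frame()` resamples a volume onto an
isotropic grid in frame coordinates, 0.2604 mm by default (the MR
in-plane spacing, so CT is downsampled slightly and MR nearly
preserved), with the frame origin at the geometric centre of the output
volume, `(dims − 1)/2` in index space. Interpolation is trilinear by
default with nearest-neighbour as the option; the output field of view
defaults to the rotated input bounding box, and out-of-field voxels take
a configurable fill value (default 0). Voxel indices are 0-based and map
to world coordinates as `index × spacing` with no half-voxel offset;
repeat-selection differences are then exact multiples of the voxel size,
which is what clinical difference tables show. A half-voxel-centre
convention is available for interoperability with tools that use it.

## The evaluation statistics

Reliability of the landmark *selection* is assessed coordinate-wise with
the intraclass correlation under the **two-way random effects, absolute
agreement** model. With between-subject, between-measurement and error
mean squares MSR, MSC, MSE from the n × k layout:

$$ICC(A,1) = \frac{MSR - MSE}{MSR + (k-1)MSE + \frac{k}{n}(MSC - MSE)},
\qquad
ICC(A,k) = \frac{MSR - MSE}{MSR + (MSC - MSE)/n}$$

Absolute agreement (not consistency) is the right model here: a rater
with a constant offset produces perfectly *correlated* but clinically
different coordinates, and MSC in the denominator penalises exactly that.
The null hypothesis ICC = 0 is tested with F = MSR/MSE on
(n−1, (n−1)(k−1)) degrees of freedom; for a non-zero null the
McGraw–Wong denominator with Satterthwaite degrees of freedom is used.
Both single- and average-measure forms are always computed; the
single-measure form is the default reported `r` since a single expert's
selection, not an average, is what enters clinical use. A zero-variance
matrix (identical cells) returns r = 1 with a `degenerate` flag rather
than the 0/0 `NaN` of the raw formulas.

`intra_rater_report()` treats one rater's two attempts as the k = 2
measurements; `inter_rater_report()` first averages each rater's two
attempts, evaluates all three rater pairs, and reports the **worst pair**
per landmark × coordinate. "Worst" means lowest single-measure r; because
the lowest-r pair and the largest-mean-difference pair can disagree, the
latter is also recorded (`worst_by_diff_pair`). Differences are
summarised as mean/SD/max of *absolute* values.

Accuracy is measured on landmarks that played no part in the frame: the
superior-canal apex on each side. `accuracy_report()` builds each
modality's frame from the componentwise **medians** of the six selections
per landmark (median, not mean, to resist the occasional transcription
error), maps each modality's SSCC medians into its own frame, and
compares CT against MR: per-coordinate ICC and differences, pooled
Euclidean **target registration error**, and Bland–Altman mean difference
with 95% limits of agreement (mean ± 1.96 SD). `target_registration_error()`
refuses LSCC labels by construction — TRE on frame-defining landmarks
would be fiducial registration error, a biased measure.

The **planarity check** (`planarity_report()`) quantifies the modelling
assumption that both lateral canals lie on one plane: per patient, the
four median landmarks are compared with their orthogonal projections on
their own best-fit plane, pooled over landmarks and patients within each
modality (4 × n pairs per coordinate).

## The synthetic study

`phantom_spec()` describes the whole observation process; its defaults
are the study conditions the evaluation assumes:

| parameter | default | meaning |
|---|---|---|
| `n_patients` | 20 | subjects, each imaged in CT and MR |
| `spacing` | CT 0.15³, MR 0.2604×0.2604×0.3 mm | acquisition grids |
| `plane_tilt_deg` | 20° | canal-plane tilt from the world horizontal |
| `canal_arc_radius` | 3.2 mm | lateral-canal arc radius (landmarks at ±radius along y) |
| `inter_ear_separation` | 66 mm | distance between canal centres |
| `sscc_arc_radius` | 3.4 mm | superior-canal arc; its apex is the probe landmark |
| `jitter_sd` | A (0.12, 0.08, 0.08); B (0.08, 0.06, 0.06); C (0.12, 0.09, 0.08) mm | per-rater selection jitter |
| `patient_translation_sd`, `patient_rotation_sd` | 2 mm, 2° | head-positioning variability |
| `anatomy_sd` | radius 0.2, separation 2.5, SSCC radius 0.25, apex y 0.5 mm | between-subject anatomy |
| `modality_pose` | CT identity; MR small rotation + shift | scanner pose difference |

Choices worth explaining:

- **Selection jitter** is Gaussian, anisotropic, largest along x: the
  junction landmarks are defined where the canal meets the vestibule, and
  the ambiguity runs along the canal, which is predominantly the
  right–left direction. The magnitudes (~0.5–1 CT voxel) give
  repeat-selection difference tables in the 0.05–0.25 mm range typical of
  expert raters at these resolutions.
- **Quantization** is nearest-voxel: a rater clicks a voxel, so every
  stored coordinate is a multiple of the spacing, and attempt-to-attempt
  differences come in voxel-size steps.
- **Between-subject anatomy variation** exists because agreement
  statistics computed *across patients* need between-subject variance to
  mean anything. Head pose provides it in world coordinates (intra- and
  inter-rater tables), but frame coordinates normalise pose away, so the
  SSCC accuracy ICC would be comparing pure noise if every synthetic
  subject had identical canals. The SDs are small fractions of the
  structure sizes, in line with reported inter-subject variability of
  canal geometry.
- **Tilt sense**: the generator tilts the canal plane by −20° about +x so
  that the standard +20° frame rotation returns a canonical-pose subject
  to upright — the same geometry the visualisation rotation was designed
  for.
- The phantom rasterizer renders each lateral canal as a half-torus arc
  *ending exactly at the junction landmarks*, a vestibule ellipsoid whose
  surface passes through them, and a superior-canal arc whose apex is the
  probe landmark; CT-like contrast is dark fluid in bright bone, MR-like
  is the inverse. It supports visual and resampling checks; it does not
  attempt partial-volume effects, MR distortion or bias fields, noise
  textures, or anatomically realistic labyrinth shape — conclusions about
  those must come from real data.

What passing tests on this generator do show: the geometric construction
is exact and equivariant, the statistics match their definitions, and the
pipeline's end-to-end error behaves lawfully (grows with selection noise,
bottoms out at the quantization floor). What they cannot show: how real
experts disagree, or how real anatomy deviates from the generator's
idealised canals.

## Numerical choices and edge cases

- Internal tolerances are fixed constants: orthonormality and inverse
  consistency 1e-10, plane-normal unit length 1e-12, degeneracy
  (collinearity/coincidence) 1e-9 relative. They are not configuration.
- Degenerate landmark configurations (collinear points, coincident
  midpoints) raise classed errors (`lsccframe_degenerate_geometry`,
  CLI exit code 3) rather than being repaired.
- In the ICC decomposition the error sum of squares is computed as
  `SST − SSR − SSC` and clamped at zero: for data with an exactly
  constant column offset the subtraction can come out at −1e-16, which
  would otherwise flip the F statistic's sign.
- The quantization floor is genuinely non-monotone: mean axis-angle error
  at jitter σ = 0.05 mm is slightly *smaller* than at σ = 0, because
  sub-voxel noise dithers the nearest-voxel quantizer and the median of
  six dithered selections estimates the true position better than six
  identical undithered ones. The parameter-recovery check therefore
  asserts a strict error decrease over positive σ and a half-voxel bound
  at σ = 0, rather than forcing monotonicity through the floor.
- Simulation sizes in the test suite (patients, seeds per condition,
  Monte-Carlo repetitions) are chosen so the full suite completes in a
  few minutes while keeping Monte-Carlo standard errors well inside the
  asserted tolerances; the statistical law being checked, not the sample
  size, is the point of each test.

## Limitations

- Landmark selection is simulated, not performed; the generator's jitter
  model is the package's assumption about rater behaviour.
- No automatic landmark detection: coordinates come from tables selected
  by humans (or the simulator).
- Rigid registration only — no deformable or intensity-based refinement,
  no DICOM reading (NIfTI and delimited tables only), and no
  intensity normalisation of the resampled volumes.
- The reference reliability tables for the original expert selections can
  only be recomputed from the corresponding coordinate-selection
  workbook, which is not redistributable with the package; the pipeline
  accepts it directly (`read_landmark_table()` on the XLSX export) when
  available.
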