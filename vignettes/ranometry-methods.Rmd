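---
title: "Measurement conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ranometry` quantifies contrast-enhancing tumor burden on 3D segmentation
label maps and assesses longitudinal response the way neuro-oncology
criteria prescribe.  Every number the package reports is the result of a
chain of geometric conventions; this vignette records those conventions,
the tunable parameters, and the reasoning behind the choices that were
genuinely open.

## Coordinates, orientation, resampling

All geometry is computed in physical millimetres with a voxel-centre
convention: the centre of voxel `(i, j, k)` (1-based) lies at
`origin + (c(i, j, k) - 1) * spacing`.  On load, images carrying a valid
orientation are reoriented to the canonical RAS axis order, so the third
array axis is superior–inferior and axial slices are planes of constant
third index; the axial axis can be overridden for unconventional
acquisitions.  `resample_iso()` implements the common 1 mm-isotropic
preprocessing convention by nearest-neighbour label resampling that keeps
the first voxel centre fixed (half-way points resolve upward so
replication counts stay uniform along each axis).  Resampling is
recommended default-on in the pipeline configuration but every measurement
operator also works at native anisotropic spacing, in mm.

Label semantics are always explicit (`label_map` / `enhancing`), because
segmentation tools do not agree on numeric label codes for the
contrast-enhancing class.

## Lesion separation

Lesions are connected components of the binary foreground under
26-connectivity: face, edge or corner contact joins voxels, so a lesion is
separate only if it touches no other lesion anywhere, including corners.
In a single slice this degenerates to 8-connectivity, which is also the
in-plane region rule used by the 2D measurement.  Components are ordered
by descending voxel count with ties broken by the first voxel in array
raster order, so lesion ids are reproducible run to run.  No minimum-size
filter is applied at this stage; size-based filtering is a separate,
opt-in RANO step (below).

## The bidimensional (Macdonald) measurement

1. **Contours.** Each axial slice of a lesion is contoured at the 0.5
   level of its binary indicator (marching-squares convention, background
   padding, holes included).  This makes small-lesion measurements well
   defined: a single voxel at 1 mm spacing contours as a diamond through
   the four face midpoints and measures exactly 1.0 mm, not the corner
   diagonal √2.
2. **Sub-voxel resampling.** Contour vertices are densified along arc
   length at `step_mm` (default 0.1 mm).  The original polygon vertices
   are retained alongside the arc-length samples, so corners — which are
   frequent diameter endpoints — are represented exactly.
3. **Longest diameter.** `d1` is the longest segment between two contour
   vertices of one in-slice region that lies entirely inside the region.
   Containment is verified by sampling the open segment at midpoint
   positions `t = (i - 0.5)/n`, `n = ceiling(length / contain_step)`
   (default 0.2 mm), and testing each sample against the region polygon
   with holes (even-odd rule).  Endpoints sit on the contour by
   construction and are not sampled.  The search scans vertex pairs in
   decreasing length order and stops at the first contained pair, which is
   exact and fast for compact shapes while remaining an exhaustive search.
4. **Perpendicular diameter.** `d2` is the longest contained vertex-pair
   segment of the same slice and region whose undirected angle to `d1`
   lies within 90° ± `tol_deg` (default 2°).  `d2` is *not* required to
   intersect `d1`; only the angle window and containment are enforced.
5. **Optimisation order.** The lesion measurement maximises `d1` over all
   slices and regions first, then `d2` on the winning slice/region —
   lexicographic, mirroring manual calliper practice, rather than joint
   maximisation of the product.  Ties in `d1` (within 1 µm) resolve toward
   the candidate admitting the larger `d2`, then lexicographically by
   endpoint coordinates, so output is deterministic.  If a 3D lesion is
   cut into several in-slice regions, each region is measured
   independently; cross-region chords are never considered because they
   would leave the enhancement.

## The 2.5D measurement

The longest diameter is searched without the axial constraint: endpoint
candidates are the lesion's boundary voxel centres plus the 0.5-level
crossing points on grid edges (the midpoints between a foreground and a
background voxel centre), which keeps the convention consistent with the
2D contour vertices — a single voxel measures 1 mm in either mode — and
guarantees the 2.5D `d1` is never shorter than the 2D `d1`.  Containment
uses trilinear interpolation of the binary indicator (≥ 0.5) at the same
midpoint sampling.  A voxel-centres-only candidate mode exists and is what
the brute-force oracle equivalence tests exercise, since a reference
enumeration over voxel centres is unambiguous.

A plane perpendicular to `d1` is then swept along its extent at
`plane_step_mm` (default 0.5 mm).  On each plane the trilinear field is
sampled on a grid at half the smallest voxel size, its 0.5-level
iso-contours are the plane–surface intersection curves, and the longest
fully contained chord between curve points is taken; `d2` is the maximum
over planes.  Containment is tested against all intersection curves of the
plane at once: a chord that crossed background between two separate
sections would be rejected by the 0.2 mm containment sampling itself, so
no per-section bookkeeping is needed.  The unit direction cosines of `d1`
are reported per lesion so the orientation stability of the free diameter
across follow-ups can be inspected — in practice this direction is the
least stable part of the 2.5D measurement.

## Volumetry and sphericity

Volume is voxel counting times the physical voxel volume — exact for the
label map, by definition.  Sphericity is Wadell's
ψ = π^⅓ (6V)^⅔ / A with V the voxel-count volume and A the area of the
triangulated 0.5-level surface, meshed by marching tetrahedra.  Meshing
the raw binary indicator would inflate A on curved surfaces with
half-voxel staircase facets (a digital sphere would read ψ ≈ 0.78), so the
indicator is first supersampled 2× and box-smoothed once at the fine
scale.  This flattens the staircase while rounding genuinely sharp edges
by only about half a voxel: a 20 mm digital sphere at 1 mm voxels measures
ψ ≈ 0.97 (doubling its size changes ψ by < 0.01), and a 20 mm cube
measures ψ ≈ 0.84 against the ideal 0.806.  The residual edge-rounding
bias decays like one over the edge length, which is why the validation
suite uses cubes a couple of dozen voxels across.  For lesions only a few
voxels across, the voxel-count volume and the mesh disagree at the
half-voxel scale and ψ may exceed 1; such values should not be
interpreted.

## Discretization bias of maximum-seeking measurements

The diameter searches are maximum-seeking: they return the longest chord
the discrete contour supports.  The 0.5-level contour of a 1 mm
voxelization carries half-voxel surface relief, and near-antipodal relief
features pair into chords up to ~0.5 mm longer per endpoint than the
analytic diameter.  On a 20 mm digital sphere the measured `d1` and `d2`
are ~20.3–20.8 mm (+2–4 %) and the 2D product is 425 mm² (+6 %) — the
value any faithful exhaustive search returns for this construction, as the
suite's independent all-pairs oracles confirm to 1e-6 mm.  The bias is
hard-bounded by one voxel per diameter, shrinks with resolution, and is
shared by consistent measurements across time points, so relative change —
what response assessment actually uses — is affected far less than the
absolute values.  Volume has no such bias.

## RANO rules

Defaults: measurability threshold 10 mm on *both* diameters (inclusive, so
`d1 = d2 = 10.0` is measurable), at most 5 target lesions ranked by the
per-lesion value of the metric being aggregated (2D product for SPD,
volume for volume totals; ties by lesion id), progression thresholds 25 %
(2D SPD) and 40 % (volume) over the nadir, comparison inclusive (≥).  Both
filters are **off** by default: for automated segmentations, which tend to
fragment recurrence along resection-cavity walls into many small lesions,
discarding sub-threshold fragments discards real burden, so the
recommended default considers all detected lesions and reports filtered
aggregates alongside.  The measurability threshold is applied in mm
regardless of voxel spacing; at strongly anisotropic native spacing it is
the user's responsibility to resample first if strict comparability with
the 1 mm convention is needed.

## Longitudinal assessment

* **Trends** between adjacent time points are increasing / decreasing /
  constant with a relative tolerance `rel_eps = 1e-9` for "constant" —
  effectively exact equality, since continuous burden measures rarely tie;
  the tolerance is configurable.  Cohort trend agreement pools all
  transitions over all patients into one percentage (a per-patient
  breakdown can be formed by calling the function per series).
* **Spearman's rank correlation** is the Pearson correlation of
  average-tie ranks; zero rank variance is an error, not silently NA.
* **ICC** is the two-way, single-measurement *consistency* coefficient
  ICC(3,1) = (MS_subjects − MS_error)/(MS_subjects + (k−1) MS_error),
  computed from the additive two-way ANOVA.  Consistency (not absolute
  agreement) is the right variant because response assessment evaluates
  relative change only: a constant segmentation-tool offset is harmless
  and the coefficient is invariant to it.
* **TTP** scans time points in order with a running reference: the minimum
  of all earlier values (`auto`) or the value at the most recent
  expert-flagged nadir (`expert`).  The default uses expert flags when the
  series has any, because a severely under-segmented follow-up would
  otherwise hijack the reference.  Progression is the first time point
  with value ≥ (1 + threshold) × reference; a never-progressing series
  gets TTP = overall survival.  A reference of exactly 0 (complete
  disappearance) followed by any positive burden is called progression and
  flagged (`zero_nadir_call`), since a relative increase over zero is
  undefined; on a scalar burden trace the flag cannot distinguish whether
  the reappearing lesion is itself measurable, so the lesion counts
  reported by the measurement step should be consulted for such cases.
  New-lesion-appearance as a progression criterion is intentionally not
  part of `compute_ttp`: the automated TTP uses size thresholds only, and
  lesion counts are reported alongside for the user.  TTP is weakly
  monotone in the threshold by construction of the running-minimum
  reference, which the suite verifies per series.

## Phantoms

Phantoms are voxelized by the voxel-centre rule (foreground iff the centre
lies inside the analytic solid), the convention consistent with 0.5-level
contouring.  The default centre sits a quarter voxel off the grid centre
per axis: a centre on a lattice symmetry point would align the solid's
symmetry with the grid and pair the half-voxel relief into artificially
long antipodal chords.  Fragmented shells place azimuthal sectors of a
shell belt around a cavity, with arc gaps of at least four voxels so
26-connectivity cannot merge fragments and the fragment count is exact by
construction.  Voxelization volume error is under 3 % for solids at least
8 voxels across.

Growth series scale a sphere's radius by the cube root of the cumulative
volume factor, so true volumes follow `V_t = V_0 ∏ (1 + g_i)` exactly, and
the threshold-crossing index over the running minimum is computed from the
analytic trace.  The sampled validation cohorts draw steps from three
regimes — shrink (×0.7), plateau (×1.0), grow (×2.0), with shrink/plateau
phases preceding growth — so every true relative increase over the running
minimum is either below 1 or at least +100 %, far from the 25 %/40 %
thresholds; the ground-truth crossing day therefore stays unambiguous
under the ≤ 3 % voxelization error of the measured volumes, and
end-to-end recovery can be asserted exactly.  The problem sizes used
throughout validation are 32³–70³ grids at 1 mm, 20-series cohorts of 5
time points, 50 random contour regions up to 24², 20 random lesions up to
12³ and 50 random 16³ label volumes.

What the phantoms deliberately do not emulate: segmentation noise and
false positives, intensity information, registration error between time
points, and longitudinal lesion correspondence.  Passing phantom tests
therefore demonstrates the correctness of the measurement and assessment
machinery given a segmentation, not the quality of any segmentation tool.

## Numerical choices and degenerate inputs

* Containment sampling at midpoints of `n = ceiling(len/step)` equal
  subdivisions — deterministic, endpoint-free, identical in the package
  and in the test oracles.
* Chord ties within 1e-6 mm are collected and resolved by the documented
  tie-breaks; all remaining floating-point comparisons use 1e-9–1e-12
  slack.
* Empty masks yield empty lesion lists and zero aggregates; single-point
  regions yield zero-length diameters with product 0; a lesion with no
  contained perpendicular in the angle window reports `d2` absent and
  product 0.
* The iso-contour level is fixed at 0.5 everywhere (slices, plane
  sections, surface meshing), so 2D, 2.5D and sphericity share one
  definition of the lesion boundary.

## Limitations

Absolute diameters on coarse voxelizations carry the positive
discretization bias quantified above; sphericity is unreliable below ~8
voxels extent; the measurability rule at anisotropic spacing follows the
mm threshold literally; and no multiple-testing correction is applied
across threshold sweeps, which are exploratory by design.
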