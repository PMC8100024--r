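---
title: "Quantitative knee-joint morphometry with boneMorph: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative knee-joint morphometry with boneMorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boneMorph)
```

# What the package measures

`boneMorph` implements the quantitative readouts used to characterise
articular cartilage and periarticular bone in preclinical knee
osteoarthritis (OA) work on the rabbit anterior-cruciate-ligament-transection
(ACLT) model, where one knee is surgically destabilised (the OA joint) and
the contralateral knee serves as healthy control (HT), across sham-operated
(SHAM), placebo (CONT) and risedronate-treated (RIS) arms of eight animals
each:

* **Zoned section morphometry.** On a traced undecalcified section of one
  femorotibial compartment (LFC, MFC, LTP, MTP), a straight region-of-interest
  chord spanning the traced boundaries is split into four equal zones
  (Z1–Z4). Per zone the package reports the non-calcified cartilage
  thickness nCg.Th (surface to tidemark), calcified cartilage thickness
  cCg.Th (tidemark to cement line), their exact sum Cg.Th, the subchondral
  plate thickness SB.Th (cement line to trabecular onset), all in µm, and the
  fibrillation index FI.
* **2D trabecular stereology.** On a binary mask cropped to the standard
  rectangular ROI (2.5 × 1.5 mm femur, 1.5 × 1.5 mm tibia): the areal bone
  fraction Tb.A (%), and the diagonal run-length metrics Tb.N (count of bone
  intercepts), Tb.Th (mean bone intercept, mm) and
  Tb.Sp = (L / Tb.N) − Tb.Th, with L the ROI diagonal length.
* **3D micro-CT-style microarchitecture.** In cylindrical volumes of
  interest (2.5 mm diameter; 2.5 mm deep femoral, 1.5 mm tibial; placed
  anterior/central/posterior and medial/lateral): BV/TV (%),
  model-independent maximal-sphere Tb.Th and Tb.Sp (mm), and plate-model
  Tb.N (1/mm).
* **Statistics.** Shapiro–Wilk and Levene gating between parametric and
  nonparametric branches; Student's t / Mann–Whitney U for two groups;
  one-way ANOVA with Holm–Šidák post-hoc or Kruskal–Wallis with Dunn
  post-hoc for three; specimen-matched Pearson correlation between the 2D
  and 3D trabecular parameters.

Because real specimens are not distributable, every measurement stage is
exercised on synthetic inputs with analytic ground truth: section phantoms,
plate/rod/random-field voxel phantoms, and simulated cohorts.

# Section measurements

## The ROI chord and the ray convention

The ROI chord joins the surface trace's endpoints restricted to the common
support of all four boundaries, with the support measured *along the chord
direction* (the direction and its support are co-dependent, so a short fixed
iteration is used). This makes every downstream quantity invariant under
rigid motion of the traces, which the test suite asserts to 1e-9 relative.

Thickness rays are cast **perpendicular to the chord**, 100 per zone by
default, evenly spaced at zone midpoints. The protocol this emulates does
not say whether distances were taken along surface normals, vertical rays or
nearest-point distances; chord-perpendicular rays were chosen because they
make the definition Cg.Th = nCg.Th + cCg.Th hold *exactly* (the same rays
measure both layers, so the means add), and because they are reproducible —
local surface normals on a fibrillated surface are not. Rays that meet only
one boundary are excluded and counted; a zone with more than half its rays
excluded is reported as missing, mirroring how damaged blocks are excluded
rather than silently averaged.

## Fibrillation index

FI is computed per zone as the ratio of the surface polyline arclength L to
the zone chord width W. The quantity is described in the field as the
"difference" between surface length and a straight line of the same width,
but all reported values of the index are dimensionless numbers slightly
above 1 (roughly 1.006–1.31), which only the ratio L/W produces; a µm
difference is therefore also returned (`excess`) but the index itself is the
ratio. FI is exactly 1 for a straight surface; a semicircular notch of
radius 100 µm in a 1000 µm zone gives the analytic value
(1000 − 200 + 100π)/1000 = 1.1142, which the tests assert, and sinusoidal
surfaces are checked against adaptive-quadrature arclength oracles to 1e-3
across the amplitude range that spans observed FI values.

## Section phantoms

`genSectionPhantom()` builds four boundary polylines: flat layers with
configurable mean thicknesses, a sinusoidal surface undulation (amplitude,
wavelength), and optional smooth seeded roughness on every boundary.
Roughness is drawn at knots one correlation length apart (default 200 µm)
and spline-interpolated, so the surface stays rectifiable — white noise at
1 µm sampling would make arclength blow up, which no stained section does.
Ground truth is computed **from the emitted polylines, never from a
rendering**: per-zone layer thickness as the exact trapezoid integral of the
piecewise-linear boundary gap in the chord frame, FI as the exact clipped
polyline arclength. If injected roughness makes adjacent boundaries cross,
the phantom is regenerated with the roughness halved, with a warning.
Default vertex spacing is 1 µm; at that spacing and 100 rays/zone the
measured thicknesses recover the ground truth to well within 1% (asserted
over 20 seeds).

# 2D trabecular stereology

`diagonalProfile()` samples the mask along the ROI diagonal at half-pixel
steps and merges samples into bone/marrow runs whose lengths sum exactly to
the diagonal length, so the identity Tb.Sp = (L/Tb.N) − Tb.Th holds exactly
by construction on any input. Runs clipped by the ROI corners are counted —
excluding them biases Tb.N low on sparse masks — and a toggle between the
main diagonal (default, matching the standard protocol figure), the
anti-diagonal, or both (averaged) is provided.

Diagonal intercepts cross trabeculae obliquely: on plates of thickness t the
intercept is t/cos θ, so intercept Tb.Th is biased high relative to
model-independent 3D thickness, with equality only when the diagonal runs
along the plate normal. This is the mechanism behind 2D intercept thickness
readings exceeding 3D maximal-sphere readings on the same specimens; the
package asserts the inequality on oblique-plate phantoms and never claims
any particular magnitude.

# 3D local thickness

Tb.Th and Tb.Sp are computed with the maximal-inscribed-sphere definition
(Hildebrand–Rüegsegger): the thickness at a point is the diameter of the
largest sphere that contains it and fits inside the phase. The
implementation (compiled, in `src/`) is

1. an exact separable squared Euclidean distance transform
   (Felzenszwalb–Huttenlocher lower envelopes) from every phase voxel to the
   nearest background voxel centre, with one layer of virtual background
   outside every domain face (a structure cut by the scan border is bounded
   by it, the usual convention for bounded scans);
2. distance-ridge extraction: a voxel is dropped when its sphere lies
   entirely inside a 26-neighbour's sphere; containment chains end at kept
   local maxima, so coverage is preserved;
3. sphere painting, largest first, writing each sphere's diameter onto the
   voxels it covers; the mean over phase voxels (volume-weighted mean) is
   reported.

**Voxel conventions.** The sphere radius is the centre-to-centre distance to
the nearest background voxel minus half a voxel (the phase boundary is taken
midway between centres), while the coverage test uses the centre-to-centre
radius so boundary voxels are painted by the spheres that reach them. This
makes an odd-width slab exact and an even-width slab one voxel low —
thickness errors are budgeted in voxels, not millimetres. For whole-volume
measurements a stereological guard zone (`guard = "auto"`, one maximal
sphere radius) excludes face-adjacent voxels from the mean, because their
sphere radii are truncated by the virtual boundary; inside a cylindrical VOI
the wall *is* the analysis boundary (voxels outside the cylinder are
excluded from both phases), so no guard is applied there and in-VOI Tb.Th is
mildly conservative near the wall.

Tb.N defaults to Parfitt's parallel-plate identity (BV/TV)/Tb.Th, with
1/(Tb.Th + Tb.Sp) available behind `method = "inverse"`; the analysis
software used for such studies does not disclose which definition it
applies, so this is a documented choice. On plate phantoms with period
t + s, the plate-model Tb.N equals the true plate frequency 1/(t + s),
which the acceptance suite asserts to 2%.

## Voxel phantoms and test sizes

Plate phantoms tile space with period t + s; the pattern starts with half a
marrow gap so no plate is cut along its normal by the domain edge, and a
domain that is an exact multiple of the period makes the rendered bone
fraction exactly t/(t+s). Rod phantoms are axis-aligned cylinders on a
square lattice with the axes snapped to voxel centres (a sub-voxel lattice
offset would smear the inscribed-sphere diameter by up to a voxel for no
physical reason). The 3D recovery suite runs plates (t = 0.15 mm,
s = 0.30 mm) on a 1.8 mm cube at 10 µm voxels — 180³, four full periods —
and rods (r = 0.1 mm, pitch 0.5 mm) on up to 2 mm cubes; these sizes keep
the analytic values exact while the whole suite stays in the minutes range
on one CPU.

Random-field phantoms threshold a smoothed Gaussian field at the empirical
quantile of the target bone fraction (so the rendered fraction is exact to
a pixel). The default field has a transverse correlation length of 0.08 mm,
which puts the thresholded strut widths at the 0.10–0.16 mm scale that 3D
micro-CT reports for rabbit subchondral trabeculae (Tb.Th ≈ 0.16 mm,
Tb.Sp ≈ 0.11 mm), and an axial correlation 2.5× longer, reflecting the
preferential orientation of subchondral trabeculae along the loading axis —
which is also the VOI axis. The anisotropy matters for the coupled 2D/3D
suite: a single 1.5 × 1.5 mm mid-plane samples few structural elements, and
with an isotropic field the plane's areal fraction is a noisy estimate of
the cylinder's volume fraction; with the axially elongated (more
plate-/column-like) structure the mid-plane is representative and the
Tb.A ↔ BV/TV coupling across 30 phantoms spanning bone fractions 0.30–0.70
is consistently strong (r ≈ 0.85–0.95). What these phantoms do **not**
emulate: stain appearance, scanner noise, beam hardening, partial-volume
grey levels, cortical/trabecular transitions — so green tests certify the
measurement pipeline's geometry and statistics, not robustness to real
acquisition artefacts.

# Cohort simulation

`genCohort()` draws every cell record — (group, joint, compartment, zone,
parameter) — from a normal distribution truncated at zero with the cell's
configured mean and SD, via the inverse-CDF map (exact, no rejection loop).
Truncation was chosen because every simulated quantity is physically
positive; it shifts the effective mean noticeably only in the one or two
printed cells whose coefficient of variation is extreme. The built-in
parameterization (`cohortDefaults()`) encodes the published group-level
means and SDs of the three-arm rabbit ACLT design, transcribed as printed,
including apparent typographical oddities — they are the study conditions,
not quantities to clean up. Group sizes default to 8/8/8 with SHAM reducible
to 7 (one sham animal died in the emulated design). Raw per-animal values
were never published, so only table-level moments can be matched; the
between-zone correlation within an animal is unknown and therefore
configurable on the latent scale (`betweenZoneCorrelation`, default 0,
exchangeable via a shared latent normal).

The power property checked in the acceptance suite uses the placebo-control
medial-tibial-plateau total cartilage thickness in the outermost zone
(CONT-OA 650.23 ± 131.00 vs CONT-HT 472.43 ± 65.06 µm), the largest printed
OA-vs-HT contrast of that parameter (standardised difference ≈ 1.7 SD, the
only magnitude for which a two-sample design at n = 8 has ≥ 80% power); the
gated two-group pipeline flags it in ~85% of simulated cohorts and flags
fully null cohorts at ~5%.

# Statistical pipeline

* **Gating** is per comparison and strict: parametric only if *every* group
  passes Shapiro–Wilk at α and Levene (classical mean-centred form) passes
  at α. Groups with n < 3 or zero variance force the nonparametric branch
  with a warning. A Levene failure with normality intact is routed
  nonparametric rather than to a Welch correction — the strictest reading of
  the emulated protocol.
* **Two groups:** pooled-variance Student's t (the protocol names Student's
  test, and the gate has already required variance homogeneity) or
  two-tailed Mann–Whitney U, exact at the study's group sizes (no ties,
  n ≤ 49). OA vs contralateral HT is compared *unpaired* by default because
  the emulated protocol names unpaired tests, although the design is
  within-animal; `paired = TRUE` is available.
* **Three groups:** one-way ANOVA with pairwise pooled-SD t contrasts under
  Holm–Šidák step-down (sorted ascending,
  adj p_(i) = 1 − (1 − p_(i))^(m−i+1), running-maximum monotone); or
  Kruskal–Wallis with Dunn's tie-corrected rank z tests under the same
  Holm-style step-down, since the protocol names Dunn's test but not its
  correction.
* **No correction across cells.** Dozens of cells/parameters are each tested
  at α = 0.05 with per-cell significance flags only, matching the emulated
  reporting; this is a documented limitation, not an oversight.
* **2D↔3D correlations** are specimen-matched Pearson coefficients with
  per-method means ± SD, one row per parameter pair (Tb.A ↔ BV/TV, Tb.Th,
  Tb.Sp, Tb.N).

# The pipeline and reproducibility

`runPipeline()` chains section phantoms → cartilage measurement, coupled 3D
phantoms → VOI + mid-plane measurement, the correlation table, cohort
simulation, and the per-cell statistics into one run directory (tidy CSVs
plus a log with versions, the full parameter echo and aggregated warnings).
All randomness flows through one master seed from which stage seeds are
derived; a repeated run is byte-identical, which the tests assert. A thin
command-line wrapper sits in `inst/scripts/run_pipeline.R`.

```{r demo, eval = FALSE}
res <- runPipeline(defaultRunConfig(seed = 1), "run1")
res$correlation
```

# Numerical choices and degenerate inputs

* Zone boundaries are exact quarters of the chord; zone means use midpoint
  rays, whose error on the piecewise-linear phantoms is far below the 1%
  recovery budget.
* Thickness and FI propagate missing values explicitly (`NA`), never by
  dropping rows.
* All-marrow masks yield all-missing intercept metrics with a warning;
  all-bone masks yield Tb.N = 1, Tb.Sp = 0 exactly.
* An empty phase in local thickness returns `NA` with a warning; a phase
  with no background at all is bounded by the domain.
* Plate/rod specs reject resolutions that cannot resolve the structure
  (voxel ≥ t) and warn beyond t/5.
* Cohort cells without a parameterization are rejected by name.

# Known limitations

* Inputs are traced polylines and pre-thresholded binary rasters;
  segmentation of stained slides and grey-level CT thresholding are out of
  scope.
* The fibrillated-surface convention (first intersection from above on
  overhangs) mimics a human tracing the visible surface; true overhanging
  fissures are not represented in the phantom family.
* In-VOI thickness is conservative near the cylinder wall (see the guard
  discussion above).
* Animal/limb nesting is not modelled (no mixed-effects analysis), matching
  the emulated protocol.
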