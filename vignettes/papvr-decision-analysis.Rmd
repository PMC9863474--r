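---
title: "Methods: the PAPVR ratio and its decision analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the PAPVR ratio and its decision analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(papvrscore)
```

## The clinical problem and the score

In right partial anomalous pulmonary venous return (PAPVR) one or more
pulmonary veins drain into the superior vena cava or right atrium, usually
alongside a sinus venosus defect (SVD). The repair is chosen by geometry:
veins close to the defect can be baffled to the left atrium through it
(single patch, or double patch when the cava must also be enlarged), while
veins draining high — near the azygos vein — favour a Warden procedure
(caval transection, reimplantation into the atrial appendage, intra-atrial
baffling). Each choice carries asymmetric risks: a long intra-atrial baffle
can obstruct venous return, while an unnecessary Warden exposes adult
patients to a prosthetic conduit and anticoagulation.

The PAPVR ratio turns this judgement into a number. With three landmarks on
a 3D reconstructed model — the superior rim of the most cranial anomalous
pulmonary vein (PV), the superior rim of the SVD, and the inferior rim of
the azygos vein — two distances are measured and combined:

$$r \;=\; \frac{d_{PV,SVD}}{d_{PV,SVD} + d_{PV,azygos}} \in [0,1].$$

The denominator normalizes by the length of the caval segment the vein can
occupy, so $r$ is the fractional position of the vein between defect and
azygos. It is invariant under rigid motion and uniform scaling of the
anatomy — a property tested explicitly — which is what makes one cutoff
applicable from infants to adults, independent of body surface area.

**Classification direction.** High ratios (vein far from the defect, close
to the azygos) predict Warden; the rule is `WARDEN iff ratio > cutoff`,
strictly, so a patient exactly at the cutoff is called patch. Published
descriptions of this score are internally inconsistent about the direction
(some passages place Warden below the cutoff); the group means (Warden
0.85 vs patch 0.51/0.62) and the prospective Warden ratios (0.99, 0.82,
0.88, all described as above 0.68) admit only the high-ratio reading, which
this package follows and states prominently rather than silently fixing.

**Distance definition.** Distances are straight-line Euclidean chords
between landmark points, not geodesics along the vessel wall. The source
material specifies only "distance in mm" on 3D models; the chord is the
simplest reproducible reading, and a geodesic would require the full
segmented surface, which is out of scope. Users whose annotation protocol
measures along the caval axis should be aware the two definitions diverge
on curved anatomy.

## Measurement pipeline

`read_landmarks()` parses a strict key-value sidecar (one `patient_id`
line, three `landmark <name> x y z` records in millimetres); anything
unexpected is an error, because silent tolerance in a clinical measurement
format is worse than a failed run. Landmarks must be pairwise separated by
more than 1e-6 mm — below that, annotation is considered degenerate.

When a triangulated surface (ASCII or binary STL) is available,
`snap_to_surface()` optionally replaces each landmark by its
Euclidean-nearest mesh vertex and reports the displacement, guarding
against annotations typed slightly off the model. Snapping is off by
default: authored coordinates are authoritative. Two landmarks snapping to
the same vertex abort the run. `measure_anatomy()` then produces the two
distances, and `papvr_ratio()` the score; ratios are never rounded
internally, only in human-readable reports (2 decimals).

## Cutoff derivation

`roc_curve()` builds the empirical ROC of ratios against the binary
outcome (Warden vs patch, the three-class labels collapsed). Candidate
thresholds are the midpoints between consecutive distinct sorted ratios
plus a sentinel 0.01 below the minimum and above the maximum: midpoints
make classification under the strict-inequality rule unambiguous, so the
reported cutoff is a midpoint by construction, not an observed score. AUC
is the trapezoid over (1 − specificity, sensitivity); the suite verifies it
equals the tie-aware Mann–Whitney probability that a random Warden ratio
exceeds a random patch ratio, on every tested cohort.

`optimal_cutoff()` maximizes Youden's J = sensitivity + specificity − 1.
The optimality criterion was genuinely open — the source phrase "maximum
sensitivity and specificity" names no statistic — and Youden is the
standard joint reading consistent with the quoted operating point (0.93,
1.0); closest-to-corner alternatives are deliberately not offered. Ties are
broken toward higher specificity, then the lower threshold: the cost
asymmetry above argues against over-calling Warden. If no threshold
discriminates at all (max J ≤ 0, e.g. all ratios identical) the function
warns and returns the lowest sentinel — a flagged degenerate outcome, not a
recommendation. Selection is verified against an exhaustive brute-force
sweep on small cohorts and against an independent ROC implementation.

No bootstrap confidence interval is attached to the cutoff; the analysis
this package reproduces reports none, and adding one is future work.

## Cohort statistics

`summarize_cohort()` reports per-procedure n, mean and sample SD (n − 1;
undefined for singleton groups). Which between-group contrast underlies a
published per-row p-value is often ambiguous, so the summary computes both
the omnibus test across groups and each group-vs-rest contrast, labelled
explicitly. `compare_groups()` in `auto` mode uses a Welch t-test (the
safer unequal-variance default) when there are exactly two groups and both
pass a Shapiro–Wilk screen at α = 0.05 with n ≥ 3; otherwise the
Kruskal–Wallis rank-sum test — the only rank test applicable to two or more
independent groups, despite occasionally being conflated with the signed-rank
test in clinical reporting. All tests are two-sided; no multiplicity
correction is applied, matching the analysis being reproduced.
`association_test()` uses Fisher's exact test for 2×2 tables with any
expected cell below 5, else Pearson's chi-square without continuity
correction, and reports the cross-product odds ratio for 2×2 tables.

## The synthetic cohort generator

No imaging data accompany the published analysis, so `sample_cohort()`
generates anatomies whose *score distributions* match the published
per-procedure calibration: ratio ~ Normal(μ, σ) truncated to (0.01, 0.99)
with presets 0.51 ± 0.08 (single patch), 0.62 ± 0.09 (double patch),
0.85 ± 0.10 (Warden). Truncation keeps draws inside the score's domain;
note it biases the Warden mean low by about 0.016 (the upper bound sits
1.4σ above μ), so large-sample Warden means settle near 0.834 — inside the
±0.02 calibration tolerance the tests assert, but a real property of the
generator worth knowing.

Each patient's total span $d_{PV,SVD} + d_{PV,azygos}$ is drawn uniformly
from 20–60 mm — plausible caval segment lengths from pediatric to adult —
and the three landmarks are placed collinearly along a randomly oriented,
randomly positioned axis so the measurement pipeline inverts *exactly* to
the drawn ratio (asserted to 1e-9). The span is irrelevant to the ratio by
scale invariance, which a test also asserts. An optional perpendicular
Gaussian jitter (`jitter_mm`) emulates annotation noise, at the documented
cost that measured ratios then deviate from drawn ones.

Group sizes: the published 30-patient cohort never prints its procedure
split. The default preset weights are 7/30, 8/30, 15/30
(single/double/Warden) because 15 Warden patients is the only split at
n = 30 under which the reported sensitivity 0.93 is a simple fraction
(14/15). This is a documented assumption, configurable via `presets` and
exactly enforceable via `group_sizes`. Labels are otherwise drawn from the
weights, so realized splits vary.

The generator emulates the statistical structure of the cohort — score
distributions, spans, seeded reproducibility — and nothing anatomical:
no vessel curvature, no real annotation error model, no imaging artefacts.
Passing tests therefore demonstrate that the *analysis machinery* is
correct and calibrated, not that the score performs as published on new
clinical images.

`prospective_fixture()` reproduces a six-patient prospective validation:
the three Warden ratios are the reported 0.99, 0.82, 0.88; the three
patch-side ratios were never published, so the fixture uses synthetic
stand-ins (0.50, 0.55, 0.62) flagged `source = "synthetic"` so they cannot
be mistaken for clinical data. `sample_mesh_fixture()` builds a tubular
STL whose wall passes exactly through the (collinear) landmark line, giving
an end-to-end snap-and-measure fixture with known ground truth.

## Problem sizes and numerical choices

The calibration checks use n = 1000 per group (standard error of the mean
≈ 0.003, comfortably inside the ±0.02 band); cutoff recovery and group
separation use 500 simulated 30-patient cohorts, which keeps the full suite
and the acceptance script in the tens-of-seconds range on one CPU while the
Monte-Carlo error of the median cutoff stays near 0.002. Ratios are exact
rational operations on measured doubles; rigid-motion invariance is
asserted at 1e-9 relative, round-trip exactness at 1e-9 absolute, and the
Mann–Whitney/AUC identity at 1e-12. Seeds fix every stochastic path:
identical spec + seed reproduces cohorts, and whole run directories,
byte for byte.

## Known limitations

- The cutoff recovered by simulation concentrates near 0.71–0.72 rather
  than exactly 0.68: with a perfectly specified generator the Youden
  midpoint between a patch mixture centred near 0.56 and a Warden group
  centred near 0.84 naturally sits there, and the published 0.68 reflects
  one specific empirical sample that was never released. The acceptance
  tolerance (±0.07) encodes exactly this calibrated-simulation status.
- Straight-chord distances; no geodesics (above).
- No DICOM/MRI ingestion, segmentation, mesh repair or centerline
  extraction; landmark coordinates are assumed already expressed in
  right-handed Cartesian millimetres.
- The multi-class single-vs-double patch distinction is out of scope; the
  decision analysis is binary by design.
- `sample_mesh_fixture()` requires collinear landmarks and is a test
  fixture, not an anatomical model.
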