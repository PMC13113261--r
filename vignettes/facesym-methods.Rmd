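---
title: "Reference-free facial asymmetry from paired landmarks: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free facial asymmetry from paired landmarks: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FaceSym)
```

## The measurement model

FaceSym treats one facial photograph as a set of indexed 2-D landmarks in
pixel coordinates (x rightward, y downward). Bilateral facial structures
come in mirror-corresponding left/right landmark pairs; in a symmetric,
horizontally aligned face the segment connecting the two members of a pair
is horizontal. Peripheral facial palsy breaks this: the affected side
droops, and the connecting segments tilt.

The pipeline has three measurement stages.

**Midline estimation and head alignment.** The facial midline is fitted to
the central-axis landmarks by ordinary least squares in the orientation
`x = a + b·y`. This orientation matters: a facial midline is vertical up
to head tilt of at most a few tens of degrees, so regressing x on y is
well-conditioned exactly where regressing y on x degenerates. The fit uses
the centred normal equations, which return slope exactly 0 for an exactly
vertical midline (QR-based solvers leave ~1e-18 residue that would
propagate into every downstream "exact zero" property). The landmark set
is then rotated rigidly by `α = atan(b)` about the image centre
`((w−1)/2, (h−1)/2)`, which maps the fitted midline direction `(b, 1)`
onto the vertical. Rotating coordinates rather than resampling pixels
keeps the metrology path free of interpolation noise; overlays reuse the
same transform. A single fit-and-rotate pass is used — no iteration —
because alignment is idempotent up to floating point. If landmarks are
noisy the OLS fit is not exactly equivariant under rotation (the residual
direction is fixed to horizontal), which is why only noise-free landmark
sets satisfy the 1e-6-degree rotation-invariance bound; with real
detector noise the residual sensitivity is small but nonzero, and the
rotation sweep exists to quantify exactly that.

**Pair angles.** For each registered pair the signed angle is
`θ = (180/π)·atan2(yR − yL, xR − xL)` degrees, positive when the
right-side point sits lower in the image. The sign is kept in the feature
vector (it encodes which side droops and is used by direction-aware
rendering); only the score takes magnitudes. Coincident pair points yield
θ = 0 with a logged warning, following the atan2(0, 0) convention, so a
degenerate detection never aborts a batch run.

**Scores.** The asymmetry score of a pair subset S is the mean of
|θ| over S, in degrees — 0 for perfect symmetry, bounded by 180. Region
scores restrict S by the registry's region labels; because all scores are
means, the full-subset score is exactly the pair-count-weighted mean of
its region scores, a decomposition the test suite asserts to 1e-12. Per
dataset (one session of nine standardized expressions) the overall "all"
score is the unweighted mean of the nine expression scores.

## Pair registries

Which landmark indices pair up, which form the midline, and which reduced
subsets exist is *data*, not code: a `PairRegistry` (JSON asset) carries
`{name, n_landmarks, midline_indices, pairs[{left,right,region}],
subsets}`. Shipped registries:

* `dense-225` — 478-landmark dense mesh: 225 pairs, 20 midline landmarks
  (the mesh's central axis minus eight mouth-axis landmarks), stored
  140/91/50/21-pair subsets; the 91-pair subset splits into 24 eye, 23
  nose and 44 mouth pairs.
* `sparse-29` / `sparse-21` — 68-landmark layouts: 29 pairs with 6 midline
  landmarks (four mouth landmarks excluded), and the contour-free 21-pair
  reduction.

The *counts* are fixed by the method; the *index identities* shipped here
are a schematic reconstruction laid out by bilateral symmetry, because no
canonical index table is published for the method and the package must
not depend on any particular detector's mesh convention. Swapping in a
mesh-specific registry is a pure configuration change, and every pipeline
stage is registry-parametric.

## Selection of informative pairs

Clinical grades follow the Stennert index: rest 0–4, movement 0–6, higher
is worse. Analysis units default to sessions (one dataset = one unit),
because grades are recorded per dataset and patients' grades change under
therapy; `unit = "patient"` pools a patient's images but insists on
constant grades (a strict reducer) and errors otherwise rather than
silently averaging grades.

Per unit and pair, deviations are the mean |θ| over the unit's images.
Per pair and condition, η² = SS_between/SS_total from one-way ANOVA
measures the fraction of deviation variance explained by grade (η² = 0
when SS_total = 0; single-observation grade levels are retained — the SS
arithmetic is valid — with a logged warning). Thresholds t = 0.001…0.400
in steps of 0.001 are swept; S(t) keeps pairs with η² strictly greater
than t in *both* conditions, so S(t) is nested and non-increasing in t.
Each distinct non-empty subset is scored per unit and tested by
Kruskal–Wallis across rest grades and across movement grades (tie-corrected
H, chi-square p on k−1 df). The chosen subset maximizes H_rest + H_move —
the symmetric default; `objective = "min"` is available — with exact ties
broken toward smaller subsets, then lower thresholds. How the two
conditions' H statistics combine into one peak criterion is a genuinely
open design point; the sum treats both conditions symmetrically and the
minimum is the conservative alternative. No multiple-testing correction is
applied anywhere in the selection path (raw p-values are reported);
a Benjamini–Hochberg column can be added to reports but never drives
selection. Spearman correlations (average ranks, two-sided t-approximation
p, α = 0.05) relate subset scores to grades per expression and condition;
degenerate cells (constant scores) are reported as NA rather than
failing the report.

Because selection and evaluation use the same cohort, the sweep is an
in-sample, exploratory feature-selection step — it inherits the selection
bias of any such procedure, which is visible in the synthetic experiments
below and should be kept in mind with small cohorts.

## Rotation robustness

Every image is rotated in-plane from −25° to 25° in 1° steps (0
excluded), the full pipeline re-run, and |Score(r) − Score(0)| recorded
per image; deviations are averaged over all (dataset, expression) images
equally — sessions are not collapsed first — then summarized per rotation
and overall. In `transform` mode the rotation acts on landmark
coordinates; with noise-free landmarks alignment undoes it exactly and
the sweep measures only floating-point rigidity (< 1e-6°, in practice
~1e-14°). Optional per-rotation landmark noise emulates detector
re-localization error and makes the deviation grow monotonically with the
noise scale. `redetect` mode re-runs a detector adapter on resampled
rotated images (bilinear, border-replicating resampling is the adapter's
concern) and reflects real detector variability; it is only available
when an adapter is configured, since the package bundles no detection
model.

## Angle maps

Maps draw one segment per subset pair between the aligned left and right
landmarks, coloured by clipped |θ|: linear interpolation in RGB from blue
`#0000FF` at 0° to red `#FF0000` at the clip (default 5°), constant red
above. The interpolation path (RGB vs a perceptually uniform space) is
not dictated by the method; linear RGB between the two stated endpoints
is the default and the ramp is monotone in |θ| by construction. Output is
hand-assembled SVG because the rendering contract requires byte-identical
files for identical inputs, which raster devices do not guarantee; a
base-graphics `plotAngleMap()` covers interactive use. Blank-background
maps never touch pixel data, so they are privacy-preserving by
construction. Grid renderings arrange sessions (chronological) or cohort
percentile picks (max, 75th, median, 25th, min by the overall score) as
rows against the nine expressions as columns, with the per-row subset
score annotated.

## The synthetic cohort generator

No clinical images or landmark archives ship with the package; all tests
and the acceptance pipeline run on synthetic cohorts with known ground
truth. The generator emulates:

* **Cohort structure** — `nPatients = 60` patients × `sessionsPerPatient
  = 2` sessions × nine expressions (about two sessions per patient
  mirrors a therapy-monitoring archive), 478 landmarks on a 512 px
  canvas.
* **Grades and severity** — the movement grade is uniform on 0–6; a
  continuous latent severity `x_p = max(0, move + U(−0.3, 0.3))` models
  the ordinal grade as a coarsening of a continuous impairment, with
  distinct grades occupying disjoint severity bands; the rest grade is
  the deterministic companion coarsening `clip(round(move·4/6), 0, 4)`.
  Both scales thus grade the same underlying impairment, which is how the
  two-scale clinical index behaves; an additive random disagreement
  between the scales was tried and rejected (see *Design notes*).
* **Asymmetry signal** — the registry's 91-pair subset is informative by
  default: the affected side's landmarks (side drawn per patient) are
  displaced vertically so the pair angle is exactly
  `droopPerGrade · x_p · gain[expression, region]` before noise, with
  `droopPerGrade = 0.8°` per grade unit and a region × expression gain
  (eye pairs amplified ×1.5 during eye/brow expressions 2–4, nose during
  nose wrinkling 5, mouth during mouth expressions 6, 7, 9; the neutral
  expression damped ×0.5).
* **Noise model** — persistent patient-level baseline asymmetry (healthy
  faces are not symmetric): a shared offset on all pairs (SD 0.05°) plus
  per-pair offsets (SD 0.1°), constant across sessions; isotropic
  landmark noise of 1 px per coordinate per image; and uniform in-plane
  head tilt within ±10° per image. Every noise component has its own
  switch, and with all of them off the construction is exact — the basis
  of the exactness and monotonicity tests.

What the generator does **not** emulate: detector-specific error
structure (occlusion, expression-dependent localization bias), out-of-plane
pose, illumination, inter-scale grading disagreement, or grade changes
across a patient's sessions. Passing tests therefore demonstrate that the
*metrology and statistics* are implemented correctly and behave as
designed under controlled conditions — not that any particular detector
reaches clinical accuracy on real photographs.

## Design notes and numerical choices

* **Rotation sign.** With the raster rotation formula
  `x′ = cx + (x−cx)cos α − (y−cy)sin α`, mapping the midline direction
  `(b, 1)` to vertical requires `α = +atan(b)`; the implementation
  asserts the re-fitted slope is < 1e-9 after alignment.
* **Threshold semantics.** "Exceeding" an η² threshold is implemented as
  strictly greater; at 0.001 granularity the choice is immaterial.
* **Tie-breaks.** Sweep ties go to smaller subsets, then lower
  thresholds, making selection deterministic.
* **Generator calibration.** The default noise scales were fixed by a
  Monte-Carlo over 40 seeds before the test seeds were frozen. Two
  earlier designs failed instructively: (i) with *identical* expected
  angles for all same-grade patients, every candidate subset containing
  the informative pairs produced an (almost) identical Kruskal–Wallis H,
  and the sweep's argmax wandered across near-ties — planted-pair
  recovery was a coin flip; (ii) with an additive random disagreement
  between rest and movement grades, units with equal movement grade but
  different rest grades were interleaved in score, and in-sample
  selection bias let chance-aligned noise pairs into the chosen subset.
  The latent-severity design removes both pathologies for a structural
  reason (both group partitions are interval coarsenings of one
  continuous severity, and severity bands of distinct grades are
  disjoint), so recovery is exact rather than marginal, and the
  recovery test checks correctness of the sweep instead of sampling
  luck. The per-pair angle noise floor also constrains the template:
  pair half-widths are kept wide enough (nose ≥ ~30 px at 512 px canvas)
  that 1 px landmark noise maps to at most a few degrees of per-image
  angle noise, as in real face geometry.
* **Degenerate inputs.** Horizontal midlines raise a degeneracy error
  (the midline model assumes near-vertical); all-identical values give
  H = 0, p = 1; zero-variance correlation inputs raise a typed error and
  become NA report cells; empty cohorts produce empty-but-valid files.
* **Serialization.** All floating-point columns are written with `%.17g`,
  so writer → reader round trips are bit-exact and repeated runs are
  byte-identical; run manifests record command, package version, seed and
  input hashes.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run on cohorts of 2–7 patients
for unit-level properties, the full 60 × 2 default cohort for selection
and correlation checks, 50-step rotation sweeps on 3-patient cohorts, and
a 10,000-replicate null calibration of the Kruskal–Wallis wrapper (3 × 15
observations). These sizes were chosen so the whole suite completes in
about a minute on a laptop while still exercising every code path at the
default study structure.

## Limitations

The method compares the two facial halves within one image, so bilateral
palsy — where both sides are affected — cannot be assessed by
construction. Accuracy is bounded by landmark localization and by the
midline estimate; the rotation sweep quantifies in-plane robustness but
out-of-plane pose is not normalized. Selection is exploratory and
in-sample; a held-out validation is the user's responsibility on real
cohorts.
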