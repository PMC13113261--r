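# FaceSym

Reference-free quantification of facial asymmetry from paired 2-D facial
landmarks, for peripheral facial palsy (PFP) research and monitoring.

Peripheral facial palsy causes one-sided loss of facial muscle control and
visible asymmetry. Objective follow-up usually requires either a clinical
grading (e.g. the Stennert index, scored at rest on 0–4 and during
voluntary movement on 0–6) or image-based measures that depend on a neutral
reference photograph of the same patient. FaceSym implements a
*reference-free* alternative: each photograph is analyzed on its own by
comparing the left and right side of the face through dense landmark
pairs.

## The method

For one image with detected landmarks (478-point dense mesh by default;
68-point layouts are supported through pair registries):

1. **Head alignment.** The facial midline is estimated from central
   landmarks by ordinary least squares, fitted as `x = a + b·y` (a facial
   midline is near-vertical, which makes this orientation well-posed). All
   landmarks are rigidly rotated by `α = atan(b)` about the image centre so
   the midline becomes vertical.
2. **Pair angles.** For each registered left/right landmark pair
   `L = (x_L, y_L)`, `R = (x_R, y_R)`, the signed angle of the connecting
   segment against the horizontal is

   `θ = (180/π) · atan2(y_R − y_L, x_R − x_L)`  [degrees]

   The vector `a = (θ_1, …, θ_N)` is the image's asymmetry feature vector;
   positive θ means the right side hangs lower (raster y points down).
3. **Asymmetry score.** For a chosen pair subset S,

   `Score = (1/|S|) · Σ_{i∈S} |θ_i|`  [degrees]

   computed globally or per facial region (eye / nose / mouth). A
   perfectly symmetric face scores 0.
4. **Pair selection.** Against per-dataset clinical grades, each pair's
   discriminatory power is measured by one-way-ANOVA effect size
   η² = SS_between/SS_total in both Stennert conditions; thresholds
   0.001–0.400 (step 0.001) are swept, keeping pairs exceeding the
   threshold in both conditions, and the subset maximizing the combined
   Kruskal–Wallis H across grades is selected (ties towards smaller
   subsets). Spearman correlations relate subset scores to clinical
   severity.
5. **Robustness and rendering.** An in-plane rotation sweep (−25°…25°,
   step 1°) quantifies score stability, and angle maps draw every pair
   segment colour-coded from blue (0°) to red (≥5°), readable as a
   privacy-preserving full-face asymmetry picture.

A seeded synthetic cohort generator (`generateCohort()`) produces
landmark/grade/truth files with grade-dependent, region-localized droop,
patient-level baseline asymmetry, landmark noise and head tilt, so the
whole pipeline is testable without any clinical data or detector model.

## Worked example

```r
library(FaceSym)

cfg <- syntheticConfig(nPatients = 6, seed = 42)   # 6 patients, 2 sessions
coh <- generateCohort(cfg)
res <- analyzeCohort(coh$records, "dense-225", subsets = c("91", "mouth"))

summ <- expressionSummary(subset(res$scores, subset_name == "91"))
summ[summ$expression %in% c("1", "5", "7", "all"), ]
#>  subset_name expression  n  mean    sd   var median   max   min
#>           91          1 12 1.389 0.872 0.760  1.062 2.695 0.528
#>           91          5 12 2.651 2.261 5.114  1.846 5.634 0.551
#>           91          7 12 2.909 2.493 6.216  1.965 6.284 0.540
#>           91        all 12 2.585 2.133 4.548  1.825 5.339 0.586
```

Scores are in degrees: this cohort averages 2.6° of absolute pair angle
over the 91-pair subset, with the dynamic nose/mouth expressions (5, 7)
more asymmetric than neutral (1) — the expected signature of
movement-dependent palsy. Correlating with the generated Stennert grades:

```r
rep <- correlationReport(subset(res$scores, subset_name == "91"),
                         coh$grades)
subset(rep, expression == "all")
#>  condition   rho  p_value  n
#>       rest 0.961 6.85e-07 12
#>       move 0.961 6.85e-07 12
```

On the full default cohort (60 patients × 2 sessions), the η² threshold
sweep recovers the 91 planted informative pairs exactly
(`thresholdSweep()`; precision = recall = 1.0 at seed 1) with a minimum
in-subset η² of 0.88, and the transform-mode rotation sweep keeps the
score stable within about 0.001° across −25°…25°.

Angle maps render as deterministic SVG:

```r
rec <- coh$records[[1]]
al <- alignLandmarks(expressions(rec)[["7"]], midlineIndices(loadRegistry("dense-225")))
av <- pairAngles(al@aligned, "dense-225")
renderAngleMap(al@aligned, av, "dense-225", subset = "91",
               file = "map.svg")
```

A command-line front end over the same functions lives at
`inst/cli/facesym.R` with subcommands `synth`, `analyze`, `select`,
`robustness` and `anglemap`.

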