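# papvrscore

Preoperative decision analysis for **right partial anomalous pulmonary
venous return (PAPVR)**, a congenital heart defect in which one or more
pulmonary veins drain into the superior vena cava or right atrium instead of
the left atrium. The choice of repair — baffling the veins through the sinus
venosus defect with one patch, adding a second patch to enlarge the vena
cava, or a Warden procedure (caval transection and reimplantation) — hinges
on how far the anomalous veins sit from the defect. `papvrscore` is for
surgical teams and methodologists who want that judgement quantified,
audited and reproducible.

## The score

From three landmarks placed on a 3D reconstructed heart model, two
straight-line distances are measured in millimetres:

- *d*(PV, SVD) — superior rim of the most cranial anomalous pulmonary vein
  to the superior rim of the sinus venosus defect;
- *d*(PV, azygos) — the same vein to the inferior rim of the azygos vein.

The **PAPVR ratio** is the normalized position of the vein along the caval
axis:

```
ratio = d(PV, SVD) / [ d(PV, SVD) + d(PV, azygos) ]
```

It is dimensionless, confined to [0, 1] and scale invariant, so it applies
across patient sizes. A ratio **strictly above a cutoff** (0.68 at the
published operating point) predicts a Warden procedure; otherwise
single/double patch repair. The cutoff itself is derived from a labelled
cohort as the Youden-optimal threshold (maximizing sensitivity +
specificity − 1) of the empirical ROC curve of ratios against the performed
surgery.

The package implements the whole pipeline: landmark-annotation and STL
surface I/O with optional nearest-vertex snapping, distance measurement,
scoring and classification, empirical ROC analysis with Youden cutoff
selection, per-procedure cohort statistics (Welch t / Kruskal–Wallis /
Fisher / chi-square), and a seeded synthetic-anatomy generator calibrated to
the published per-procedure score distributions (single patch 0.51 ± 0.08,
double patch 0.62 ± 0.09, Warden 0.85 ± 0.10) so every stage is testable
without imaging data.

## Worked example

```r
library(papvrscore)

# simulate a 30-patient cohort (7 single patch / 8 double patch / 15 Warden)
# and run the full study: measure -> score -> ROC -> cutoff -> statistics
st <- run_study(spec = cohort_spec(seed = 42, group_sizes = c(7L, 8L, 15L)))
print(st)
```

```
<papvr_study>
operating cutoff 0.71 (youden), AUC 0.95
confusion: TP=13 FP=1 TN=14 FN=2 (sens 0.87, spec 0.93)
Mean PAPVR ratio by surgical procedure
  procedure                n   mean     SD
  SINGLE_PATCH             7   0.48   0.07
  DOUBLE_PATCH             8   0.63   0.10
  WARDEN                  15   0.81   0.10
omnibus (Kruskal-Wallis rank-sum): p = 4.96e-05
SINGLE_PATCH vs rest (Welch t-test): p = 5.22e-07
DOUBLE_PATCH vs rest (Welch t-test): p = 0.161
WARDEN vs rest (Welch t-test): p = 6.53e-07
Warden vs patch (Welch t-test): p = 6.53e-07
```

Read: on this simulated cohort the data-derived operating cutoff is 0.71
(close to the published 0.68), the score separates Warden from patch
patients almost perfectly (AUC 0.95; 13 of 15 Warden and 14 of 15 patch
patients correctly called), group mean ratios are ordered single < double <
Warden as the calibration prescribes, and the Warden-vs-patch difference is
decisive (p < 0.001).

Scoring a single patient is one call:

```r
papvr_ratio(30, 10)            # 0.75
classify_procedure(0.75, 0.68) # WARDEN
```

A thin command-line wrapper with `simulate`, `score`, `study` and `fixture`
subcommands lives at `inst/cli/papvr.R`:

```sh
Rscript inst/cli/papvr.R study --simulate --seed 42 --out out/
```

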