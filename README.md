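# organodose

Drug-transport simulation and exposure-corrected dose–response analysis
for patient-derived organoid (PDO) culture platforms.

## The problem

PDO drug screens are run in physically very different formats: organoids
suspended directly in drugged media, organoids embedded in a static
hydrogel under a media overlay, and organoids in a perfused multi-well
bioreactor where drug reaches the gel only by diffusion from a channel fed
by a recirculating reservoir. The same nominal (applied) 5-fluorouracil
concentration then delivers very different local exposures — constant in
media, 50% of the source at equilibrium in an equal-volume static gel, and
a persistent spatial gradient in the bioreactor. Comparing IC50s across
platforms on the applied-dose axis is therefore misleading.

`organodose` puts the three platforms on a common footing:

1. **Transport simulation.** Conservative finite-volume diffusion models
   for each platform. The bioreactor couples the gel field
   *C*(*x*, *t*) to a recirculating reservoir through the channel wall:

   ∂C/∂t = D ∇²C in the gel,
   V_res dC_res/dt = −J(t), C|_lumen = C_res(t),

   with no-flux outer boundaries (closed system, no drug consumption).
   The effective gel diffusivity is calibrated from a single observable —
   the static gel reaching steady state at 24 h — and then held fixed, so
   the bioreactor gradient is a parameter-free prediction.
2. **Exposure metrics.** Region partition of the bioreactor gel (near/far
   of the channel at a 4.5 mm lateral cut), volume-weighted region means,
   trapezoidal AUC (µM·h), day-7 mean concentration and fraction of
   applied dose.
3. **Dose–response.** Min/max-normalized four-parameter logistic fits
   *y* = bottom + (top − bottom)/(1 + (*x*/IC50)^hill) against the
   *effective* (simulated) dose, asymptotic CIs on log IC50, and
   extra sum-of-squares F tests for curve comparison.
4. **Synthetic assays.** Seeded generators for endpoint viability
   luminescence, cumulative lactate time series and organoid
   morphometrics, so the full pipeline is testable without wet-lab data.

## Worked example

```r
library(organodose)
report <- run_pipeline(seed = 1)
print(report)
```

```
<pipeline_report> seed 1 - wall 4.1 s
IC50 fits (uM):
  media                   3.659  [2.836, 4.720]
  static_gel             26.442  [12.822, 54.531]
  bioreactor_region1     23.050  [17.736, 29.957]
  bioreactor_region2     79.732  [22.077, 287.952]
```

The pipeline simulates all three platforms across their dose panels,
generates synthetic viability readouts from the packaged per-condition
ground truths (3.387, 33.96, 22.6 and 69.8 µM), and refits them on the
exposure-corrected dose axis — every fitted IC50 covers its generating
truth. The delivered-dose table at the lowest applied concentrations:

```r
summarize_auc(report)$auc
```

```
   platform  region applied_uM auc_uMh day7_mean_uM fraction_pct
      media   media          1  168.00        1.000       100.00
 static_gel     gel          2  161.45        1.000        50.00
 bioreactor region1          4  223.57        1.727        43.18
 bioreactor region2          4   97.44        1.167        29.18
```

Media at 1 µM delivers exactly 168 µM·h over the week; the static gel at
2 µM delivers a near-identical cumulative dose (161 µM·h) because it
equilibrates to 50% within a day; the bioreactor needs 4 µM to bracket
that dose between its near (224 µM·h) and far (97 µM·h) regions, which
reach 43% and 29% of the applied concentration by day 7. Curve
comparisons reproduce the expected pattern — the media condition differs
from every gel condition, the static gel is indistinguishable from the
bioreactor's near region but not from its far region, and the two
bioreactor regions differ from each other:

```
static_gel vs bioreactor_region1: F(1,41) = 0.05,  p = 0.83
static_gel vs bioreactor_region2: F(1,41) = 14.00, p = 5.6e-04
bioreactor_region1 vs region2:    F(1,41) = 30.00, p = 2.4e-06
```

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/run_pipeline.R",
                                       package = "organodose"))')" \
  --outdir out/ --seed 42
```

writing `exposure.csv`, `auc.csv`, `fits.json` and `report.log`.

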