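# otolithsr

Reconstruction of fish life histories from laser-ablation otolith
⁸⁷Sr/⁸⁶Sr transects, for movement ecologists and otolith geochemists
working in estuaries. The motivating system is a small semi-anadromous
estuarine fish whose population mixes freshwater-resident (FWR),
brackish-water-resident (BWR) and semi-anadromous (SA) phenotypes; the
package reconstructs, for each fish, a daily salinity-habitat chronology
from hatch to capture and classifies its life history — and ships a fully
ground-truthed synthetic-cohort generator so the whole chain can be
validated end to end without any instrument data.

## What it computes

**Signal reduction.** Raw multi-collector ICP-MS per-cycle intensities on
masses 84/85/86/87/88 are reduced to a distance-resolved ⁸⁷Sr/⁸⁶Sr profile:
gas-blank subtraction, ⁸⁷Rb interference correction via the mass-85 channel
(⁸⁷Rb/⁸⁵Rb = 0.385710), exponential-law mass-bias normalization against
canonical ⁸⁶Sr/⁸⁸Sr = 0.1194

&nbsp;&nbsp;β = ln(0.1194 / (i₈₆/i₈₈)) / ln(m₈₆/m₈₈),  R = (i₈₇/i₈₆)·(m₈₇/m₈₆)^β,

and a single-pass 2σ outlier criterion on a 40-point moving window.

**Age alignment.** Cumulative daily increment widths convert age to
proportional otolith radius; a cubic regression B-spline (df = 10) fitted to
ratio vs proportional distance predicts the ⁸⁷Sr/⁸⁶Sr onto the daily age
transect.

**Salinity.** A two-endmember conservative mixing model links water
⁸⁷Sr/⁸⁶Sr to salinity. With seawater fraction f = S/S_ocean,

&nbsp;&nbsp;R(S) = (f·Sr_o·R_o + (1−f)·Sr_f·R_f) / (f·Sr_o + (1−f)·Sr_f),

with ocean endmember R_o = 0.70918, Sr_o = 7.9 mg/L, S_ocean = 35 PSU, and
the freshwater endmember ratio calibrated in closed form so the curve passes
through 0.7075 at the 0.5 PSU freshwater/brackish boundary. The inverse is
algebraic and exact.

**Life-history assignment.** Threshold rule at ⁸⁷Sr/⁸⁶Sr = 0.7075: FWR when
the whole profile stays below, BWR when the natal period (ages 0–30) is
already above, SA when a fresh natal period is followed by a sustained move
above threshold. Dispersal age for SA fish comes from at-most-one-changepoint
(AMOC) mean-shift detection with a Schwarz-type penalty. Unsupervised
grouping uses level-1 Haar DWT approximation coefficients of 170-day
chronologies, Euclidean distances, Ward clustering and a 6-cluster cut.
Cluster structure is validated by PERMANOVA on the three standardized
attributes (natal mean, post-dispersal mean, dispersal age) and jackknifed
quadratic discriminant reclassification. A companion module fits the
binomial logistic maturity model `late ~ JD * sex * region` with AICc,
McFadden R² and likelihood-ratio comparisons.

## Worked example

```r
library(otolithsr)
mx <- calibrate_freshwater_endmember()
mx
#> Two-endmember Sr mixing model
#>   ocean: R = 0.70918, Sr = 7.90 mg/L, S = 35 PSU
#>   fresh: R = 0.70673, Sr = 0.250 mg/L
#>   anchor: 0.7075 at 0.5 PSU

res <- run_pipeline(pipeline_config(
  params = cohort_params(n_fish = 285, seed = 7), n_perm = 999))
res
#> Life-history pipeline run (seed 7)
#>   285 fish -> 285 chronologies, 285 trimmed for clustering (0 excluded)
#>   phenotype recovery vs truth: 100.0%; SA dispersal-age median |error|: 2.0 d
#>   phenotype percentages:  BWR 6, FWR 12, SA 82
res$stats$permanova$pseudo_F   #> 41.1  (SA clusters, p = 0.001)
res$stats$qda$overall_percent  #> 96
```

The manifest lines read: every simulated fish was carried through signal
reduction and spline alignment; classification recovered the true phenotype
of all 285 fish; for semi-anadromous fish the changepoint estimate of the
freshwater-to-brackish dispersal age was within 2 days of truth (median);
and the supervised phenotype split of this seed's cohort is 12% FWR / 6%
BWR / 82% SA. The PERMANOVA pseudo-F and jackknife percentage quantify how
separable the SA clusters are on the three life-history attributes.

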