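---
title: "Reconstructing estuarine life histories from otolith Sr isotopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing estuarine life histories from otolith Sr isotopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otolithsr)
```

## The problem

Otoliths accrete daily calcium-carbonate increments that record the
⁸⁷Sr/⁸⁶Sr of the ambient water. In an estuary, water ⁸⁷Sr/⁸⁶Sr is set by
conservative mixing of river water (low Sr concentration, locally variable
ratio) with seawater (high Sr, globally uniform 0.70918), so a laser
transect from the otolith core to its edge is a proxy record of the salinity
habitat a fish occupied on every day of its life. This package implements
the full chain from raw ablation intensities to classified life histories,
together with a synthetic-cohort generator that provides machine-precision
ground truth for every intermediate quantity.

## The mixing model

With seawater mass fraction $f = S/S_{ocean}$ (river salinity taken as
zero — salt itself mixes conservatively), the water ratio is the
Sr-concentration-weighted mean of the endmember ratios:

$$R(S) = \frac{f\,Sr_o R_o + (1-f)\,Sr_f R_f}{f\,Sr_o + (1-f)\,Sr_f}.$$

Because $Sr_o \approx 7.9$ mg/L dwarfs $Sr_f \approx 0.25$ mg/L, the curve
is very steep below ~6 PSU, which is precisely why otolith ⁸⁷Sr/⁸⁶Sr
resolves the freshwater-to-brackish transition so well, and why it saturates
toward the ocean ratio at higher salinity. The freshwater endmember ratio is
not taken from a fixed water survey; it is calibrated in closed form so the
curve passes through an anchor — by default a ratio of 0.7075 at the 0.5 PSU
freshwater/brackish boundary. The inversion is an exact algebraic solve for
$f$. Ratios that fall below the calibrated freshwater endmember by no more
than a tolerance (default 5e-5, about twice a typical per-day noise SD) are
clamped with a warning; larger excursions are treated as data errors. The
single-freshwater-endmember simplification (one blended river source) is
deliberate: all endmembers are configurable, and a multi-river model would
change the calibration, not the algebra.

```{r mixing}
mx <- calibrate_freshwater_endmember(mixing_params())
mx
salinity_from_ratio(0.7075, mx)
```

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` draws a cohort with three phenotypes (default 12% FWR,
7% BWR, 81% SA) and four SA dispersal-age sub-types (means 113, 93, 72, 51
days; SDs 20, 20, 8, 8 — the two later-dispersing types are wider, the two
earlier ones tighter). Residents hold a near-constant salinity with
multiplicative AR(1) jitter (log-scale SD 0.03, lag-1 correlation 0.9);
SA fish follow a logistic freshwater-to-brackish transition with a 5-day
10–90% width, centred so the 0.5 PSU crossing falls exactly on the true
dispersal age (an offset of $s\,\ln((S_{adult}-0.5)/(0.5-S_{natal}))$ from
the logistic midpoint — this pins the day-scale invariant "fresh before,
brackish after" without a hard step). Dispersal ages are truncated 20 days
from either end of life to avoid degenerate changepoint geometry. Habitat
levels are drawn per fish: fresh natal 0.05–0.2 PSU, brackish 2–4 PSU;
lifespans are uniform on 180–240 days; daily increments are lognormal with
mean 2 µm and SD 0.3 µm.

`simulate_ablation_run()` renders each fish as a raw instrument run: a
leading 20 s gas blank, a 100 µm pre-core segment, then ablation at
10 µm/s with 0.25 s cycles. Intensities honour natural Sr abundances
(⁸⁸Sr/⁸⁶Sr = 8.375), carry configurable Rb contamination on mass 85/87 and a
configurable exponential per-amu mass-bias factor (default 1.002), and
receive multiplicative lognormal noise. The noise model is
plasma-flicker-dominated (lognormal, strongly correlated with signal level)
rather than Poisson shot noise, and the user-facing knob is the resulting
per-cycle ratio SD (default 1e-4). The published description of such runs
reports no noise magnitudes, so these defaults are conventional
LA-MC-ICPMS values and are all configurable.

What the generator does **not** emulate: instrument drift between sessions
(no reference-material correction is modelled), Kr interferences on masses
84/86, ablation-pit geometry effects, age-reading error in the increment
series, or multi-river freshwater sources. Passing tests therefore
demonstrate the internal consistency and statistical behaviour of the
chain under the stated error model — not robustness to every artefact of
real instrument data.

## Numerical and design choices

**Reduction.** The 2σ outlier criterion uses a centred 40-point moving
window, truncated at the series edges, with the point included in its own
window, and runs in a single pass (no iteration to convergence): read
literally, a "2σ criterion" is one pass, and a single pass keeps the
operation order-deterministic. Whether the criterion should use the
windowed SD or a global SD is not fixed by convention; the windowed SD is
used. The Rb correction applies the Sr-derived mass-bias exponent to carry
the mass-85 estimate onto the measured mass-87 scale (common practice).
The core-crossing position comes from run metadata (100 µm offset);
automatic onset detection is out of scope. Reduction steps are single-shot:
re-applying a step to already-reduced data is rejected via state flags.

**Alignment.** "Cubic spline (df = 10)" is read as a regression B-spline
with interior knots at equally spaced quantiles of the observed proportional
distances — deterministic, no smoothing-parameter search. A smoothing spline
at the same equivalent df is available behind the same interface
(`method = "smoothing"`). The fit is never extrapolated: ages mapping
outside the observed distance range take the nearest endpoint fit. A df-10
basis cannot localize a 5-day transition exactly; ringing of order 20% of
the step height extends about one knot spacing (~T/7 days) around the
transition. This is why the pipeline's salinity conversion uses a wider
clamping tolerance (5e-4) than the point-measurement default, and why
changepoint detection is run on the chronology rather than on its
derivative.

**Classification.** "Later life above the threshold" is operationalized as
at least 10 consecutive post-natal days above 0.7075, with the final 5 days
excluded everywhere (edge chemistry can record late return movements that
the scheme deliberately ignores). Single-day excursions therefore never
flip a call. Natal means within 2e-5 of the threshold are flagged
borderline but still classified. Raising the threshold can never turn an
FWR call into BWR/SA (monotonicity), which the tests check explicitly.

**Changepoint.** AMOC with a normal likelihood and pooled variance:
statistic $n\log(RSS_0/RSS_1(\tau))$ maximized over splits with at least 10
days on each side, declared only above a Schwarz-type penalty $2\log n$.
The series is centred first to avoid catastrophic cancellation in the
cumulative-sum RSS. The changepoint runs on the measured ratio, not the
salinity transform: a monotone transform moves the estimate only through
noise, and the ratio is the measured quantity.

**Clustering.** The level-1 Haar approximation uses the orthonormal
convention $a_k = (x_{2k-1}+x_{2k})/\sqrt2$; the mean-based convention
differs by a global factor and cannot change Ward merge order. Coefficients
are not standardized before distances (all coordinates share the ratio
scale). Ward linkage is the Lance–Williams recurrence on squared Euclidean
distances (`hclust`, `ward.D2`), whose merges the test suite checks against
an exhaustive greedy minimal-variance oracle. The 6-cluster cut is a
configurable default, with labels renumbered by descending size; a
within-cluster-variance elbow can be read off the tree heights but is not
used for selection.

**Validation statistics.** PERMANOVA standardizes the three attributes
first (ratio spreads ~1e-3 against age spreads ~60 days would otherwise
make Euclidean distance meaningless) and uses the add-one permutation
p-value with 9999 permutations by default. QDA priors are proportional to
group size; the jackknife is an explicit refit-per-fish loop, so the
reported rate is exactly the leave-one-out reclassification rate, with a
1e-10 diagonal ridge as a singularity fallback.

**Maturity model.** Treatment coding with references sex F and region SP-S;
Julian date is centred on day 76 (the midpoint of the January–May window)
so intercept-scale terms are estimated where the data live rather than
extrapolated to day 0 — centring changes coefficients but not fitted
probabilities, which the tests verify. AICc counts every estimated
coefficient including the intercept.

## Problem sizes used in the tests

The shipped suite validates on cohorts of 285 fish (the headline end-to-end
run, classification fidelity, six-type cluster recovery), 100-fish SA
cohorts for dispersal-age recovery, 400 null replicates for the PERMANOVA
size check (199 permutations each), and 100 random instances for each
oracle-equality property (changepoint, Ward merges, outlier windows). These
sizes give stable Monte-Carlo behaviour at interactive runtimes.

## Known limitations

- The freshwater endmember is calibration-pinned, not surveyed; transferring
  the default calibration to a different estuary requires a local anchor.
- The df-10 spline limits dispersal-age resolution to a few days; fish that
  disperse within ~20 days of hatch can leak brackish signal into the natal
  window and are intrinsically ambiguous under the threshold rule.
- Chronologies shorter than the 170-day trim are excluded from clustering
  rather than padded; the manifest records each exclusion.
- PERMANOVA assumes exchangeability under the null; with strongly unequal
  multivariate dispersions its p-values reflect dispersion as well as
  location differences.
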