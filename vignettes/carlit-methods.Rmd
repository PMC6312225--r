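---
title: "Methods: CARLIT scoring, WFD classification and variance partitioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CARLIT scoring, WFD classification and variance partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carlites)
```

## The index

CARLIT assesses the ecological status of rocky Mediterranean shores from the
dominant macroalgal community of consecutive coastline sectors (typically
50 m each). Each community category carries a sensitivity level
$SL \in [1, 20]$: canopy-forming *Cystoseira* belts and trottoir rims score
20, opportunistic green algae and cyanobacterial films score 3 and 1. Each
sector also belongs to one of six geomorphological relevant situations
(GRS) — the cross of coastal morphology (decimetric blocks, low coast, high
coast) and substrate (natural, artificial) — with a reference quality value
$EQ_i$ observed at unimpacted sites.

The water-body Ecological Quality Ratio is the length-weighted mean of
per-sector ratios,

$$
EQR = \frac{\sum_s \ell_s \, SL_s / EQ_{i(s)}}{\sum_s \ell_s},
$$

capped at 1, and is translated into the five Water Framework Directive
classes: bad $[0, 0.25]$, poor $(0.25, 0.40]$, moderate $(0.40, 0.60]$,
good $(0.60, 0.75]$, high $(0.75, 1]$. Boundaries belong to the lower
class; this convention is fixed by the band wording ("0–0.25", ">0.25–0.40",
…) and by published examples (an EQR of 0.61 is *good*, 0.50 is
*moderate*).

### Scoring conventions

* **Co-dominance.** A sector equally dominated by two categories is
  recorded `A+B` and scores the mean of the two SLs (`Cor+Mgal` scores 7).
  Rare scattered *Cystoseira amentacea* over a dominant community is the
  same mechanism (`CA1+Cor` scores 9). Labels with more than two components
  are averaged with a warning — field protocols only define pairs.
* **Ratio-then-average.** Each sector is divided by the $EQ_i$ of its own
  GRS before length-weighted averaging. Averaging SL first would make the
  divisor ill-defined whenever a water body mixes morphologies.
* **Capping.** Individual ratios may exceed 1 (SL 20 on a low natural coast
  gives $20/16.6 = 1.205$). The cap is applied to the aggregated EQR, not
  per sector, because the ratio scale — not the field observation — is
  bounded; both behaviours are exposed (`cap`, `cap_sectors`) since the
  original method description is silent on the order.
* **Catalogues as data.** The sensitivity and reference tables ship as CSV
  under `inst/extdata` and can be swapped for regional recalibrations;
  seagrass categories (Pos, Cym, Zos) pass through the GRS lookup exactly
  like macroalgal ones.
* **Trottoir.** The mediolittoral trottoir category is scored as recorded;
  no precedence rule over infralittoral sectors is applied (none is
  defined), only a `Zone` flag is carried.

### Intra-seasonal consistency

Repeated spring assessments of a site are summarised by the modal ES class
and the deviating months. A modal tie is broken by dropping the earliest
month and recomputing until the tie resolves, and the tie is flagged:
later months lie nearer the macroalgal growth peak and are treated as more
representative. (Taking the literal last month's class instead would call
`moderate, good, good, moderate` modal-moderate; the drop-earliest rule
calls it modal-good, which matches how seasonal deviations are reported —
an early-season month deviating from the rest.)

## LUSI

The Land Uses Simplified Index is the sum of four ordinal pressure scores
(urban, industrial, agricultural land use, freshwater inputs) multiplied by
a coastline-shape factor: 0.75 for convex, 1 for straight coast. The
concave factor is accepted as a plain number rather than an enum because
published tables for this region only print 0.75 and 1; supplying the
regional concave value is the user's choice. The mariculture-adjusted
MA-LUSI-WB is accepted and reported as metadata but never computed — its
additional terms are defined elsewhere.

## Variance partitioning of EQR panels

Decade-scale monitoring yields a panel of EQR values indexed by water body
(WB), campaign year, and surveyor. The model is the Gaussian crossed
random-effects model

$$
EQR_{w,y} = \mu + u_{w} + v_{y} + s_{\sigma(y)} + b_{w,y} + \varepsilon_{w,y},
$$

with independent components: WB, year and surveyor intercepts, a
WB-within-year term $b_{w,y} \sim N(0, \sigma^2_{w|Year})$ with one
variance per water body, and residual. Fractions are reported as
$P_{samp} = 100\,\sigma^2_x / \sigma^2_T$ with
$\sigma^2_T = \sigma^2_{Year} + \sigma^2_{WB} + \sigma^2_{Surveyor} +
\sum_w \sigma^2_{w|Year} + \sigma^2_R$.

Design choices:

* **Diagonal WB-within-year covariance.** The literal random-slope formula
  `(0 + WB | Year)` implies an unstructured covariance across water bodies
  (28 parameters for 7 WBs), which 28 observations cannot identify. The
  per-WB diagonal matches what a per-water-body partition table reports and
  is what this package fits. With one observation per (WB, year) cell these
  per-WB variances are still only weakly identified against the residual;
  `fit_reml()` warns in that case.
* **Estimation.** REML, maximised directly: the restricted log-likelihood
  and its analytic gradient are evaluated through the Woodbury identity, so
  each evaluation costs $O(q^3)$ in the number of random-effect levels
  rather than $O(n^3)$. Optimisation is bounded L-BFGS-B on the
  log-variance scale from three deterministic starts (equal split,
  residual-dominant, component-dominant), convergence tolerance `factr =
  1e2` (≈1e-14 relative on the criterion). Estimates below
  `1e-7 * var(EQR)` are snapped to an exact 0, so boundary estimates (year
  and surveyor variances of zero in well-behaved monitoring data) are
  representable. The engine reproduces lme4's variances and `REMLcrit` to
  ~1e-6 on crossed designs, and equals the closed-form ANOVA moment
  estimator on balanced one-way designs — both asserted in the test suite.
* **Rounding.** Integer-percent presentation uses round-half-away-from-zero.
* **AIC.** Candidate random structures are compared on their REML fits
  (criterion + 2·(variances + 1) parameters). All candidates share the
  single grand-mean fixed effect, so the restricted likelihoods are
  comparable; comparing REML fits across *fixed*-effect specifications
  would not be valid and is not offered.
* **Residuals.** `residuals_vs_fitted()` returns conditional residuals:
  observation minus grand mean minus BLUPs of the random effects under the
  fitted variances — the standard validation plot.

## What the synthetic generators state

`simulate_survey()` emulates the hierarchical survey design: each water
body has three areas (West/Central/East) of 25 sectors × 50 m by default
(protocols use 20–30). Geomorphology is drawn i.i.d. from `grs_mix`, by
default mostly natural low/high coast (0.40/0.35) with small block and
artificial fractions — a realistic mix for a steep, lightly armoured
regional coastline. The dominant community is drawn from a softmax over
sensitivity levels whose inverse temperature is solved so the expected SL
equals $1 + 19q$ for latent quality $q \in [0,1]$: $q = 0$ and $q = 1$ are
degenerate (all blue-greens / all continuous *Cystoseira* belt) and
expected EQR is monotone in $q$. The generator does **not** emulate spatial
autocorrelation along the coast, within-area habitat structure, or
surveyor misclassification, so a green scoring test establishes arithmetic
correctness of the pipeline, not field realism.

`simulate_eqr_panel()` is the generative twin of the variance model above.
Defaults state a plausible monitoring world: 7 water bodies × 4 campaign
years × 2 surveyors, grand mean 0.7, $\sigma^2_{WB} = 0.03$,
$\sigma^2_R = 0.004$, all other components 0 — i.e. essentially all
variance between water bodies, none across years or surveyors, matching
what decade-scale CARLIT monitoring finds. Surveyors are assigned to
contiguous blocks of years (a plausible campaign staffing; the true
assignment is not published). Clipping to $[0,1]$ is off by default because
truncation biases variance recovery; when switched on for pipeline smoke
fixtures it warns if any value is clipped.

## Known limitations

* The seven-WB × four-year published fit is not exactly reproducible here
  because the underlying per-sector EQR panel is not published; the
  variance-partitioning acceptance check therefore feeds the published
  variance components through `variance_fractions()` and separately
  demonstrates parameter recovery on simulated panels at 50 WB × 10 years.
* One published per-WB fraction (Capo Mortola) prints 2% where the
  components imply 2.51% → 3%; the package reports the computed value.
* LUSI component scores are taken as given; deriving them from land-use
  GIS layers is out of scope, as is the MA-LUSI-WB formula.
* Sectors are abstract 1-D stretches; the GeoJSON export lays them on a
  synthetic line purely for GIS convenience.
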