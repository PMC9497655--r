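---
title: "Assessing heavy-metal contamination and dietary risk along the soil-food chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing heavy-metal contamination and dietary risk along the soil-food chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(metalchain)
```

## The problem

Farmland in karst regions sits on a naturally metal-rich geological
background, often with mining activity on top of it. Staple crops —
rice, maize and cabbage — take up cadmium, mercury, arsenic, lead and
chromium from the soil, and the people who grow them eat them daily.
Three questions follow: how contaminated is the soil, how much risk
does eating the crops carry, and can the edible-part concentration be
predicted from easily measured soil properties?

`metalchain` implements that assessment chain for paired soil-crop
surveys: one row per monitoring site, with soil pH, the five soil
concentrations, and the five edible-part concentrations (possibly
left-censored, i.e. below the instrument's detection limit).

## Contamination indices

The **geo-accumulation index** compares a measured soil concentration
`Cs` against a geochemical background `Bn`:

\[ I_{geo} = \log_2\!\frac{C_s}{1.5\,B_n} \]

The 1.5 factor absorbs natural lithogenic variation. Values are classed
0 (uncontaminated, `Igeo < 0`) through 6 (extremely contaminated,
`Igeo >= 5`) on unit intervals. The top interval of the conventional
scheme is stated as `Igeo > 5`, which leaves the point 5 unassigned; we
carry the half-open convention through, so exactly 5 falls in class 6.
Because the index is logarithmic, the mean of per-sample indices is
*not* the index of the mean concentration — summaries must say which
they report (ours report per-sample indices).

The **Hakanson potential ecological risk index** weights the
contamination factor of each metal by its toxic response:

\[ E_r = TF \cdot \frac{C_i}{C_B}, \qquad R = \sum_m E_r^{(m)} \]

with `TF` = 30 (Cd), 40 (Hg), 10 (As), 5 (Pb), 2 (Cr). `Er` grades at
40/80/160/320 and `R` at 150/300/600/1200, both closed on the left.
`Er` is linear in the concentration, so per-sample means and the index
of the mean agree — a useful cross-check, and the reason background
choice simply rescales every value by a per-metal constant.

**Background sets.** Two are bundled: the provincial (Guizhou) set
(Cd 0.66, Hg 0.11, As 20.0, Pb 35.2, Cr 95.9 mg/kg) and the national
set (Cd 0.10, Hg 0.07, As 11.2, Pb 26.0, Cr 61.0 mg/kg). `Igeo`
defaults to the provincial set (it describes the regional lithology the
index is supposed to reference); `Er` defaults to the national set,
which is the reference under which the published cabbage-soil Cd values
reproduce (30 x 13.01 / 0.10 = 3903). The published *rice* Cd `Er`,
however, reproduces under the provincial set, so the surveys this
package models appear to mix references; both knobs are therefore
mandatory, logged arguments of `contamination_table()` rather than
hidden constants, and the manifest records the choice.

```{r}
soil_means <- c(Cd = 13.01, Hg = 0.14, As = 24.77, Pb = 320.6, Cr = 163.83)
risk <- potential_ecological_risk(soil_means, background_set("national"))
round(risk$er, 1)
c(R = round(risk$r, 1), grade = risk$r_grade)
```

## Dietary exposure and risk

Exposure follows the standard EPA ingestion equation. The estimated
daily intake of metal `i` via one crop is

\[ EDI_i = \frac{C_i \cdot IR \cdot EF \cdot ED}{BW \cdot AT}, \qquad
   AT = ED \times 365\ \mathrm{d}, \]

so with exposure frequency `EF` = 365 d/year the duration cancels and
`EDI = C * IR / BW`. The cancellation is applied symbolically — `ED`
never enters numerically — but the profile keeps the field so
non-default `EF` still works. Default profiles: children 16 kg, adults
61.75 kg; ingestion rates 0.14/0.32 kg/d for rice and 0.100/0.150 kg/d
for maize and cabbage (children/adults). Since `IR/BW` is larger for
children in every crop, child risk exceeds adult risk uniformly — a
property the test suite asserts over random concentrations.

Non-carcinogenic risk divides by the oral reference dose
(`HQ = EDI/RfD`; Cr 3e-3, As 3e-4, Cd 1e-3, Pb 3.5e-3 mg/(kg d)), and
`THQ` sums `HQ` over metals, with 1 as the action threshold.
Carcinogenic risk multiplies by the cancer slope factor (`CR = EDI*SF`;
Cr 0.50, As 1.50, Cd 0.0038, Pb 0.0085) with the usual 1e-6/1e-4
negligible/unacceptable bounds. The Pb slope factor deserves a note:
the survey literature sometimes typesets it ambiguously ("00085"); we
use 0.0085, the standard oral value, which is also the only reading
under which Pb stays below the 1e-4 bound as the surveys report.

**Mercury** has neither an RfD nor an SF in the parameter set the
package bundles, and was undetected in rice and maize anyway; it is
excluded from THQ/TCR by default, with a warning naming the dropped
metal. `toxicity_table(rfd = c(Hg = ...), sf = c(Hg = ...))` brings it
in when external values are available.

```{r}
h <- hazard_assessment(reference_food_means("rice"), "rice",
                       exposure_profile("child"))
round(h$hq, 3)
round(h$thq, 2)
```

Both entry points — survey means via `hazard_assessment()` /
`carcinogenic_assessment()`, and per-sample distributions via
`risk_by_sample()` — share one intake kernel, so they cannot drift
apart.

## Non-detects

Detection limits for these surveys are reported in digest-solution
units (µg/L), which cannot be converted to dry-weight mg/kg without
unreported digestion masses and volumes. Censored entries are therefore
carried as flags and *excluded* from statistics — matching how the
survey tables compute their summaries over "the remaining samples" —
rather than substituted. An explicit `substitute_nd()` helper applies
LOD/2 substitution when a caller does have limits in mg/kg, so the
sensitivity of results to the censoring policy can be quantified; it is
never applied implicitly.

## The transfer model

Edible-part concentration is modelled from soil pH and soil
concentration on the log scale:

\[ \log_{10} C_f = a + b\,\mathrm{pH} + c\,\log_{10} C_s +
   \varepsilon, \qquad \varepsilon \sim N(0, \sigma^2) \]

fitted by ordinary least squares on detected pairs, with the overall
F-test (2, n-3 df) as the headline p-value and per-coefficient t-tests
alongside. Predictions back-transform, `Cf = 10^(a + b pH + c log10 Cs)`,
and are therefore always positive. A raw-`Cs` regressor is available
(`log_soil = FALSE`) purely as a sensitivity check; the log form is the
fitted artifact in the surveys this package models. The model is
deliberately minimal — no censored-data (Tobit) likelihood, no spatial
or mixed effects — because its role is prediction from two routinely
measured covariates.

**Outlier screening.** Survey datasets occasionally contain sites with
very high soil but anomalously low food concentrations. The screening
rule makes that symptom operational: a point is excluded only if its
externally studentized residual from a provisional full-data fit is
below -2.5 *and* its soil concentration is above the crop's 90th
percentile. Requiring both keeps the false-positive rate low on clean
data (an ordinary low residual, or an ordinary high-soil point, is
never dropped); the conjunction targets exactly the reported symptom.
The thresholds are arguments, the excluded site ids are part of the fit
object, and the screen refuses outright to drop 20% or more of the
points. On datasets emulating the 103-site maize survey with one such
planted point, the rule removes exactly that point, reproducing the
published n = 102.

Fits are attempted for all metals rather than suppressed for the weak
ones (Hg/As/Pb/Cr, heavily censored in food): the `n`, `r2` and `p`
fields carry the evidence, and the survey experience — only Cd yields a
usable model — shows up as high p-values rather than silent absence.

## The synthetic-data generator

No raw per-sample data are deposited for the surveys this package
models, so the generator reproduces the *published statistical
structure* and serves as the test bed for every stage:

* **Design:** 22 rice, 103 maize, 35 cabbage sites.
* **pH:** truncated normal per crop, matched to the published mean/SD
  and truncated at the published min/max.
* **Soil metals:** truncated lognormals, moment-matched via
  `sigma^2 = log(1+(sd/mean)^2)`, `mu = log(mean) - sigma^2/2`, then
  rejection-sampled into the published ranges. Lognormality reflects
  the strong positive skewness of the published tables. The mild
  mean/SD distortion from truncation is accepted, not corrected; the
  generator errors out if bounds leave under 1% acceptance.
* **Food Cd:** generated *through the transfer model* with the
  published per-crop coefficient triples, plus lognormal noise. The
  residual SD is calibrated so the fitted R² matches the published
  value per crop (0.438 / 0.504 / 0.850): since pH and log10(Cs) are
  truncated normals, their variances — hence the signal variance
  `b² var(pH) + c² var(log10 Cs)` — are closed-form, and
  `resid_sd² = signal · (1-R²)/R²`. Accounting for truncation here (as
  opposed to in the marginal moments) matters: the untruncated formula
  would systematically overshoot the noise and undershoot R² by ~0.03.
* **Other food metals:** independent truncated lognormals with
  Bernoulli censoring at the published non-detect rates (e.g. Hg fully
  censored in rice and maize, Pb censored in 91 of 103 maize samples).
* Metals are generated independently — the published tables give no
  inter-metal correlations — with a log-scale correlation-matrix hook
  (`log_corr`) for stress tests.

What passing tests on this generator do **not** show: real surveys have
spatial autocorrelation, inter-metal source correlations, shared-digest
censoring (non-independent NDs), and measurement error in the
covariates. Results proven on the generator are therefore statements
about the *methods* under the published marginal structure, not
re-analyses of the field data.

## Numerical and estimator conventions

* SD is the n-1 sample estimator; CV = SD/mean; quartiles interpolate
  at `1 + (n-1)p` (the "inclusive" spreadsheet scheme, `quantile`
  type 7); skewness and kurtosis are the adjusted (spreadsheet)
  estimators, kurtosis as *excess*. These match the toolchain the
  survey tables were produced with; other quartile conventions differ
  in small samples, which is why the choice is pinned and documented.
* CV labels: `< 0.5` low, `(1.0, ∞)` strong; the closed middle interval
  is "moderate". Grade steps for `Igeo`, `Er` and `R` are closed on the
  left and total — every finite value maps to exactly one class.
* Degenerate inputs: constant samples give CV 0 and undefined (`NA`)
  skewness/kurtosis; kurtosis requires n ≥ 4, skewness n ≥ 3;
  zero-residual screens flag nothing; collinear transfer designs error
  rather than silently drop a term.
* Concentrations are dry-weight mg/kg throughout; no wet/dry
  conversion is attempted.

## Problem sizes used in the checks

The test suite works at the survey's own design (160 sites) for
end-to-end runs; calibration properties that need tighter Monte-Carlo
error use larger synthetic draws (R² calibration at n = 500, covariate-
variance checks at n = 2000, parameter recovery on 500 replicates of
n = 200), all completing in well under a minute each.

## Known limitations

* Combined indices printed in survey reports from unrounded per-sample
  data (e.g. a combined rice R of 104.44) are not exactly recoverable
  from rounded printed means; the package reproduces the grades and the
  linear single-metal anchors instead.
* Cross-crop aggregate CR figures in the survey literature use an
  undocumented weighting; the per-sample summary reports both the
  per-crop means and sample-weighted pooling, and targets neither
  printed aggregate.
* The censoring policy (exclusion) follows the published tables; with
  heavy censoring (maize Pb: 88%) the detected-sample mean is a
  substantially upward-biased estimate of the population mean, and any
  risk computed from it inherits that conservatism.
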