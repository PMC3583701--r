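---
title: "Methods: measurement protocol, body composition and observer reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measurement protocol, body composition and observer reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinfoldrel)
```

## The problem

Skinfold thickness measurement is one of the few body-composition
methods appropriate in pregnancy, since the pinched subcutaneous sites
(biceps, triceps, subscapular) are not confounded by fetal growth. In
overweight and obese women, however, landmarking and pinching are
harder, and studies typically pool measurements from several trained
observers. Two questions then matter: *does the measurement protocol
control reading-to-reading error*, and *how much variance do the
observers add*? This package implements the protocol layer, the derived
body-composition quantities, and the reliability analysis, plus a
generative model for validating all three together.

## The measurement protocol

Each observer takes two calliper readings per site. If the pair differs
by more than 7.5% a third reading is taken; the reported value is the
mean of two or the median of three (none discarded). Values are recorded
at 0.1 resolution (mm for skinfolds, cm for arm circumference) within
the 0–80 mm calliper range.

Decisions the protocol statement leaves open, and how they are resolved
here:

* **Denominator of the 7.5% rule.** "Differ by more than 7.5%" does not
  say 7.5% *of what*. The default compares |v1 − v2| against the mean of
  the pair — symmetric in the two readings and the common convention in
  anthropometric practice. `denominator = "min"` and `"first"` are
  provided so alternative readings of the rule can be examined; both are
  more conservative (they trigger at least as often as the mean rule).
* **Strictness.** The rule is strict: a pair at exactly 7.5% does not
  trigger a third reading.
* **Rounding.** Aggregated values are rounded *half away from zero* to
  0.1, matching how field values are written down (base R's default
  half-to-even would turn the mean of 10.1 and 10.2 into 10.1). The mean
  of two readings is computed in integer tenths so the halfway case is
  exact, free of binary floating-point representation error. Readings
  are assumed already recorded at 0.1 resolution.
* **Non-conformant sessions.** A discrepant pair lacking its third
  reading is aggregated anyway, flagged, and reported in the conformance
  findings. The protocol source never states an exclusion rule, so
  exclusion is left to the analyst; nothing is dropped silently.

## Body composition

BMI is weight (kg) over height (m) squared with the WHO bands used for
cohort eligibility (overweight 25.0–29.9, obese ≥ 30.0 kg/m²). Body fat
percentage comes from a population-specific linear equation for
overweight/obese pregnant women,

$$\mathrm{BF\%} = 12.7 + 0.457\,T + 0.352\,S + 0.103\,B
  - 0.057\,H + 0.265\,A,$$

with triceps $T$, subscapular $S$ and biceps $B$ in mm and height $H$
and arm circumference $A$ in cm. The coefficients are taken as given;
their external derivation and validation samples are out of scope here.
Two consequences of linearity are used in the tests: the BF% of mean
inputs equals the mean of per-woman BF%, and each input moves the output
by exactly its coefficient. The equation is unbounded, so a prediction
outside 5–60% raises a warning (the plausible band for this population;
observed cohort values span roughly 22–47%) but is returned as computed.
Height appears in cm here and in m in BMI; the argument names
(`height_cm`, `height_m`) keep the units explicit at every call site.

BF% is computed once per observer session from that observer's
measurements plus the woman's height, then treated as a fifth measure in
the reliability analysis — so the BF% ICC inherits the inter-observer
variability of the anthropometric inputs, as it does in practice.

## The reliability model

The design has each woman measured by $k = 2$ observers drawn from a
pool, *not necessarily the same pair for each woman*. Observer identity
is therefore not a crossed factor, and the canonical estimator is the
one-way random-effects model, in which observer effects are absorbed
into measurement error:

$$y_{ij} = \mu + b_i + \varepsilon_{ij}, \qquad
\mathrm{ICC}(1,1) = \frac{MS_B - MS_W}{MS_B + (k-1)\,MS_W}, \qquad
\mathrm{SEM} = \sqrt{MS_W},$$

with $MS_B$ and $MS_W$ the between- and within-subject mean squares.
The SEM is model-based, consistent with "obtained from this model"; the
classical alternative $SD\sqrt{1-\mathrm{ICC}}$ is available via
`sem_method = "sd_based"` but is not the default. Negative ICC estimates
(possible in small samples with little subject signal) are reported as
computed, flagged, and classed as poor-to-moderate — truncation to zero
would bias averages of estimates upward.

For fully crossed panels `icc_twoway_random()` implements ICC(2,1),
$(MS_R - MS_E)/(MS_R + (k-1)MS_E + k(MS_C - MS_E)/n)$, separating
observer variance ($MS_C$) from residual error. It deliberately refuses
non-crossed designs: with observers varying by subject the observer and
error components are not separable by this decomposition. One subtlety
worth recording: a constant observer offset does **not** generally push
ICC(2,1) below ICC(1,1) on the same data — the one-way model absorbs the
whole offset into $MS_W$ (shrinking the numerator *and* growing the
denominator), which typically penalises it more than the explicit
$k(MS_C-MS_E)/n$ term penalises ICC(2,1). The tests assert the correct
direction: an offset lowers both estimators relative to offset-free
data.

Classification uses the two Portney–Watkins bands with the 0.75 cut,
boundary inclusive below (ICC ≤ 0.75 poor to moderate, > 0.75 good).
Finer verbal labels ("moderate"/"good"/"excellent") are inconsistently
applied across reports, so they are only an optional cosmetic layer
(`descriptors = TRUE`: ≤ 0.6 / ≤ 0.9 / > 0.9) and never affect the band.
Subjects lacking a complete two-observer pair for a measure are excluded
for that measure only; a measure with fewer than two usable subjects
yields an NA row, not an error. All statistics are computed at full
precision; the 2-decimal formatting lives only in the print method.

## The generative model

`simulate_cohort()` draws, per measure,

$$y_{ij} = \mu + b_i + o_j + e_{ij}, \quad
b_i \sim N(0, \sigma^2_s),\; o_j \sim N(0, \sigma^2_o),\;
e_{ij} \sim N(0, \sigma^2_e),$$

the latent session value for subject $i$ and observer $j$ (observers
sampled without replacement from a pool of 4 per subject), and then
*replicate readings* around each session value with SD
`reading_noise_sd`, rounded to 0.1, with a third reading drawn whenever
the duplicate pair trips the 7.5% rule. The population ICC is
$\sigma^2_s / (\sigma^2_s + \sigma^2_o + \sigma^2_e)$ and the population
SEM is $\sigma_e$ (with $\sigma^2_o$ folded into error by the one-way
analysis). Skinfold values are resampled while outside the open
(0, 80) mm interval; at the default parameters the boundary is
essentially never touched, so the truncation distortion is negligible.

Default calibration (a display calibration to the published cohort
scale, not recovered ground truth): per-measure means 34.57 cm / 13.21 /
24.13 / 25.37 mm, error SDs equal to the reported SEMs (0.53 / 2.34 /
3.02 / 3.58), subject variances solved from the reported ICCs (0.97 /
0.56 / 0.50 / 0.71) with $\sigma^2_o = 0$, and 49 subjects. Maternal
height is N(165.25, 6.5²) cm — the mean being the value that reconciles
the published average measurements with the published average BF% under
the linear equation, since no cohort mean height was reported — and BMI
is 25 + Gamma(1.6, scale 3), giving a median near 29 and an
overweight/obese split near the published 55/45.

No replicate-reading SD is published anywhere in the source material, so
`reading_noise_sd` is a stated assumption: 0.5 mm for skinfolds and
0.15 cm for the tape measure (2–4% of the site means, plausible for
trained observers) and recorded in every truth record. Under duplicate
averaging it adds $\sigma^2_r/2 \approx 0.125$ mm² to the within-session
variance — about 1.4% of the default $\sigma^2_e = 9$ mm², so quoted
true ICCs ignore it.

What the generator does **not** emulate: skewed or heteroscedastic
measurement error, correlation of errors across sites within a session,
gestational-age trajectories, and observer-by-subject interactions
(e.g. landmarking difficulty increasing with BMI). Passing
parameter-recovery tests therefore shows the estimators are correct
*under the model the analysis assumes*, not that real skinfold data meet
those assumptions.

## Validation strategy and problem sizes

Three layers, all run by the test suite:

1. **Oracle equivalence.** ICC(1,1) and SEM agree to 1e-10 with a
   brute-force loop over the definitional sums of squares on 200 random
   small instances (n ∈ [2,10], k = 2), and the mean squares agree with
   `stats::aov` on a fixed table.
2. **Parameter recovery.** For true ICC ∈ {0.5, 0.75, 0.9}, 200 cohorts
   of 49 women × 2 observers are simulated per grid point and pushed
   through the *entire* pipeline (replicate readings → aggregation →
   one-way model). The suite requires mean estimated ICC within 0.05 of
   truth and mean SEM within 10% of $\sigma_e$; `analysis/05` writes the
   observed bias/RMSE table. These sizes (600 cohorts) keep the sweep
   in a few seconds while the Monte-Carlo error of the mean (~0.007 at
   ICC 0.5) stays well under the 0.05 margin.
3. **Determinism.** Identical configuration and seed give byte-identical
   datasets and byte-identical written reports.

## Limitations

* The published per-site ICC/SEM values cannot be reproduced because the
  underlying raw measurements were never deposited; single simulated
  cohorts at n = 49 scatter around the calibrated truth exactly as the
  recovery sweep quantifies.
* Which SAS formulation produced the published values (one-way vs
  two-way, single vs average measures) is unrecorded; this package makes
  the design-driven choice (one-way, single-measure) and exposes the
  two-way alternative.
* Confidence intervals for the ICC are not provided; at n = 49 the
  recovery RMSE (reported by `analysis/05`) is the honest uncertainty
  summary.
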