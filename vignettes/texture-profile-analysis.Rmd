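---
title: "Methods: double-compression texture analysis of fish fillets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: double-compression texture analysis of fish fillets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishtpa)
```

## The measurement and its model

Texture profile analysis (TPA) compresses a cooked fillet twice with a
ball probe, imitating two chews. The instrument records force against
time while the crosshead moves at a known, constant speed, so time and
probe travel are interchangeable up to that speed. Eight anchor points
structure the curve: the trigger-force crossing and the peak of each
compression, the end of the first positive decompression limb, the
bounds of the negative adhesion region, and the end of the trace. Four
work areas (trapezoidal integrals of force over time between anchor
times), two travel distances (displacement differences between anchors)
and the two peak forces yield twelve attributes; the test protocol is
trigger force 5 g, 50% strain, pre-test speed 3 mm/s, test and post-test
speeds 1 mm/s, and a 5 s pause between cycles, with eight probe points
per fillet.

Three conventions deserve note, because the attribute definitions do
not fix them:

* **Integration variable.** Areas are integrated over *time* (N·s).
  At the constant 1 mm/s test speed this is numerically equal to work
  over distance, so hardness‑1b and the chewiness family keep their
  published magnitudes either way.
* **Springiness is a distance ratio**, `100 · D2/D1` in percent
  (cohort values near 70), and is converted to a fraction inside the
  chewiness products so chewiness magnitudes stay on the published
  scale.
* **Force unit.** The canonical unit is the newton; readers convert
  gram-force (`/101.97`) and centimetres on input. The published cohort
  tables never state their force unit; only labels, not ratios, depend
  on this choice.

## Anchor detection: numerical choices

Anchor *location* works on a 5-sample running median of the force
channel; all *reported* values (peaks, integrals) use the raw samples.
Cycles are found as runs above a detection threshold
`max(trigger, 5·sigma)`, where `sigma` is the robust noise estimate
`mad(diff(force))/sqrt(2)` — the first difference removes the
piecewise-smooth signal, and the estimate stays honest where a
median-filter residual would not (the median of five samples *is* one
of them about a fifth of the time, deflating that residual). Runs
shorter than 3 samples are debounced away and the longest below-trigger
gap splits the two cycles. The trigger-crossing anchors are then
localized by walking back from each cycle's detection onset to the
interpolated trigger crossing; peak anchors are refined to the raw
maximum in an 11-sample window (the median filter flattens the apex
into a plateau whose earliest tie would otherwise win); ties at a
maximum break to the earliest index. The first return of force to zero
after the first peak closes the decompression limb; when the force
never dips below zero the adhesion region collapses (`a4 = a5`,
adhesiveness 0). A dip counts as real only when the minimum falls below
`-max(2·trigger, 4·sigma)`.

A consequence worth knowing: when trace noise is of the same order as
the 5 g trigger, the trigger crossing can only be localized where the
force clears the noise band. Because the force toe at ball-probe
contact is flat (a power law steeper than linear), this biases both
compression distances — and springiness — *low* by up to ~10% at 0.05 N
noise, while peak forces and all work ratios are essentially untouched.
Quantitative distance extraction therefore assumes hardware-trigger
quality traces (noise well below the trigger force); the noiseless
round trip recovers every attribute within 0.5%.

## The synthetic generator

No public instrument traces exist for this design, so the generator is
a first-class, tested module. One simulated test point follows a
power-law compression limb `F = F_t + (S - F_t)(x/d)^shape` that crosses
the trigger force `F_t` exactly at nominal contact (a short sub-trigger
toe precedes it). This choice makes every ground-truth attribute an
exact closed form of the parameters: springiness equals
`100 · recovery_fraction`, peak force equals `S`, and all areas are
analytic. Withdrawal relaxes force to zero over `unload_fraction` of
the compression depth (so resilience ≈ `100 · unload_fraction`), a
half-sine adhesion dip of fixed 1 s duration follows (adhesiveness
`= -2 · amplitude/pi`), and the second compression returns to the same
absolute probe depth from the partially recovered surface — which is
exactly what makes thickness‑2 `= thickness‑1 × springiness/100` an
identity of the design.

Defaults: shape 2.5 for the first compression; peak-force ratio 0.89
and a second-cycle shape solved so the default cohesiveness is 0.48
(one shared shape cannot reproduce the published cohesiveness and
peak-force ratio simultaneously, since `A4/A1` would equal their
product with springiness, about 0.62). Noise is additive Gaussian on
force only; displacement is crosshead-driven and treated as exact.
`fillet_from_attributes()` inverts the generator, returning parameters
whose noiseless curve carries prescribed attribute values exactly.

Cohorts (`simulate_cohort()`) draw the eight *base* attributes
(adhesiveness, cohesiveness, the three hardnesses, resilience,
springiness, thickness‑1) as independent Gaussians per fish at the
published group moments — 60 IQF and 34 fresh-frozen fish, eight points
per fillet — and derive thickness‑2 and the chewiness family row by row
from the TPA formulas, so the derived means land near their published
values automatically (a mean of products is not a product of means,
which is why e.g. the derived chewiness‑1 mean sits near 67 rather than
the published 68.6). Within-fish point-to-point noise defaults to half
the between-fish SD — the published tables only report between-fish
dispersions, so this is a modelling choice, not a calibration. Sensory
scores come from a linear link on fish-mean TPA values plus Gaussian
noise (SD 0.7, matching the published equation RMSEs of 0.6–1.1),
clipped to the 0–15 descriptive intensity scale (published anchor
references reach 11; 15 is the conventional spectrum ceiling). What the
generator does *not* emulate: correlations among base attributes,
non-Gaussian tails, panelist effects, and real contact mechanics — so
passing tests certify the pipeline's arithmetic and statistics, not
biological realism.

One deliberate deviation: it has been suggested that with shape 2.5 the
work-based hardness‑1b sits near three-quarters of hardness‑1; with
areas in N·s at 1 mm/s the ratio is actually `d/(shape + 1)` (about
2.25 at typical thickness). No shape can reach 0.75, so curve-level
hardness‑1b is left uncalibrated and the cohort simulator draws
hardness‑1b directly at its published moments instead.

## Thickness residualization

Every residual attribute is `value − (slope · thickness‑2 + intercept)`.
Eight fixed published lines ship verbatim (five TPA attributes, three
sensory); residual hardness‑1 — used as a predictor in one published
equation — has no published line and is always cohort-fitted, with a
message when requested in builtin mode. Cohort fitting is ordinary
least squares on per-fish means (matching the study's aggregation);
per-point fitting is available since the published granularity is not
stated. Two identities anchor the tests: fitted residuals have mean
zero and zero correlation with thickness‑2 on the fitting sample, and
for any line `mean(residual) = mean(value) − slope · mean(thickness‑2)
− intercept` exactly — the basis of the cross-checks between the
published attribute and residual means.

A recorded inconsistency: applying the published chewiness‑1b line to
the published group means gives −2.30 (IQF) and +4.14 (fresh-frozen)
against printed residual means of −3.713 and +6.552 — beyond rounding,
suggesting that line was fitted on a different granularity or subset.
The chewiness‑1b cross-check is therefore not used as a headline check;
the seven that do validate are.

## Group comparison

Repeated measures are averaged per fish (unweighted, missing points
omitted; the published data were unbalanced) and the fish means enter a
one-way fixed-effects ANOVA. The original analysis used a mixed model,
but with one observation per fish and no other random effects it
reduces to exactly this fixed-effects comparison; with two groups
`F = t²` of the pooled-variance t test, verified exactly in the tests.
Summary SDs are across fish, not across the eight points. Tests are
two-sided with no multiplicity correction, and no covariates (fillet
side, pond) are used — the published analysis states none.

## Sensory prediction

The published group-specific equations are stored as verbatim constants
(ten fresh-frozen; nine IQF plus an explicit absent-model marker for
IQF moisture retention, where no predictor qualified) and evaluated as
exact arithmetic — they are never refit. Group-specific modelling is
the default; pooling is available but the published remark that pooled
coefficients of determination halve motivates the separation.

The re-derivation is two-phase forward selection: phase 1 over main
effects — the twelve attributes plus the five TPA residuals, the union
of predictor abbreviations appearing in the published equations, since
the candidate pool itself is never listed — entering the candidate with
the smallest partial-F p-value while it is below 0.05; phase 2 over the
squares and pairwise cross products of phase‑1 survivors only, same
rule. Ties break by larger R² gain, then alphabetically (the original
software's tie rule is unknown). Collinear candidates are skipped with
a warning; an empty selection returns the intercept-only model. Fit
reports use the regression conventions: `RMSE = sqrt(SSE/(n − p − 1))`,
`R = sqrt(R²)`, `adjusted R² = 1 − (1 − R²)(n − 1)/(n − p − 1)`.
Stepwise fitting operates on per-fish means, as the ANOVA does; whether
the published fits did is unstated.

A second recorded inconsistency: the published IQF sensory-springiness
equation evaluated at the published mean of its single predictor gives
1.22, far from the published sensory mean 3.09, violating the OLS mean
identity that every linear-terms-only fit must satisfy on its own
sample; it was likely fitted on a subset or contains a typo. Only
cross-checks that do satisfy the identity are used as headline checks.

## Problem sizes and verification

The test suite runs the full pipeline at the study's own design (60 +
34 fish, 8 points) and uses larger sizes only where a law-of-large-
numbers or rate check needs them: 2000 fish per group for moment
convergence, 1000 replicates for the springiness separation and type-I
calibration, 400–600 replicates for the null entry rate of forward
selection (expected near `1 − 0.95^k` for `k` independent null
candidates), and n = 500 for coefficient recovery. Closed-form oracles
(triangle and `sin²` integrals, normal-equations regression, the exact
published-line arithmetic) pin the numerics; the stochastic checks use
fixed seeds and tolerances stated next to each test.

## Known limitations

* Base attributes are drawn independently within fish; real attributes
  correlate (hardness‑1 with hardness‑2 at R² ≈ 0.98 in the published
  scatter), so variance of derived composites is understated.
* Distance extraction under heavy noise is biased low (see above).
* No fracturability detection, no mixed-model variance components, no
  cross-validation or regularization of the stepwise fits — all outside
  the scope of the published analysis this package operationalizes.
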