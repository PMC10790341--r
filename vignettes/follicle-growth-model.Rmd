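---
title: "Modelling granulosa-cell proliferation and preovulatory follicle recruitment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling granulosa-cell proliferation and preovulatory follicle recruitment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(follicledyn)
```

## The scientific problem

Mice ovulate around 10 oocytes per estrous cycle while most antral follicles
die by atresia. Which follicles make it into the preovulatory cohort? The
pipeline in this package addresses the question quantitatively, through three
connected pieces:

1. **Labeling-index (LI) quantification.** BrdU incorporated during a short
   pulse marks proliferating granulosa cells. On segmented histology masks the
   LI is the area fraction of BrdU-positive granulosa inside a region of
   interest drawn at the basal lamina, with the cumulus excised:
   \[ LI = \frac{A_{BrdU^+}}{A_{BrdU^+} + A_{BrdU^-}}. \]
2. **Stereological measurement.** Follicle size is the *pseudodiameter*
   \(D = 2\sqrt{A/\pi}\) of the widest cross-section in a serial-section
   series; a follicle whose widest section falls on the first or last section
   of the series is excluded because its true widest point may lie outside
   the sampled volume. Atresia is classified from five morphological
   criteria (any one present makes the follicle atretic).
3. **An iterative growth model.** The mural granulosa layer obeys the
   volume allometry \(V_M = 0.18\,D^{3.05}\) (\(\mu m^3\)), so the mural cell
   count is \(N = V_M / V_G\) with \(V_G = 132.6\,\mu m^3\) per cell. Each
   24-h iteration multiplies the cell count by \(1 + LI_{\mathrm{eff}}\) and
   converts back to a diameter through the inverse allometry.

## The effective LI and its interpretation

Proliferation slows as follicles mature, so iterating the raw day-0 LI
overestimates growth. The model corrects it as

\[ LI_{\mathrm{eff}, i} = a \,\max\{0,\; LI_0 - s\,(D_{i-1} - D_0)\}, \]

with decline slope \(s = 0.0008\) per \(\mu m\) (the exact line through the
mean proliferation rates of the regenerated summary table: 49 % at 100
\(\mu m\) down to 21 % at 450 \(\mu m\), intercept 0.57) and the adjustment
factor \(a = 0.795\) obtained by calibrating modeled against observed growth
of the largest follicles. At the first iteration the correction reduces to
\(0.795 \times LI_0\).

The source equation for this correction as printed multiplies the correction
factor by the *cell-number increase*, which is dimensionally inconsistent
with the textual definition in terms of diameter gain (a dimensionless factor
applied per cell suppresses the first iteration almost completely and then
alternates erratically). We therefore adopt the diameter-based reading above
as the default; the literal reading remains available via
`simulate_growth(..., strategy = "literal")` so the degeneracy can be
inspected. Effective LIs are clamped to \([0, 1]\): a proliferating fraction
cannot be negative, and the clamp is the only behaviour consistent with
iterating past the point where the linear decline crosses zero.

Two further numerical choices: cell counts stay real-valued during iteration
(the model is a deterministic rate equation; rounding would break the exact
exponential limit \(N_n = N_0 (1+LI_0)^n\) that holds when \(s = 0, a = 1\)),
and `diameter_from_cell_count()` uses the closed-form inverse of the power
law, with a bisection inversion kept in the test suite as an independent
oracle.

```{r growth}
params <- growth_params()
simulate_growth(250, median_li(250, params), 3, params)
days_to_diameter(250, 0.62, 350, params)
```

## Calibration

`calibrate_adjustment()` recovers the adjustment factor from a sequence of
(day, mean diameter) observations by 1-D bounded least squares over
\((0, 1.5]\) (`stats::optimize`). The search interval and objective are our
design choices — the original calibration procedure is not described — and
the function is validated by parameter recovery on model-generated
trajectories (planted 0.795 and 1.0 recovered to \(\pm 0.01\)). The observed
per-stage mean diameters of the five largest follicles (334, 388, 441
\(\mu m\)) cannot be aligned to model days because stage durations vary
between animals (estrus alone averages 2.5 days), so calibration against them
is deliberately not asserted; the demonstration in `analysis/04` uses
self-generated observations.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `volume_coefficient`, `volume_exponent` | 0.18, 3.05 | — | mural volume allometry |
| `granulosa_cell_volume` | 132.6 | \(\mu m^3\) | single-cell volume |
| `adjustment_factor` | 0.795 | — | per-iteration LI adjustment |
| `li_decline_slope` | 0.0008 | LI/\(\mu m\) | LI decline with diameter |
| `li_intercept` | 0.57 | LI | median LI line at \(D=0\) |
| `iteration_interval_h` | 24 | h | one iteration = one ovulation opportunity |

Stage thresholds default to preantral/secondary [80, 130), FSH-sensitive
[130, 170), FSH-dependent [170, 350], preovulatory strictly > 350 \(\mu m\);
boundaries are lower-inclusive except the strict preovulatory cut-off, so
every diameter above 80 \(\mu m\) maps to exactly one stage (170 \(\mu m\)
belongs to FSH-dependent). Alternative literature thresholds (130–200,
200–350) are not used.

## What the synthetic data emulate — and what they do not

No archived dataset accompanies the study, so every input is generated in
code, seeded and reproducible (identical config + seed gives identical
output).

**Populations** (`sample_population()`): per cycle stage, sub-preovulatory
diameters are a mixture of a small-follicle log-normal and a uniform
FSH-dependent band (40 % by default — sectioned ovaries show a roughly evenly
populated antral band), plus a planted non-atretic preovulatory cohort that
accumulates across the cycle (1 at estrus, 5 at metestrus, 10 at diestrus),
representing the surviving dominant cohort. True LIs follow a piecewise mean
trajectory — constant 0.20 below 130 \(\mu m\) (preantral LIs rarely exceed
0.30), a linear growth spurt to 0.434 at 170 \(\mu m\), then the linear
decline \(0.57 - 0.0008\,D\) — with between-follicle SD 0.07 at fixed
diameter (matching the 10–40 % spread of LIs among same-size large antral
follicles) and truncated-Gaussian measurement noise (SD 0.03). The spline
knots at 130 and 170 \(\mu m\) are the stage boundaries; the original spline
knots are unpublished.

**Atresia** is a daily hazard, logistic-decreasing in the LI percentile and
scaled by a stage multiplier (estrus 0.2, metestrus 1, diestrus 1.5), applied
only above the 170 \(\mu m\) onset diameter. The mechanism is invented but
consistent with atretic follicles having LIs in the low range and with
atresia being rare at estrus; all parameters are exposed in
`atresia_hazard()`.

**Histology** (`render_section_stack()`, `render_mask()`): spherical
follicles sliced at 5-\(\mu m\) section midplanes (75 consecutive sections
for the 2-h design, every 25th for the 48-h design), and equatorial masks
with a mural annulus whose thickness follows a linear law derived in code so
that the spherical-shell volume matches \(0.18\,D^{3.05}\) within 10 % over
170–450 \(\mu m\) (the published thickness line prints no coefficients).
BrdU-positive pixels form one contiguous angular patch (spatial clustering);
cumulus granulosa is rendered unlabeled, so omitting the cumulus exclusion
measurably biases the LI low — which is exactly what the exclusion-rule tests
exploit.

What passing tests therefore show: the pipeline's arithmetic, filtering and
selection logic are correct on data whose ground truth is known. What they do
not show: performance on real histology (staining variability, segmentation
error, non-spherical follicles, nucleus-level texture) or the true biological
atresia mechanism.

## The survivor-effect experiment

The long-term pulse-chase analogue (`survivor_experiment()`) uses a cohort of
150 follicles of identical starting diameter (300 \(\mu m\)) with
heterogeneous LI, grown two model days under the hazard; survivors are the
non-atretic follicles exceeding 350 \(\mu m\). Fixing the starting size is a
deliberate design choice: in a mixed-size cohort mean LI falls with diameter,
confounding size with growth rate, whereas at fixed size both selection
channels (the growth threshold and the LI-percentile hazard) act on LI alone,
so the positive survivor-minus-population difference is guaranteed by
construction — the same logic as modelling same-size follicles at varied
proliferation rates. The original effect size on real data (rank-test
\(P < 0.001\) over hundreds of follicles) is not reproduced quantitatively;
only its sign and robustness across 100 seeded replicates are asserted.

## Cohort recruitment and minimum cycle length

`simulate_cohort()` grows a starting population until a target number
(default 10, configurable 6–12) of follicles exceeds 350 \(\mu m\); the
minimum cycle length is that day plus one proestrus/ovulation day. Growth is
deterministic; the hazard, when enabled, is the only source of randomness and
is fully seed-controlled. With 12 follicles of 250 \(\mu m\) growing at LI
0.45 the target is met at day 4 (a 5-day cycle); at the median rate a 250
\(\mu m\) follicle cannot cross 350 \(\mu m\) within the 3-day window of a
4-day cycle, and recruitment from 170 \(\mu m\) takes 9 median-rate days.

## Problem sizes and determinism

Simulations in the tests and analysis scripts use populations of ~170–260
follicles per stage, 100-replicate stability checks, and masks of ~300 px —
sizes at which every statistical property asserted (slope recovery to
\(\pm 0.0002\) at generating noise SD 0.02 and \(n = 200\); survivor-effect
sign in \(\ge 95/100\) replicates) holds with wide margin. All generators are
pure functions of (configuration, seed); ties in widest-section selection go
to the lowest section index, and ties in the fast-subset ranking to the
smaller diameter.

## Known limitations

- No hormone (FSH/LH/inhibin) feedback, antrum fluid volume, oocyte growth,
  or stochastic per-cell division; the growth model is deterministic.
- Fractional days are not modelled (ovulation is a once-daily opportunity).
- The "fast" regression of the original study is unpublished; fast scenarios
  use either a planted high LI or the regression fitted to synthetic data.
- Partial follicle profiles at series edges are recorded and then excluded,
  which matches the stated sampling rule but may differ from bench practice.
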