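---
title: "Simulating chart-based and staircase-based CSF measurement: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating chart-based and staircase-based CSF measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcsf)
```

`crcsf` replays, on synthetic observers, a two-arm measurement of the
contrast sensitivity function (CSF): a *three-click* adjustment of a
truncated log-parabola onto a Campbell-Robson chart, and a gold-standard
QUEST staircase measurement of the same curve, followed by group statistics
and a cross-validated prediction analysis. This vignette documents the
models, the tunable parameters, the calibration of the synthetic
populations, and the design choices made where the procedure left room for
interpretation.

## The truncated log-parabola

The CSF model has four parameters: peak linear sensitivity `y_max`
(dimensionless, the reciprocal of the Michelson contrast threshold at the
peak), peak frequency `f_max` (cycles/degree), full width at half maximum
`β` (octaves), and truncation depth `δ` (decades). In log10 units,

$$f(x) = \log_{10}(y_\mathrm{max}) - \left(\frac{\log_{10}x -
\log_{10}f_\mathrm{max}}{\beta\,\log_{10}(2)/2}\right)^{2},$$

except below the peak frequency, where the curve never falls under the
plateau $\log_{10}(y_\mathrm{max}) - \delta$. Two readings of the truncation
condition are possible because it is stated self-referentially; we truncate
where the *parabola* falls below the plateau, and only for $x <
f_\mathrm{max}$ — the convention used by adaptive-CSF implementations and
the only one that leaves the high-frequency limb intact. The equation
returns log10 sensitivity (the plateau expression forces log units);
`sensitivity()` is the linear wrapper. Note that with this
parameterisation the parabola is one full decade below the peak at
$\beta/2$ octaves from $f_\mathrm{max}$.

**Fitting** (`fit_csf`) is bounded least squares on log10 sensitivities,
with bounds $y_\mathrm{max} \in [2, 5000]$, $f_\mathrm{max} \in [0.2, 20]$
cpd, $\beta \in [0.5, 12]$ octaves, $\delta \in [0, 3]$ — generous relative
to any plausible human curve, and wide enough that the bounds are inactive
for all synthetic data the package generates. The objective is piecewise
smooth (the branch boundary moves with the parameters), so the optimiser
uses eight deterministic multi-starts (one data-driven, seven on a fixed
grid) into `L-BFGS-B`, followed by a bound-clamped Nelder-Mead polish; the
procedure involves no random numbers and on noiseless 7-point data recovers
parameters to well under 0.1%. A flat input (zero variance in log
sensitivity) cannot identify the model and returns a flagged fit with
`r_squared = NA` instead of an error. `r_squared` is $1 -
\mathrm{SSE}/\mathrm{SST}$ on log10 sensitivities.

**Clicks.** The first click fixes $(f_\mathrm{max}, y_\mathrm{max})$ through
the chart's log axes. The second click is described only as a horizontal
adjustment of the right half-parabola; we define `β` as the unique width for
which the half-parabola passes through the full cursor position, which is
monotone and invertible in cursor *x* at fixed height and therefore
parameter-identifiable. The inverse mapping (`clicks_from_params`) places
that click at the point one decade below the peak, $x = f_\mathrm{max} \cdot
2^{\beta/2}$. The third click's height sets `δ`, floored at zero when the
click is at or above the peak. Click positions outside the chart are clamped
to its edges with small safety margins (the peak keeps a 1% horizontal
margin so a width click remains placeable, and the peak sensitivity a floor
of 2.5); extreme parameters are thereby *censored at the chart range*, as
they necessarily were for human adjusters, rather than rejected.

**AUC** (`area_under_curve`) integrates $\max(f(x), 0)$ over $\log_{10}x$ on
a fixed 256-point trapezoidal grid: the conventional area under the log CSF
above sensitivity 1. The clamp at zero follows the usual reading of "area
under the curve" for a sensitivity function; a 10^5-point refinement changes
the default-range value by less than $10^{-3}$.

## Stimulus rendering

The chart (`chart_spec`, `render_chart`) spans 0.16–40 cpd over 14.4° and
Michelson contrast 0.001–0.5 over 8.12° (a 9°-tall, 1920×1200 preset is
provided; the shorter variant is the default since one must be). Contrast is
maximal at the *bottom*: the task instruction — click the highest point where
stripes are visible — only makes sense with stripes below and gray above,
the standard chart layout. The carrier's phase is the cumulative integral of
the log-swept instantaneous frequency, $\Phi(x) = \nu_0 W (r^{x/W} - 1)/\ln
r$ with $r = \nu_1/\nu_0$, not $\sin(2\pi\,\nu(x)\,x)$: only the integral
makes the local frequency at every column equal the labelled axis value.
The zero-crossing check in `analysis/01_render_stimuli.R` confirms the local
frequency to better than 1% across the chart; at very low frequencies the
crossing-based estimate must be compared to the label at the crossing
interval's midpoint, since the sweep changes by tens of percent within a
single half cycle there. `chart_spec` rejects geometries whose upper
frequency violates the Nyquist limit of the pixel grid.

Gratings (`render_grating`) are cosine-phase sinusoids under a Gaussian
window of 2° FWHM on the mean-gray background, so the Michelson contrast at
the envelope centre equals the nominal contrast.

Both renderers apply **noisy-bit dithering** (`noisy_bit`): each pixel's
continuous level `L` is stochastically rounded to `floor(L) + 1` with
probability `frac(L)`, one independent draw per pixel from a seeded stream.
The expected displayed image equals the ideal continuous image, which is the
method's entire point — spatial pooling then yields effective luminance
resolution beyond 8 bits. Renders are bit-identical under a fixed seed.

## QUEST and the session protocol

Each staircase (`quest_init`, `quest_update`) holds a posterior over
candidate log10-contrast thresholds on a 400-point grid spanning $[-4, 0]$
(the chart's contrast range with headroom), starting from a Gaussian prior
(SD 1 decade). The psychometric model is a Weibull in log10 contrast with
guess rate 0.5 (two-alternative orientation judgement), lapse 0.01 and slope
3.5 — the task and the 82% target are part of the protocol; slope and lapse
are not stated, so the reference QUEST defaults are used. The function is
*anchored* so that the probability of a correct response at threshold equals
the 82% target; this makes the staircase's estimand coincide with the
generative CSF, so parameter recovery is well defined. Both trial placement
and the final estimate use the posterior mean (the mean variant; the
placement rule is not stated, and the mean minimises expected quadratic
loss). Shown contrasts are clipped to $[10^{-4}, 0.5]$ — physical
displayability. The prior is supported on the grid, so with an extreme prior
mean the zero-trial estimate is the grid-truncated prior mean.

The session (`session_plan`, `run_session`) is 48 trials at each of 0.5,
0.99, 1.96, 3.87, 7.66, 15.16 and 30 cpd — 336 trials in four blocks of 84,
each frequency 12 times per block in randomised order, orientations
equiprobable. Starting values are configuration inputs: the published
protocol seeds them from group-average Gabor thresholds (ModelFest), whose
exact values are not printed, so the packaged defaults
(`default_start_values()`) are the adult group-mean curve evaluated at the
seven frequencies, rounded to 0.1 log unit. Monte-Carlo checks show a
48-trial track recovers a known threshold with bias under 0.05 and SD under
0.15 decades, and the empirical percent correct at the converged estimate is
within a point of the 82% target (slightly below it, because the estimate's
trial-to-trial spread interacts with the psychometric function's asymmetric
saturation).

## Synthetic observers and their calibration

`population_spec`/`sample_population` draw each observer's true CSF from
group distributions moment-matched to the gold-standard reference rows:
log-normal for `y_max` and `f_max`, zero-truncated normal (with numerically
moment-corrected parent parameters) for `β` and `δ`. Group means and SDs of
the samples therefore converge to the reference values — for adults
`β` 5.13 (1.02), `δ` 0.90 (0.36), `f_max` 3.62 (0.82), `y_max` 294.33
(135.19), and the corresponding child row.

The chart arm needs a generative link between the true curve and what an
observer adjusts on the chart. No mechanism is given for the chart/QUEST
discrepancy (candidates range from the subjective criterion to grating
adaptation and stimulus-size differences), so the package uses the *minimal*
stand-in able to reproduce the published group statistics: a multiplicative
log-space bias per parameter,

$$\log p_\mathrm{chart} = \log p_\mathrm{true} + b_p + \eta_{o,p} +
\varepsilon_{o,r,p},$$

with a fixed shift $b_p$, a stable per-observer effect $\eta \sim N(0,
\tau_p^2)$ and fresh per-run noise $\varepsilon \sim N(0, \sigma_p^2)$.
`calibrate_chart_bias` solves $b_p$ and the total bias variance from the
chart-row means and SDs (averaged across the three runs) by exact moment
algebra, then splits the variance so the expected inter-run correlation is
0.70, the published average reliability.

Two calibration facts deserve emphasis. First, the chart's contrast axis
caps displayable sensitivity at 1000, and the adult chart-row `y_max`
statistics (mean ≈ 667, SD ≈ 444) lie within a few percent of the largest SD
*any* distribution bounded by that cap can have at that mean (≈ 471). An
exact match therefore forces a near-two-point population in which a quarter
of simulated observers barely see the chart; the solver instead matches the
mean exactly (via closed-form censored-lognormal moments) and takes the most
dispersed population in which at most 1% of observers fall below peak
sensitivity 20, giving a chart-side `y_max` SD of about 370 for adults.
Second, the same censoring slightly depresses the realised chart `δ` mean
(≈ 0.99 vs the 1.05 reference for adults) and attenuates the realised
reliabilities to about 0.55–0.70 — still inside the bracket $[0.5, 0.9]$ the
tests enforce. These are consequences of pushing the published moments
through an explicit generative model, not tuning targets; the directions of
every published group difference (inflated chart peak at a lower frequency,
compressed width, higher low-frequency sensitivity) emerge from the default
calibration.

What the generator does **not** emulate: real observers' deviations from the
truncated log-parabola (our gold-standard fits reach median R² ≈ 0.99 vs
the published ≈ 0.96, because the generative truth *is* the model), eye
movements and grating aftereffects during chart viewing, attention lapses
beyond the constant lapse rate, and any age-specific mechanism other than
different population moments. Passing tests therefore validate the
*machinery* — staircase convergence, fitting, exclusion logic, CV protocol —
and the calibration's group-level statistics, not claims about individual
human behaviour.

## Group statistics

`apply_exclusions` applies the two published filters in order: drop
observers whose gold-standard fit has R² < 0.5, then drop observers with any
parameter |Z| > 3 within group × source, with z-scores computed once on the
post-R²-filter sample (no iterative re-screening — iteration is not stated,
and one pass is the minimal reading). Zero within-cell SD yields Z = 0.
Paired tests compare each observer's across-run chart mean to the
gold-standard value (which single run entered the published tests is not
stated; the mean is the least arbitrary choice), two-sided throughout, plus
log10 sensitivity at 0.5 cpd — the lowest tested frequency — since `δ`
itself confounds peak height and plateau. The method × group interaction is
the one-way ANOVA of the per-observer difference scores on group, the
between-subjects equivalent of the mixed-design interaction F(1, N−2).
Degenerate cases are flagged (`t = 0` for literally identical samples,
`NA` for constant nonzero differences) rather than returned as infinities.

## The prediction analysis

`nested_cv` follows the published protocol literally: 100 iterations; an
outer test set of ⌊N/6⌋ observations (16 of 96 adults, 12 of 74 children);
the training remainder split evenly into five inner folds; one
epsilon-insensitive SVR per kernel width (Gaussian kernel, FWHM 0.1–5.0 in
steps of 0.1, i.e. 50 candidates, converted by
$\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$) per fold; and — reading "the best
model (lowest RMSE) was chosen across the five folds and applied" verbatim —
the single *fold-model* with the globally lowest validation RMSE is applied
unchanged (not retrained) to the outer test set. Ties break towards the
smallest width for determinism. Only the kernel width is selected; `C = 1`
and `ε = 0.1` stay fixed so that selection is exactly the described
one-dimensional search. Features and targets are z-scored with
outer-training statistics only — reported RMSEs are then in target-SD units,
the only scale on which values like 0.74–0.92 are interpretable for
parameters ranging over hundreds — and the leakage test verifies that
shuffling test labels cannot change the inner selection. Test R² is
$1 - \mathrm{SSE}/\mathrm{SST}$ on the held-out set (may be negative; the
squared-correlation alternative is a config option, since which definition
was used is not stated). The permutation null re-pairs predictors and
targets across observers each iteration through a dedicated RNG stream, so
the identity permutation reproduces the real analysis bit for bit.

## Problem sizes, determinism, limitations

All randomness flows through `derive_seed(master, labels...)`, a hash of the
master seed and stage labels, so stages have independent streams and reruns
are byte-identical; changing one stage's configuration leaves upstream
output untouched. The package defaults match the study sizes (96/74
observers, 100 CV iterations). The bundled analysis scripts run the
simulation at full size but the 48-cell CV grid at 10 iterations per cell,
and the test suite exercises the machinery at 40 observers per group
(end-to-end), 10^4 draws (population calibration) and N = 96 (CV protocol) —
sizes chosen so the whole suite completes in a few minutes while leaving
every statistical check at least several standard errors of headroom.

Known limitations: the chart-bias model is a stand-in, explicitly labelled
as such — it reproduces published group moments and reliabilities but
implies nothing about the mechanism of the chart/gold-standard discrepancy;
the published RMSE/R² values of the prediction stage depend on the
unavailable human data and are deliberately not targets; rendering ignores
gamma calibration and monitor-specific luminance tables; and the chart is
rendered edge-to-edge (margin handling on the original displays is
unspecified).
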