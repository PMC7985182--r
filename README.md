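# crcsf

Does the visibility boundary on a Campbell-Robson chart trace the observer's
contrast sensitivity function (CSF)? The chart — a grating whose spatial
frequency sweeps logarithmically left to right while its Michelson contrast
sweeps logarithmically bottom to top — is the textbook illustration of the
CSF, on the intuition that the border between visible stripes and uniform
gray is the viewer's own sensitivity curve. `crcsf` implements, end to end
and on synthetic observers, the computational study needed to test that
intuition: a *three-click* procedure that adjusts a truncated log-parabola
directly onto the chart, a gold-standard QUEST measurement of the same
curve, and a machine-learning analysis asking how much of the gold-standard
CSF the chart adjustments can predict. No human data ship with the package;
a calibrated synthetic-observer generator stands in for both groups
(96 adults, 74 children), so every stage of the pipeline runs, and can be
probed, at desk scale.

## The model

Contrast sensitivity (the reciprocal of the Michelson contrast threshold) as
a function of spatial frequency *x* (cycles/degree, cpd) is modelled as a
truncated log-parabola with four parameters:

```
f(x) = log10(y_max) − ( (log10 x − log10 f_max) / (β·log10(2)/2) )²,
```

truncated on the low-frequency side to the plateau `log10(y_max) − δ`
wherever the parabola falls below it for `x < f_max`. Here `y_max` is the
peak sensitivity, `f_max` the frequency of the peak (cpd), `β` the full
width at half maximum (octaves), and `δ` the truncation depth (decades).

Three clicks on the rendered chart determine the four parameters: the first
click places the peak `(f_max, y_max)` through the chart's log axes, the
second sets `β` as the unique width whose right half-parabola passes through
the cursor, and the third sets the plateau height `δ`. The gold standard
measures the same curve by fitting the model to contrast thresholds at seven
frequencies (0.5–30 cpd), each estimated by an independent QUEST staircase
(48 trials, 82% target) on Gabor orientation judgements. The prediction
stage trains Gaussian-kernel support-vector regressions (50-width grid,
5-fold inner selection, N/6 outer test sets, 100 iterations) to predict each
gold-standard parameter from the chart parameters, against a permutation
null.

## A worked example

```r
library(crcsf)

# one synthetic adult: a true CSF plus chart-bias parameters
obs <- sample_population(population_spec("adult", n = 1, seed = 1))[[1]]
obs$true_csf
#> CSF (truncated log-parabola): y_max = 185.6, f_max = 3.679 cpd, beta = 4.491 oct, delta = 0.776

# gold standard: 336 QUEST trials, then fit the model to the 7 thresholds
session <- run_session(obs, session_plan(seed = 1), seed = 2)
round(session$estimates, 3)   # final log10-contrast thresholds per frequency
#>    0.5   0.99   1.96   3.87   7.66  15.16     30
#> -1.419 -1.595 -2.118 -2.375 -1.984 -1.418 -0.417
fit <- fit_csf(c(0.5, 0.99, 1.96, 3.87, 7.66, 15.16, 30), session$sensitivities)
fit
#> Truncated log-parabola fit (R^2 = 0.9950)
#> CSF (truncated log-parabola): y_max = 196.3, f_max = 3.584 cpd, beta = 4.46 oct, delta = 0.8736

# the same observer adjusts the chart: inflated peak, compressed width
cl <- simulate_clicks(obs, chart_spec(), run = 1, seed = 3)
params_from_clicks(cl$click1, cl$click2, cl$click3, chart_spec())
#> CSF (truncated log-parabola): y_max = 1000, f_max = 2.168 cpd, beta = 3.377 oct, delta = 0.9102

area_under_curve(fit$params, 0.5, 30)
#> [1] 3.114
```

The QUEST session recovers the generative curve (peak 196 vs 186, width 4.46
vs 4.49 octaves), while the chart adjustment shows the calibrated
distortions: a higher apparent peak at a lower frequency with a narrower
parabola.

## The analysis workflow

The numbered scripts under `analysis/` replay the whole study and write
their tables under `results/`:

1. `01_render_stimuli.R` — renders the chart (default and 9°-tall presets)
   and example gratings with noisy-bit dithering; verifies the local carrier
   frequency against the axis labels (max error < 1%).
2. `02_simulate_study.R` — simulates 96 adults and 74 children through the
   336-trial QUEST session and three chart runs each; writes the parameter
   table.
3. `03_group_stats.R` — exclusions (fit R² < 0.5, then |Z| > 3), the group
   mean/SD table per method, paired tests with the method × group
   interaction and the 0.5-cpd sensitivity contrast, AUC correlations,
   inter-run reliability, and average curves.
4. `04_prediction.R` — the 2 × 4 × 3 × 2 nested-CV SVR grid (real vs
   permuted pairings).

Run them in order from the repository root, e.g.
`Rscript analysis/02_simulate_study.R`.

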