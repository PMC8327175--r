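---
title: "Estimating transpulmonary driving pressure from EIT and airway pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating transpulmonary driving pressure from EIT and airway pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventdp)
```

## The physiological model

During controlled mechanical ventilation the respiratory system is well
approximated, over a tidal breath, by a single-compartment linear model in
which the pressure at the airway opening partitions into a resistive and an
elastic component,

$$P_{aw}(t) = PEEP + R_{rs}\,\dot V(t) + E_{rs}\,V(t),$$

and the elastance partitions into a lung and a chest-wall component,
$E_{rs} = E_L + E_{cw}$. With an end-inspiratory and an end-expiratory
occlusion (zero flow), the airway pressure reads out the elastic recoil
directly: the plateau pressure $P_{plat}$ and the total PEEP. The driving
pressure is $DP = P_{plat} - PEEP_{tot}$ and $E_{rs} = DP/TV$.

Esophageal pressure $P_{eso}$, a surrogate for pleural pressure, separates
the two compartments: the transpulmonary pressure is
$P_L = P_{aw} - P_{eso}$, its tidal swing is the transpulmonary driving
pressure $DP_L$, the lung elastance is $E_L = DP_L/TV$, and the
elastance-derived inspiratory transpulmonary pressure is
$PI = P_{plat}\,E_L/E_{rs}$ — the share of the plateau pressure borne by the
lung. End-expiratory $P_L$ may legitimately be negative and is never
clamped.

The package's central estimator replaces the esophageal measurement with
quantities available non-invasively. Because the esophageal signal reflects
the central lung, regional ventilation distribution measured by EIT — the
percentage of the tidal impedance change in four equal-height
ventral-to-dorsal bands of the 32×32 image — predicts $DP_L$ jointly with
airway mechanics through a five-regressor linear model:

$$\widehat{DP}_L = k + \alpha\,IBW + \beta\,E_{rs} + \gamma\,roi1\% +
\delta\,roi2\% + \epsilon\,roi3\%$$

with fixed coefficients $k = 16.64$, $\alpha = 0.074683$,
$\beta = 0.230941$, $\gamma = -0.21449$, $\delta = -0.15974$,
$\epsilon = -0.32996$ (ROI percentages on the 0–100 scale; the dorsal band
is intentionally absent). From $\widehat{DP}_L$ the chain continues
non-invasively: $E_{L,EIT} = \widehat{DP}_L / TV$ and
$PI_{EIT} = P_{plat}\,E_{L,EIT}/E_{rs}$.

Two points in this chain required a decision. First, the elastance
derivation is sometimes written with the ratio inverted ($TV/DP_L$); that
form is dimensionally inconsistent with elastance in cmH2O/L, so the package
implements $E_{L,EIT} = \widehat{DP}_L/TV$ throughout. Second, the scale of
the ROI covariates is inferred from the coefficient magnitudes: with
$roi1\% \approx 19$ the term $\gamma \cdot roi1\%$ contributes about
$-4$ cmH2O, which is physiologically plausible only on the 0–100 scale; the
0–1 scale would make the regional terms negligible.

## Model refitting: pooled OLS on a panel

Cohort data are a panel — each patient contributes one measurement at each
of several PEEP levels. `fit_dpl_model()` refits the prediction equation by
*pooled* ordinary least squares with an intercept on the stacked rows,
keeping the patient index as metadata. Pooled OLS contains no patient
dummies; describing a pooled estimation with unit fixed factors is
internally contradictory, and plain pooled OLS is also the estimator whose
in-sample mean residual — hence the Bland-Altman bias of predictions against
the fitting data — is zero to machine precision, matching the near-zero bias
that validation of this estimator reports. A fixed-effects (within)
estimator is available via `method = "within"` for sensitivity analysis; it
demeans all variables by patient and therefore cannot estimate the
coefficient of patient-invariant IBW, which is returned as `NA`.

## Agreement statistics

`rmcorr()` implements the repeated-measures correlation: an ANCOVA with
subject as a categorical factor and a common slope. With the sequential
sum-of-squares decomposition,
$r = \mathrm{sign}(b)\sqrt{SS_x/(SS_x + SS_{err})}$, which reduces exactly
to the Pearson correlation of the subject-mean-centered pairs; the degrees
of freedom are $N_{obs} - N_{subjects} - 1$ and p-values are two-sided from
the t distribution. No multiple-testing correction is applied by default
(a Bonferroni adjustment can be applied by the user); missing pairs are
dropped listwise, and subjects left with fewer than two pairs are excluded
with a warning.

`bland_altman()` reports the mean difference and limits of agreement at
bias ± 2 SD — the multiplier is exactly 2 by default, with 1.96 available
through `loa_mult` — using the sample (n−1) standard deviation.

Every statistic honors the per-measurement quality flag (`usable` column):
a measurement excluded after a quality check simply drops out of all
downstream statistics, and the pipeline manifest reconciles
`generated = analyzed + excluded`.

## What the synthetic cohort emulates

No clinical recordings ship with the package; the generator produces data
with the structure the analysis assumes.

* **Mechanics.** Each virtual patient has a true $E_L$, $E_{cw}$ and
  $R_{rs}$; severity strata draw $E_L$ uniformly from 8–15 (mild), 12–30
  (moderate) and 25–45 (severe) cmH2O/L with $E_{cw}$ from 5–15 cmH2O/L —
  ranges chosen to bracket a typical ARDS cohort with median $E_L$ 18 (IQR
  14–23) and median $E_{rs}$ 27 cmH2O/L — and a 6/9/5
  mild/moderate/severe mix in mechanistic cohorts. Ventilation is
  volume-controlled at 6 ml/kg IBW (Devine formula: male
  $50 + 0.91(h - 152.4)$, female $45.5 + 0.91(h - 152.4)$), square
  inspiratory flow, respiratory rate 19/min, occlusion pauses of 0.5 s on
  every breath, waveforms at 100 Hz and EIT at 20 Hz (typical of ICU
  monitors and EIT devices; all configurable). Expiration is passive with
  time constant $R_{rs}/E_{rs}$, and each breath starts from the
  steady-state residual volume, so volume is conserved exactly over a cycle
  and $P_{plat} - PEEP_{tot} = E_{rs}\,TV$ holds identically. The sampled
  flow is the sample-window mean of $dV/dt$, as a real flow sensor reports,
  which keeps the trapezoidal integral of flow consistent with the volume
  trace across the square-wave edges.
* **Esophageal signal.** $P_{eso} = baseline + E_{cw} V(t)$ plus Gaussian
  noise and a 1.3 Hz sinusoidal cardiac artifact (default amplitude
  1 cmH2O in mechanistic cohorts). Pause pressures are read as the median
  over the final half of each pause window; combined with averaging over
  the last 10 breaths — whose pause windows drift through the cardiac phase
  — this suppresses the artifact to well under 0.5 cmH2O.
* **EIT.** Band impedances are the regional volume shares resampled to the
  frame rate; the baseline ventral-to-dorsal profile centers on
  (19, 37, 31, 13) % and shifts dorsally with PEEP (linear shift,
  renormalized to the simplex), emulating PEEP-induced redistribution.
* **Cohort tables.** In *equation* mode the covariates are drawn as
  truncated normals around the pooled medians (IBW 65 kg, $E_{rs}$ 27
  cmH2O/L, ROI1–3 19/37/31 %, TV 375 ml) with spreads calibrated to the
  corresponding interquartile ranges (IQR/1.349), half the variance at the
  patient level and half at the condition level; the outcome is the
  published equation plus $N(0, \sigma)$ noise with $\sigma = 1.2$ cmH2O by
  default, the value consistent with limits of agreement of ±2.4 cmH2O.
  The noiseless outcome is retained for exact-recovery tests.

What the generator does **not** emulate: spontaneous breathing effort
(patients are modelled as sedated and paralyzed), nonlinear
(volume-dependent) elastance, intra-breath pendelluft, image reconstruction
from electrode voltages, and the device-specific anthropometric lung
contouring — the ROI bands are the standard equal-height quarters of the
image. Passing tests therefore demonstrate correctness of the computational
chain under linear two-compartment physiology, not robustness to every
feature of clinical signals.

## Numerical and tie-break choices

* Breath starts are flow upcrossings above `min_insp_flow` (default
  100 ml/s); occlusion windows are runs of $|flow| <$ `flow_eps` (10 ml/s)
  lasting at least `min_dur_s` (0.2 s). The inspiratory window is the first
  such run after peak inspiratory flow; the expiratory window is the last.
  Because the passive expiratory tail merges into the expiratory window,
  pressures are read over the final half of the window only, which lies
  inside the true occlusion whenever the occlusion is at least as long as
  the sub-threshold tail.
* Averaging order: per-breath landmarks are averaged first (up to the last
  10 usable breaths), then the mechanics formulas are applied — matching
  the one-value-per-measurement presentation of clinical tables. The
  alternative (per-breath mechanics, then averaging) differs only at second
  order and is available with `per_breath = TRUE`.
* Ensemble tidal image: per breath, the median frame over the inspiratory
  pause minus the median frame over the expiratory pause; negative pixels
  (artifact/pendelluft) are floored at zero with the count logged as an
  attribute. Whether regional fractions are computed per breath and then
  averaged, or from the ensemble image, is a genuinely open choice; the
  ensemble route is implemented (for identical noiseless breaths the two
  coincide).
* Published coefficients are stored at full printed precision and never
  rounded internally. Exact refit recovery (coefficients to 1e-6 on a
  noiseless equation-mode cohort) is part of the test suite.
* Degenerate inputs: zero tidal signal, constant outcomes, rank-deficient
  designs, missing pauses and absent oscillations all raise informative
  errors or flags rather than propagating NaNs.

## Problem sizes

The validation experiments use 20 patients × 3 PEEP conditions (60
measurements) for the mechanistic end-to-end run and the in-sample bias
check, 300 rows for coefficient-recovery refits at noise SD 0.1 cmH2O, 200
subjects × 3 observations for repeated-measures correlation recovery, and
500 seeded replicates (20 subjects × 3 each) for the null-calibration check
of the rmcorr p-values — sizes at which the Monte-Carlo error of each check
is comfortably below its acceptance tolerance.

## Known limitations

* The estimator transfers information from the central lung; dorsal (ROI4)
  regional compliance correlates weakly with esophageal $DP_L$, and the
  model deliberately omits ROI4. Regional transpulmonary pressure per ROI is
  out of scope.
* The published coefficients were estimated on one device family with
  proprietary lung contouring; with equal-band ROIs on other devices a refit
  (`fit_dpl_model()`) is advisable.
* Reported sign conventions for some ventral-ROI correlations differ
  between published summaries of this approach; `rmcorr()` reports the
  signed coefficient as computed and leaves interpretation to the user.
* No PEEP-step ΔEELV method, stress index, P0.1, balloon-calibration
  optimization, or mixed-effects agreement models are implemented.
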