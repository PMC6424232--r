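---
title: "Static ¹⁸F-fluoride Ki: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static fluoride Ki methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorideKi)
```

## The model

¹⁸F-fluoride exchanges between plasma, a free bone extracellular pool and
a bound bone-mineral pool:

$$\frac{dC_f}{dt} = K_1 C_p - (k_2+k_3)C_f + k_4 C_b, \qquad
  \frac{dC_b}{dt} = k_3 C_f - k_4 C_b,$$

with $K_1$ the plasma-to-tissue clearance (mL·min⁻¹·mL⁻¹), $k_2$ the
washout, $k_3$ the mineralization (binding) rate and $k_4$ the efflux from
bound mineral (all min⁻¹). Over a 60–90 min study $k_4 \approx 0$, the
tracer is effectively irreversible, and the physiologically meaningful
macro parameter is the net plasma clearance to bone mineral

$$K_i = \frac{K_1 k_3}{k_2 + k_3}.$$

The source text for this method names the model but never writes the
ODEs; we adopt the standard two-tissue configuration above, which is the
configuration the named framework uses. `simulate_tissue_curve()` solves
it by convolving the plasma input with the model's bi-exponential impulse
response using a recursive exponential integrator that is *exact* for
piecewise-linear input — so the only discretization error is the linear
resampling of the plasma curve onto the simulation grid (0.1 min by
default). The test suite checks it against an independent fixed-step RK4
integration of the ODEs to a relative error of 10⁻⁴.

For an irreversible tracer the Patlak transform
$x(t)=\int_0^t C_p\,ds / C_p(t)$, $y(t)=C_T(t)/C_p(t)$ becomes linear
beyond a settling time $t^*$, with slope $K_i$ and intercept the effective
distribution volume $V_0 = K_1 k_2/(k_2+k_3)^2$ (plus any fractional blood
volume). `patlak_fit()` is the dynamic (oracle) estimator; the product
estimator is the **static** single-time-point inversion

$$\hat K_i = \frac{C_{bone}(T) - V_0\,C_p(T)}{\int_0^T C_p\,dt},
\qquad T = 60\ \text{min}.$$

## The semi-population input function

Two venous samples at 55 and 85 min determine a terminal exponential
$A e^{-\lambda t}$ exactly ($\lambda=\ln(c_1/c_2)/(t_2-t_1)$,
$A = c_1 e^{\lambda t_1}$; three or more samples fall back to log-linear
least squares). The unobservable early bolus/distribution phase is
borrowed from a population curve as the *residual*
$r(t) = C_p^{pop}(t) - A^{pop}e^{-\lambda^{pop} t}$, where the population
terminal is fitted over the same 55–85 min window, so $r(t)\approx 0$
wherever the patient's own data constrain the curve:

$$\hat C_p(t) = A e^{-\lambda t} + s\, r(t).$$

**Residual scaling `s`.** The method description ("add the population
residual") does not say whether prior work rescales $r$ per patient.
Both behaviours are implemented on `reconstruct_input()`:
`"unit"` ($s=1$, the literal reading) and `"terminal-ratio"`
($s$ = patient/population terminal value at 55 min). The cohort
quantifier defaults to `"terminal-ratio"` because synthetic patients
differ from the population curve by a global scale (injected dose and
disease-burden depression), for which the ratio mode is exact while
$s=1$ leaves a ∼7% bias in $\int C_p$; on real data with shape (not just
scale) differences neither mode is provably better, and we assert
neither as "correct".

**The packaged population curve is synthetic.** The original population
acquisition (10 postmenopausal women) is not reproducible from printed
data, so the default tri-exponential — amplitudes (200, 35, 10) kBq/mL at
rates (4.0, 0.25, 0.011) min⁻¹ — was chosen once to resemble published
fluoride input-function shapes for a ∼230 MBq injection (sharp bolus
peaking near 245 kBq/mL, fast distribution phase, late plasma of
4–6 kBq/mL over 55–85 min). It is a documented fixture stored in
`inst/extdata/population_if.json`, not a measurement.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| scan time $T$ | 60 | min | single static acquisition at 60 min uptake; per-bed time offsets ignored |
| venous times | 55, 85 | min | the sampling protocol |
| $V_0$ | 0.40 | — | population intercept placeholder; never printed by the source, calibrated to be of the right magnitude for the simulator's kinetics (lesion-true values ≈ 0.1–0.6, mean ≈ 0.31); sensitivity is exactly $\partial \hat K_i/\partial V_0 = -C_p(T)/\int_0^T C_p \approx -0.008\,\text{min}^{-1}$, i.e. a ±0.1 error in $V_0$ moves $\hat K_i$ by ∓0.0008 (∼1% of a typical 0.067) |
| $t^*$ (dynamic Patlak) | 10 | min | fluoride Patlak plots are conventionally linear beyond ∼10 min; the suite checks 10 vs 30 min agreement |
| threshold | ±25 | % | PD is a change **strictly** greater than +25%, PR strictly below −25%, SD otherwise; the source uses both "at least 25%" and ">25%", the strict reading is chosen and pinned by a boundary regression test (25.0 → SD) — on the packaged fixture both readings give identical counts |
| index-lesion rule | ≤5, SUV$_{max}$≥10, ≥1 cm | | diameter is the equivalent-sphere diameter from ROI volume, since no measurement axis is specified |
| segmentation threshold | 40% of local max | | voxels ≥ 0.40 × the hill-climbed component maximum, 26-connected; manual reader correction is out of scope |
| half-life | 109.77 | min | ¹⁸F |
| blood volume fraction | 0 | — | not modelled by the method; exposed on the simulator for realism studies |

## What the synthetic generator emulates

`cohort_spec()` defaults state one world and are not revisited:

* 12 patients, 4 PD / 8 non-PD; 2–6 lesions each; injected activity
  $\mathcal N(228, 15^2)$ MBq; body weight $\mathcal N(70, 12^2)$ kg.
* Baseline kinetics log-normal with medians $K_1=0.20$, $k_2=0.30$,
  $k_3=0.15$ (median $K_i \approx 0.067$, matching typical published
  metastasis values); $k_4 = 0$.
* Treatment multiplies $K_i$ by a log-normal factor — median ×1.9 (PD) or
  ×1.1 (non-PD) — applied through $k_3$, because response is attributed to
  mineralization, not delivery; if the implied extraction fraction
  $k_3/(k_2+k_3)$ would exceed 0.9, the remainder is carried by $K_1$ so
  the drawn multiplier is always achieved exactly.
* 15% of non-PD lesions *flare* (median ×1.5), emulating the ∼5/32
  false-positive lesions of the reference cohort. Dispersion parameters
  are calibrated only to patient-level printed summaries and are flagged
  as assumptions — no lesion-level variances are published.
* **Disease burden.** The patient/visit plasma curve is the population
  curve times $(\text{dose}/228)\cdot\exp(-\beta \sum_j K_{i,j})$ with
  $\beta = 1$ mL⁻¹·min·mL. Rising total flux at week 8 depresses the
  input function; $C_{bone}$ then rises less than $K_i$, and SUV (which
  never sees $C_p$) underestimates progression. This is the mechanism
  behind the directional acceptance check (Ki PD-sensitivity ≥ SUV's),
  and it is the package's chosen quantification of a mechanism the source
  only describes qualitatively.
* Measurement noise: mean-one multiplicative log-normal, CV 5% on venous
  samples and on $C_{bone}(T)$.
* SUV$_{mean}$ is derived from the same $C_{bone}(T)$ plus a 5%
  plasma-pool term; SUV$_{max}$ = SUV$_{mean}$ × a per-lesion
  heterogeneity factor (log-normal, median 1.85) held fixed across visits.

**What it does not emulate:** scanner physics (resolution, scatter,
partial volume — explicitly uncorrected in the method), anatomically
realistic skeletons, reader variability, arterial/venous differences, or
any biology of the flare phenomenon beyond a multiplier mode. A green
simulation test therefore establishes internal consistency of the
estimator chain, not clinical accuracy.

## Numerical choices and degenerate inputs

* All $\int C_p$ terms use the trapezoidal rule on the stored grid;
  simulation grid 0.1 min.
* The convolution kernel's $a\to 0$ branch (e.g. $k_4=0$) switches to the
  exact polynomial limit below $ah < 10^{-8}$.
* Negative reconstructed plasma values are clipped to 0 with a warning
  (concentrations are physical); negative static $\hat K_i$ likewise,
  configurable via `clip = FALSE`.
* `static_ki()` requires $V_0 \ge 0$. A *fitted* Patlak intercept can come
  out slightly negative at small true $V_0$ (residual curvature beyond
  $t^*$); validation against "correct $V_0$" therefore uses the model-true
  $K_1k_2/(k_2+k_3)^2$.
* Index-lesion ties: SUV$_{max}$ desc, then volume desc, then lexical id.
* Degenerate statistics (zero variance groups) are reported as `NA` with a
  warning rather than an error; the Shapiro–Wilk log-transform gate
  (α = 0.05, on paired differences, only when all values are positive)
  treats near-constant vectors as normal.
* `fit_terminal_exponential()` rejects equal sample times and non-positive
  concentrations; a rising pair (c₂ > c₁) yields a negative λ, which is
  mathematically valid and left to the caller.

## Known limitations

* $V_0$ is a single population scalar; per-lesion deviations leave a
  residual error of a few percent in absolute $K_i$ (largely cancelling
  in percentage change). The "modified" element of the published static
  method and its $k_4$ correction live in prior work that prints no
  formula; $k_4$ is therefore exposed in simulation (so the induced bias
  can be *measured*) but no bespoke correction is implemented.
* The package reproduces patient-level published summaries exactly from
  the packaged fixture, but lesion-level counts, baseline/week-8
  correlation tables, disease-burden subgroups and normal-bone changes
  depend on unpublished lesion-level data and are deliberately not
  asserted anywhere.
* The response classifier is the ±25% EORTC-adapted rule only; PERCIST/MDA
  variants are out of scope beyond the configurable threshold.

## A minimal end-to-end run

```{r example, eval = FALSE}
cohort <- generate_cohort(cohort_spec(), seed = 1)
tab <- quantify_cohort(cohort)            # static pipeline
ref <- unique(cohort$truth[, c("patient_id", "group")])
names(ref) <- c("patient_id", "reference_label")
confusion_counts(classify_response(tab), ref)
```
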