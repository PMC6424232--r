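# fluorideKi

Quantification of bone metabolic flux from **static ¹⁸F-fluoride PET** and
treatment-response classification of bone metastases.

¹⁸F-fluoride is cleared from plasma into the bone mineral compartment at a
net rate K_i (mL of plasma per minute per mL of tissue), the macro
parameter of the standard two-tissue ("Hawkins") compartment model,

    K_i = K1 · k3 / (k2 + k3).

Measuring K_i normally needs a 60-min dynamic scan and arterial sampling.
This package implements the static alternative: a **semi-population input
function** — a terminal exponential fitted to two late venous plasma
samples (55 and 85 min), plus a population-derived residual curve for the
unobservable early bolus phase — combined with a single-time-point
inversion of the Patlak relation,

    K_i = ( C_bone(T) − V0 · Cp(T) ) / ∫₀ᵀ Cp dt ,     T = 60 min,

where V0 is a population value of the Patlak intercept (effective
distribution volume). Because SUV ignores the input function, it can
underestimate changes in mineralization when plasma fluoride falls (high
disease burden, treatment effects on normal skeleton); K_i does not. The
package bundles:

- `kinetics` — forward two-tissue simulator (exact exponential-integrator
  convolution) and dynamic Patlak analysis, used as the validation oracle;
- `input_function` — venous-sample terminal fit, population residual,
  reconstruction, plasma integral;
- `quantification` — well-counter calibration, decay correction, SUV,
  40%-of-maximum lesion segmentation, static K_i;
- `response` — index-lesion selection (≤5, SUV_max ≥ 10, ≥1 cm),
  percentage change, PD/SD/PR classification at ±25%, cohort statistics,
  confusion counts against a clinical reference standard;
- `synthetic` — a full synthetic-study generator (cohorts with ground-truth
  kinetics, treatment multipliers, flare false positives, disease-burden
  input depression, Gaussian-blob phantoms) so every stage is testable
  without patient data;
- a small CLI: `simulate`, `quantify`, `classify`, `report`, `fixtures`.

## Worked example

Simulate a 12-patient cohort (4 progressive / 8 non-progressive), quantify
it through the static pipeline, and score the classification against the
simulated ground truth:

```r
library(fluorideKi)

cohort <- generate_cohort(cohort_spec(), seed = 1)
tab    <- quantify_cohort(cohort)                 # venous fit -> Cp -> static Ki
ref    <- unique(cohort$truth[, c("patient_id", "group")])
names(ref) <- c("patient_id", "reference_label")

res <- classify_response(tab)
confusion_counts(res, ref)
```

which prints

```
    metric n_PD n_nonPD identified_PD identified_nonPD false_positive
1       ki    4       8             4                7              1
2  suv_max    4       8             4                7              1
3 suv_mean    4       8             4                7              1
```

i.e. at this seed every metric identifies all 4 progressive patients and
7 of 8 non-progressive patients (one flare-like false positive); across
seeds K_i's PD sensitivity is never below the SUV metrics' (the
acceptance suite prints the per-seed table). The packaged reference-cohort
fixture shows the published-scale behaviour:

```r
fx <- table3_cohort()
res <- classify_response(fx$lesion_table)
cohort_stats(res, fx$reference)$group_stats
```

```
    metric  group n mean_pct_change sd_pct_change
1       ki     PD 4         89.6750        61.163
2       ki non-PD 8         11.0375        36.902
3  suv_max     PD 4         41.7750        27.836
4  suv_max non-PD 8          6.1625        28.797
5 suv_mean     PD 4         43.4750        41.763
6 suv_mean non-PD 8          7.4375        27.394
```

— the progressive group's mean K_i rises ~90% versus ~11% in the
non-progressive group, a much wider separation than either SUV metric.

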