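# radcell

Tools for planning and analysing in vitro exposures of cell cultures to a
radionuclide dissolved in the culture medium, built around the
beta-emitter silver-111 (t½ = 7.45 d). The package covers the full
computational chain of such a study, for radiobiologists and medical
physicists running cell experiments with unsealed radiometal sources:

* **MIRD-schema cell dosimetry** — absorbed dose from an activity
  concentration, D(T) = S·Ac·(1−e^(−λT))/λ, its exact inversion for
  exposure planning, dose-rate curves, time-matched activity series for
  multi-arm designs, and the cytoplasm-internalization scenario
  (extra nucleus dose S_cyto·V_cyto/S_medium).
* **Ag–Cl speciation** — mass-balance equilibrium over Ag⁺, AgCl(aq),
  AgCl₂⁻ and solid AgCl (Ks = 1.77×10⁻¹⁰, β₁ = 2×10³, β₂ = 1.86×10⁵),
  with an explicit saturation branch.
* **Clonogenic assay reduction** — plating efficiency, surviving
  fractions against each arm's own control, weighted linear-quadratic
  fits SF(D) = exp(−αD−βD²) with an exactly handled β ≥ 0 bound,
  isoeffect doses and RBE at a surviving-fraction endpoint
  (RBE = D_ref/D_test).
* **Image quantification** — γ-H2AX/53BP1 foci per nucleus by
  difference-of-Gaussians filtering and the 3× median-background-SD
  threshold rule, recurrence groups (0, 1–4, 5–9, ≥10), and micronucleus
  frequency with binomial standard errors.
* **Synthetic data** — colony tables (binomial thinning under the LQ law)
  and two-channel micrograph pairs with full ground truth, so every stage
  is testable without external data; `run_pipeline()` chains everything
  into a machine-readable report.

Functions take data frames first and return tibbles; fitted LQ objects
support `tidy()`, `glance()`, `confint()`, `predict()` and `autoplot()`.

## Worked example

Plan a two-arm exposure, check the chemistry, simulate an experiment and
fit it:

```r
library(radcell)

plan_exposure(c(0.5, 1, 2, 4), c(4, 6))
#> # A tibble: 8 × 4
#>   dose_Gy exposure_days activity_kBq_per_mL activity_planned_kBq_per_mL
#>     <dbl>         <dbl>               <dbl>                       <dbl>
#> 1     0.5             4                59.8                          60
#> 2     1               4               120.                         120
#> 3     2               4               239                          239
#> 4     4               4               478                          478
#> 5     0.5             6                43.4                          43
#> 6     1               6                86.8                          87
#> 7     2               6               174.                         174
#> 8     4               6               347.                         347
```

Delivering 4 Gy over 4 days needs 478 kBq/mL; the same doses over 6 days
(a lower dose rate) need the 43–347 kBq/mL series, because only the decay
integrals differ.

```r
speciate_agcl(total_ag = 1.23e-7, total_cl = 2.46e-1)
#> AgCl2-: 95.8%  AgCl: 4.2%  free Ag+: 0.0085%  saturated: FALSE
```

The administered solution holds the silver almost entirely as the soluble
dichloroargentate complex; no free ion, no precipitate.

```r
colonies <- simulate_clonogenic(alpha = 0.5, beta = 0.04, seed = 42)
fit <- fit_lq_colonies(colonies)
fit
#> <lq_fit> SF(D) = exp(-alpha D - beta D^2)
#>   alpha = 0.4762 +/- 0.0414 Gy^-1
#>   beta  = 0.0476 +/- 0.0135 Gy^-2
#>   fitted on 15 points (inverse-variance weighted)

rbe(fit, lq_params(0.12, 0.06), sf = 0.1)
#> [1] 1.479786
```

The dish-level fit recovers the generating parameters (α = 0.5,
β = 0.04) within one standard error. Against a photon reference curve
(α = 0.12 Gy⁻¹, β = 0.06 Gy⁻²) the fitted curve needs 1.48× less dose
for 10% survival. `autoplot(fit)` draws the survival curve;
`run_pipeline(pipeline_config())` runs every stage and writes
`report.json`/`report.md`.

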