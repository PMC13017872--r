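---
title: "Methods: cell-level dosimetry, speciation and assay statistics in radcell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-level dosimetry, speciation and assay statistics in radcell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radcell)
```

radcell supports in vitro studies in which a beta-emitting radiometal —
silver-111, half-life 7.45 d — is dissolved directly in the culture medium
and cells are scored for clonogenic survival, DNA-damage foci and
micronuclei. This vignette is the package's account of the models it
implements, the defaults it chose where choices were open, and what its
synthetic-data validation does and does not demonstrate.

## Dosimetry: the MIRD schema for a medium source

With the radionuclide uniformly dissolved in the medium, the dose rate to a
cell is the product of an S-value (mean absorbed dose per unit cumulated
activity concentration) and the decaying activity concentration,

$$\dot D(t) = S \cdot A_c \cdot e^{-\lambda t}, \qquad
  D(T) = S \cdot A_c \cdot \frac{1 - e^{-\lambda T}}{\lambda},$$

with $\lambda = \ln 2 / T_{1/2}$. `decay_integral()` implements the factor
$(1-e^{-\lambda T})/\lambda$ (computed with `expm1` so short windows do not
lose precision), `dose_from_activity()` and `activity_for_dose()` are the
forward map and its exact algebraic inverse, and `equivalent_activity()`
re-plans a concentration from one exposure time to another — the S-value
cancels, so only the two decay integrals matter.

Internally every time is in seconds and every concentration in Bq/mL; the
user boundary speaks days and kBq/mL (1 d = 86 400 s exactly). Planned
concentrations are rounded to integer kBq/mL only in the reporting column
`activity_planned_kBq_per_mL`, never internally.

### The medium S-value and its calibration

The literature value for a cell in a radioactive medium half-space is
quoted as "half of 0.06 mGy/(Bq s)" with a unit string whose volume factor
is ambiguous. radcell therefore ships two constants:

* `s_medium_calibrated()` — the default, $2.8998\times10^{-11}$
  Gy·mL/(Bq·s), obtained by inverting the dose equation at the published
  anchor point (478 kBq/mL delivering 4 Gy over 4 d). This value
  reproduces the full published two-arm concentration ladder.
* `s_medium_nominal` — the naive reading $3\times10^{-11}$ Gy·mL/(Bq·s)
  (0.03 mGy·mL/(MBq·s)), which reproduces the ladder only to about 3.5%.

The 3.4% gap between the two is documented rather than hidden: use the
calibrated value to reproduce the published plans, the nominal one to
propagate the original Monte Carlo figure.

A subtlety of the published ladders: the 4-day and 6-day series were each
rounded to integer kBq/mL independently, from the same dose ladder
{0.5, 1, 2, 4} Gy. Mapping one integer series onto the other can therefore
disagree with the printed partner by up to
$0.5 \cdot I(4\,\mathrm{d})/I(6\,\mathrm{d}) + 0.5 \approx 0.86$ kBq/mL
(119 kBq/mL maps to 86.45, printed as 87). The tests assert the anchor
pairs exactly and the full series within this provable 1 kBq/mL
double-rounding slack.

### Internalization scenario

If the cell internalizes the radiometal so that the cytoplasm carries the
same activity concentration as the medium, the extra nucleus dose relative
to the medium-only dose is

$$\frac{S_{N \leftarrow Cy} \cdot A_c V_{cy} \cdot I(T)}
       {S_{med} \cdot A_c \cdot I(T)}
  = \frac{S_{N \leftarrow Cy} \, V_{cy}}{S_{med}},$$

independent of both $A_c$ and $T$. With the published
$S_{N \leftarrow Cy} = 0.075$ mGy/(Bq·s) and the calibrated medium
S-value, a 1000 µm³ cytoplasm adds 0.26%. The cytoplasm volume is an
order-of-magnitude assumption (the source reference for the S-values does
not print it); it is a configurable parameter, flagged as assumed in
pipeline reports, and the sub-1% conclusion is insensitive to it up to
3000 µm³.

## Ag–Cl speciation

The administered solution contains trace silver
($1.23\times10^{-7}$ M) in a large chloride excess (0.246 M). Four species
are modelled: Ag⁺, AgCl(aq) ($\beta_1 = 2\times10^3$ M⁻¹), AgCl₂⁻
($\beta_2 = 1.86\times10^5$ M⁻²) and solid AgCl
($K_s = 1.77\times10^{-10}$ M²). `speciate_agcl()` solves both mass
balances: the outer loop brackets free [Cl⁻] (the chloride balance is
monotone in it), and at fixed [Cl⁻] the silver balance is linear in free
[Ag⁺], so the inner step is closed-form. If the resulting ion product
exceeds $K_s$, the saturated branch re-solves with the solid as an
unknown, pinning the residual solution exactly at $K_s$; fractions are
then reported over total silver including the solid. Root bracketing
failures raise errors; nothing converges silently.

Activity coefficients are ignored (concentrations treated as activities),
matching how the stability constants are used; no polynuclear complexes
and no temperature corrections are modelled. The unrounded equilibrium
gives 95.8% AgCl₂⁻ and 4.2% AgCl — reported unrounded, rounded to 96%/4%
only for display.

## Clonogenic survival and the linear-quadratic model

Plating efficiency is colonies over seeded cells per dish; a condition's
PE is the replicate mean with SE = SD/√n (a single dish reports `NA`, not
zero). The surviving fraction divides a treated condition's PE by the
same arm's control PE, with relative errors added in quadrature. The
dose-0 row carries SF = 1 with the control's own relative SE: the
numerator and denominator of SF(0) are the same measurement, so doubling
that error term would be wrong.

`fit_lq()` fits $-\ln SF = \alpha D + \beta D^2$ by (optionally
inverse-variance weighted) least squares with $\beta \ge 0$. Because the
model is linear in the coefficients, the constrained optimum is exact:
when the unconstrained $\hat\beta$ is negative the bound is active and
the linear-only model is refitted, with `bound_active = TRUE` recorded —
the behaviour survival tables show when the quadratic term is estimated
"exactly as zero". Points with SF ≥ 1 at positive dose are retained (with
a message); points with SF ≤ 0 cannot enter a log-scale fit and are
dropped loudly.

### Two inference routes, one calibrated

The SF-point route above matches the traditional presentation, but its
reported uncertainties are approximate for two structural reasons we
quantified by simulation: every SF point shares the same control divisor
(correlated errors a diagonal-weight fit ignores), and SEs estimated from
triplicates are themselves ~50% noisy. At the study-scale design
(4 doses, triplicate, 1000 cells/dish) its nominal 95% intervals for
$\alpha$ covered the truth in only ~82% of 500 simulated experiments.

`fit_lq_colonies()` is therefore the preferred route whenever dish-level
counts exist: it fits $\ln PE_{dish} = \ln pe_0 - \alpha D - \beta D^2$
to the independent per-dish observations with model-based binomial
weights $w = n\hat p/(1-\hat p)$. The control enters through the
intercept, dish errors are independent, and t-intervals on the residual
degrees of freedom are calibrated: measured coverage 95.0% over 500
simulated experiments at the same design. The pipeline and the package's
own validation use this route; `fit_lq()` remains for tabulated survival
data.

### Isoeffect doses and RBE

`dose_at_sf()` inverts the survival model in closed form: for
$\beta > 0$, $\beta D^2 + \alpha D + \ln s = 0$ has exactly one positive
root (the root product is negative), which is asserted rather than
assumed; $\beta = 0$ reduces to $-\ln(s)/\alpha$. RBE at an endpoint is
$D_{ref}/D_{test}$. With the tabulated reference photon curve
(α = 0.12 Gy⁻¹, β = 0.06 Gy⁻²) and the 6-day arm (α = 0.5, β = 0.04) the
10%-survival RBE evaluates to 1.47 from these rounded parameters; the
unrounded study fits give 1.43, so agreement is expected only to ~5%. No
RBE uncertainty is propagated — a documented limitation, as the
underlying fits' covariances would be needed on both sides.

## Image quantification

Nuclei are segmented from the DAPI channel by Otsu's global threshold on
a lightly smoothed image, connected-component labelling, and removal of
objects below `nucleus_min_area` (50 px) or touching the border. No
watershed splitting is attempted: the synthetic fixtures place nuclei
without contact, and a segmentation method should not be more elaborate
than its validation data can exercise.

Foci are counted per nucleus in the DoG-filtered focus channel
(σ = 1 and 4 px) with the threshold rule used by standard foci-counting
macros: threshold = 3 × the median over nuclei of the per-nucleus
background SD. The background SD is computed in two passes, both
deliberate choices:

1. a provisional threshold uses the per-nucleus **median absolute
   deviation** — a plain SD here is inflated up to ~3× by bright foci,
   which would push the final threshold to a large fraction of the spot
   peak and silently drop real foci;
2. pixels above the provisional threshold are **dilated by 3 px**
   (`bg_exclusion_radius`) before exclusion, because a bright spot's
   sub-threshold Gaussian tail otherwise remains in the "background" and
   still inflates the SD when foci are dense.

Candidate foci are connected components above the final threshold inside
each nucleus; components under `min_focus_area = 3` px are discarded
(DoG-filtered noise is spatially correlated, so 2-px noise clusters do
occur; measured on blank channels, 3 px removes them while real spots
span 8–15 px). Counts fall into the conventional recurrence groups 0,
1–4, 5–9, ≥10. Pixel coordinates are 1-based (row, column) throughout,
the native R matrix convention.

Micronuclei are small DAPI-positive objects outside any nucleus with area
in 1–30% of the mean nucleus area, circularity ≥ 0.6, and centroid within
25 px of the nearest nucleus boundary; each is assigned to the nucleus
with the closest centroid. These morphology gates are declared defaults,
not inferred from any reference macro (manual counting has no published
criteria), and all are configurable via `detection_params()`. The summary
statistic is the fraction of cells with ≥ 1 micronucleus with the
binomial standard error $\sqrt{p(1-p)/n}$ over scored cells; records from
several images or coverslips can be concatenated before summarising if
the denominator should be a different sampling unit.

## Synthetic data: what it emulates, and what it does not

`simulate_clonogenic()` draws per-dish colony counts as binomial
thinnings, colonies ~ Binomial($n$, $pe_0 \cdot SF(D)$) — binomial rather
than Poisson so a count can never exceed the cells seeded. Defaults are
the study-scale design chosen once and kept: dose ladder {0.5, 1, 2, 4}
Gy, triplicate dishes, 1000 cells per dish, $pe_0 = 0.5$ (a mid-range
plating efficiency for established lines seeded at 50–1000 cells per
dish). A noise-free mode returns expected counts, making generating
parameters exactly recoverable — the sharpest possible regression test of
the fitting code.

`generate_image_pair()` renders elliptical nuclei (major axis 20–30 px at
the default 512×512 scale, smooth interior profile), near-diffraction
foci (Gaussian, σ = 0.8 px) planted inside nuclei, micronuclei as small
discs 3–6 px outside a random fraction of nuclei, and white Gaussian
noise in both channels; focus amplitudes are stated in multiples of the
noise SD, the scale the detection threshold lives on. Foci are planted
with a minimum pairwise separation (5.5 px) by best-candidate sampling:
two spots closer than that are not resolvable by connected-component
counting at this band-pass (their superthreshold regions bridge), so
closer configurations would make the ground truth unverifiable by
construction. Dense counts (k = 7) therefore need nuclei at the upper end
of the size range; the validation fixtures use 24–30 px major axes.
Infeasible packings — of nuclei in the image or foci in a nucleus — fail
explicitly rather than degrade.

Every generator is a pure function of its configuration and seed (RNG
state is isolated with `withr::with_seed`), and ground-truth tables list
every planted object.

What passing these tests shows: the dosimetry algebra, the equilibrium
solver, the fitting and inference machinery, and the detection rules are
implemented correctly and are calibrated under their own assumptions.
What it does not show: performance on real micrographs — real nuclei
touch and overlap, illumination is uneven, foci sizes and intensities are
heterogeneous, background is structured — nor the biology of real
survival curves (dose-rate-dependent repair, the G factor, cell-cycle
effects are all out of scope). The simulators validate the software, not
the assay.

## Numerical choices and problem sizes

* Speciation root bracketing: relative tolerance $10^{-12}$; mass
  balances verified to $10^{-10}$ in tests.
* Decay integral vs quadrature: agreement to $10^{-8}$ relative.
* Inversion round-trips (dose ↔ activity, SF ↔ isoeffect dose):
  $10^{-9}$ relative.
* Validation sizes, chosen as the package's own test design: 500
  simulated experiments for CI coverage; 100 nuclei for foci recovery
  (mean absolute error ≤ 0.5 at 10× amplitude); 200 cells for the
  micronucleus frequency check (3 binomial SEs around the planted 10%).

## Known limitations

* No dose-rate-dependent survival modelling; each exposure arm is fitted
  independently with the plain LQ model.
* RBE is reported without uncertainty.
* The micronucleus morphology gates are plausible defaults, not tuned to
  any reference dataset.
* The segmenter has no overlap resolution; crowded fields need a
  watershed-capable tool upstream, after which the counting functions
  apply unchanged.
* Activity-coefficient corrections are absent from the speciation model;
  at 0.25 M ionic strength the true constants shift somewhat, which is
  why the solver takes the constants as inputs.
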